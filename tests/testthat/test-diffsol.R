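sim_norm_profile <- function(n = 300, noise_sd = 0, seed = 21, ...) {
  sim <- simulate_solubility_dataset(sim_config(n, noise_sd = noise_sd,
                                                seed = seed, ...))
  norm <- fit_apply_normalization(sim$table,
                                  select_calibration_subset(sim$table))
  list(sim = sim, prof = compute_solubility(norm$table))
}

test_that("solubility and RBF arithmetic follow the definitions", {
  x <- sim_norm_profile(200, noise_sd = 0, seed = 21)
  sol <- x$sim$truth$class == "predominantly_soluble"
  ins <- x$sim$truth$class == "rnase_insensitive_insoluble"
  sen <- x$sim$truth$class == "rnase_sensitive_insoluble"
  expect_equal(max(abs(x$prof$S$preserved[sol, ])), 0, tolerance = 1e-6)
  expect_equal(unname(x$prof$S$preserved[ins, 2]), rep(-1, sum(ins)),
               tolerance = 1e-6)
  rbf <- compute_rna_bound(x$prof)
  expect_equal(max(abs(rbf[sol | ins, ])), 0, tolerance = 1e-6)
  # rescue +1 in the digested lysate gives RBF = -1 exactly
  expect_equal(unname(rbf[sen, 1]), rep(-1, sum(sen)), tolerance = 1e-6)
})

test_that("moderated test handles identical groups and degenerate rows", {
  m <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("f", 1:10), NULL))
  res <- suppressWarnings(moderated_diff(m, m, paired = TRUE))
  expect_equal(res$logFC, rep(0, nrow(res)))
  expect_equal(res$p, rep(1, nrow(res)))
  expect_true(all(res$call == "not_changing"))
})

test_that("prior df forced to 0 reproduces the ordinary t exactly", {
  set.seed(31)
  a <- matrix(rnorm(600, 0, 2), 200, 3, dimnames = list(paste0("f", 1:200), NULL))
  b <- matrix(rnorm(600), 200, 3, dimnames = list(paste0("f", 1:200), NULL))
  res <- moderated_diff(a, b, paired = FALSE, prior_df = 0)
  tt <- vapply(seq_len(200), function(i)
    unname(stats::t.test(a[i, ], b[i, ], var.equal = TRUE)$statistic),
    numeric(1))
  expect_equal(res$t, tt, tolerance = 1e-9)
  # paired flavor too
  resp <- moderated_diff(a, b, paired = TRUE, prior_df = 0)
  tp <- vapply(seq_len(200), function(i)
    unname(stats::t.test(a[i, ] - b[i, ])$statistic), numeric(1))
  expect_equal(resp$t, tp, tolerance = 1e-9)
})

test_that("empirical-Bayes fit matches the limma oracle", {
  set.seed(7)
  n <- 400
  s2_true <- 0.5 * stats::rf(n, 4, 8)
  y <- t(sapply(seq_len(n), function(i) stats::rnorm(6, 0, sqrt(s2_true[i]))))
  y[1:40, 1:3] <- y[1:40, 1:3] + 2
  rownames(y) <- paste0("f", 1:n)
  res <- moderated_diff(y[, 1:3], y[, 4:6], paired = FALSE)
  fit <- limma::eBayes(limma::lmFit(y, design = cbind(1, c(1, 1, 1, 0, 0, 0))))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  set.seed(17)
  for (rep in 1:20) {
    p <- runif(sample(3:100, 1))^sample(1:3, 1)
    expect_equal(phosol:::bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("null simulation keeps the BH false-call fraction controlled", {
  set.seed(41)
  n <- 500
  a <- matrix(rnorm(3 * n), n, 3, dimnames = list(paste0("f", 1:n), NULL))
  b <- matrix(rnorm(3 * n), n, 3, dimnames = list(paste0("f", 1:n), NULL))
  res <- moderated_diff(a, b, paired = FALSE)
  frac <- mean(res$padj < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n)
  expect_lte(frac, 0.05 + 3 * mc_se)
})

test_that("protein classification applies the FC and p gates", {
  mk <- function(ids, fc, padj) {
    structure(data.frame(feature_id = ids, logFC = fc, t = 0, p = padj,
                         padj = padj,
                         call = "not_changing", stringsAsFactors = FALSE),
              class = c("differential_result", "data.frame"))
  }
  ids <- c("a", "b", "c")
  pres <- mk(ids, c(log2(0.6), log2(0.9), -2), c(1e-4, 1e-6, 1e-6))
  dig <- mk(ids, c(0, 0, 0), c(1, 1, 1))
  rna <- mk(ids, c(0, 0, -1), c(1, 1, 1e-5))
  cl <- classify_proteins(pres, dig, rna)
  # ratio 0.6 (log2 ~ -0.74), adj p 1e-4, no RNase change
  expect_equal(cl$class[1], "rnase_insensitive_insoluble")
  # ratio 0.9 fails the FC gate regardless of p
  expect_equal(cl$class[2], "predominantly_soluble")
  # insoluble and significantly rescued by digestion
  expect_equal(cl$class[3], "rnase_sensitive_insoluble")
  expect_true(cl$gained_solubility[3])
})

test_that("class recovery on a modest noisy simulation", {
  x <- sim_norm_profile(1500, noise_sd = 0.15, seed = 7)
  pres <- solubility_diff(x$prof, "preserved")
  dig <- solubility_diff(x$prof, "digested")
  rna <- rnase_diff(x$prof)
  cl <- classify_proteins(pres, dig, rna)
  truth <- x$sim$truth$class[match(cl$feature_id, x$sim$truth$protein_id)]
  for (k in unique(truth)) {
    expect_gt(mean(cl$class[truth == k] == k), 0.9)
  }
})

test_that("peptide-vs-protein test recovers planted shifts and signs", {
  sim <- simulate_solubility_dataset(sim_config(200, noise_sd = 0, seed = 5))
  ph <- simulate_phospho_dataset(sim, n_peptides = 300, shift_frac = 0.4,
                                 rbf_shift_frac = 0.4, noise_sd = 0, seed = 5)
  norm <- fit_apply_normalization(sim$table,
                                  select_calibration_subset(sim$table))
  prof <- compute_solubility(norm$table)
  pep_tab <- intensity_table(as.matrix(ph$table[ph$samples$sample]),
                             data.frame(feature_id = ph$table$peptide_id,
                                        protein_id = ph$table$protein_id),
                             ph$samples)
  pep_norm <- fit_apply_normalization(pep_tab,
                                      select_calibration_subset(pep_tab))
  pep_prof <- compute_solubility(pep_norm$table)
  map <- data.frame(peptide_id = ph$table$peptide_id,
                    protein_id = ph$table$protein_id)
  sol <- diff_phospho_vs_protein(pep_prof, prof, map, "solubility")
  idx <- match(sol$feature_id, ph$truth$peptide_id)
  expect_equal(sol$logFC, ph$truth$sol_shift[idx], tolerance = 1e-6)
  rna <- diff_phospho_vs_protein(pep_prof, prof, map, "rna_bound")
  expect_equal(rna$logFC, ph$truth$rbf_shift[match(rna$feature_id,
                                                   ph$truth$peptide_id)],
               tolerance = 1e-6)
  # sign convention: more-insoluble planted shift => negative logFC
  neg <- ph$truth$sol_shift[idx] < 0
  expect_true(all(sol$logFC[neg] < 0))
  # identical profiles => not_changing
  same <- ph$truth$sol_shift[idx] == 0
  expect_true(all(sol$call[same] == "not_changing"))
  # orphan peptides are excluded and reported
  map2 <- rbind(map, data.frame(peptide_id = "ghost", protein_id = "nope"))
  sol2 <- diff_phospho_vs_protein(pep_prof, prof, map2, "solubility")
  expect_identical(attr(sol2, "orphans"), "ghost")
})

test_that("planted-effect screen has high sensitivity and low FDP", {
  sim <- simulate_solubility_dataset(sim_config(800, noise_sd = 0.15, seed = 11))
  ph <- simulate_phospho_dataset(sim, n_peptides = 1500, shift_frac = 0.1,
                                 shift_size = 1, rbf_shift_frac = 0,
                                 noise_sd = 0.15, qc_fail_fraction = 0, seed = 11)
  norm <- fit_apply_normalization(sim$table,
                                  select_calibration_subset(sim$table))
  prof <- compute_solubility(norm$table)
  pep_tab <- intensity_table(as.matrix(ph$table[ph$samples$sample]),
                             data.frame(feature_id = ph$table$peptide_id,
                                        protein_id = ph$table$protein_id),
                             ph$samples)
  pep_norm <- fit_apply_normalization(pep_tab,
                                      select_calibration_subset(pep_tab))
  pep_prof <- compute_solubility(pep_norm$table)
  map <- data.frame(peptide_id = ph$table$peptide_id,
                    protein_id = ph$table$protein_id)
  res <- diff_phospho_vs_protein(pep_prof, prof, map, "solubility")
  shifted <- ph$truth$sol_shift[match(res$feature_id, ph$truth$peptide_id)] != 0
  called <- res$call != "not_changing"
  expect_gt(sum(called & shifted) / sum(shifted), 0.9)   # sensitivity
  expect_lt(sum(called & !shifted) / max(1, sum(called)), 0.1) # FDP
})
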