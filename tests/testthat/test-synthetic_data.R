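test_that("config validation rejects bad and non-finite values", {
  expect_error(sim_config(100, noise_sd = -1), "noise_sd")
  expect_error(sim_config(100, n_replicates = 1), "n_replicates")
  expect_error(sim_config(100, class_fractions = c(0.5, 0.4, 0.2)), "sum")
  expect_error(sim_config(100, insoluble_effect = NaN), "insoluble_effect")
  expect_error(sim_config(NA), "n_proteins")
  # published proportions summing to 1.005 are accepted and renormalized
  cfg <- sim_config(100, class_fractions = c(0.815, 0.055, 0.135))
  expect_equal(sum(cfg$class_fractions), 1, tolerance = 1e-12)
})

test_that("zero-noise all-soluble simulation has NP-40/SDS ratio exactly 1", {
  sim <- simulate_solubility_dataset(sim_config(
    100, noise_sd = 0, class_fractions = c(1, 0, 0), seed = 5))
  sm <- sim$table$samples
  for (ly in c("preserved", "digested")) for (r in 1:3) {
    np <- sim$table$values[, sm$sample[sm$detergent == "NP40" &
                                       sm$lysate == ly & sm$replicate == r]]
    sd_ <- sim$table$values[, sm$sample[sm$detergent == "SDS" &
                                        sm$lysate == ly & sm$replicate == r]]
    expect_equal(np / sd_, rep(1, 100), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(sim$table$values > 0))
})

test_that("planted insoluble effect appears verbatim at zero noise", {
  sim <- simulate_solubility_dataset(sim_config(
    500, noise_sd = 0, insoluble_effect = -1, rnase_rescue_effect = 1,
    seed = 2))
  sm <- sim$table$samples
  s_of <- function(ly, r) {
    np <- sm$sample[sm$detergent == "NP40" & sm$lysate == ly & sm$replicate == r]
    sd_ <- sm$sample[sm$detergent == "SDS" & sm$lysate == ly & sm$replicate == r]
    log2(sim$table$values[, np]) - log2(sim$table$values[, sd_])
  }
  ins <- sim$truth$class == "rnase_insensitive_insoluble"
  sen <- sim$truth$class == "rnase_sensitive_insoluble"
  expect_equal(unname(s_of("preserved", 1)[ins]), rep(-1, sum(ins)),
               tolerance = 1e-9)
  expect_equal(unname(s_of("digested", 2)[ins]), rep(-1, sum(ins)),
               tolerance = 1e-9)
  # RNase-sensitive proteins are rescued in the digested lysate only
  expect_equal(unname(s_of("preserved", 1)[sen]), rep(-1, sum(sen)),
               tolerance = 1e-9)
  expect_equal(unname(s_of("digested", 1)[sen]), rep(0, sum(sen)),
               tolerance = 1e-9)
})

test_that("simulation is deterministic and class draw reproduces by seed", {
  cfg <- sim_config(5000, seed = 1)
  a <- simulate_solubility_dataset(cfg)
  b <- simulate_solubility_dataset(cfg)
  expect_identical(a, b)
  # independent re-draw of the multinomial with the same derived seed
  set.seed(derive_seed(1L, "solubility"))
  cls <- sample(c("predominantly_soluble", "rnase_sensitive_insoluble",
                  "rnase_insensitive_insoluble"),
                5000, replace = TRUE, prob = cfg$class_fractions)
  expect_identical(a$truth$class, cls)
  # ground-truth bookkeeping complete: exactly one record per feature
  expect_identical(sort(a$truth$protein_id),
                   sort(a$table$features$feature_id))
  expect_false(anyDuplicated(a$truth$protein_id) > 0)
})

test_that("phosphopeptide generator plants shifts verbatim at zero noise", {
  sim <- simulate_solubility_dataset(sim_config(300, noise_sd = 0, seed = 4))
  ph <- simulate_phospho_dataset(sim, n_peptides = 400, shift_frac = 0.3,
                                 shift_size = 1, rbf_shift_frac = 0.3,
                                 noise_sd = 0, seed = 4)
  sm <- ph$samples
  s_pep <- function(ly, r) {
    np <- sm$sample[sm$detergent == "NP40" & sm$lysate == ly & sm$replicate == r]
    sd_ <- sm$sample[sm$detergent == "SDS" & sm$lysate == ly & sm$replicate == r]
    log2(ph$table[[np]]) - log2(ph$table[[sd_]])
  }
  parent <- sim$truth[match(ph$truth$protein_id, sim$truth$protein_id), ]
  for (r in 1:3) {
    # preserved-lysate solubility = parent S + planted shift, exactly
    expect_equal(s_pep("preserved", r),
                 parent$s_preserved + ph$truth$sol_shift, tolerance = 1e-9)
    # RBF relative to parent = planted rbf shift, exactly
    rbf_pep <- s_pep("preserved", r) - s_pep("digested", r)
    rbf_parent <- parent$s_preserved - parent$s_digested
    expect_equal(rbf_pep - rbf_parent, ph$truth$rbf_shift, tolerance = 1e-9)
  }
  expect_error(simulate_phospho_dataset(list(truth = NULL)), "empty proteome")
})

test_that("QC-failure fraction matches the binomial draw for the seed", {
  sim <- simulate_solubility_dataset(sim_config(300, seed = 9))
  ph <- simulate_phospho_dataset(sim, n_peptides = 1000,
                                 qc_fail_fraction = 0.3, seed = 9)
  expect_identical(ph$table$signal_to_interference < 0.5,
                   ph$truth$qc_fail)
  # regeneration with the same seed reproduces the same draw
  ph2 <- simulate_phospho_dataset(sim, n_peptides = 1000,
                                  qc_fail_fraction = 0.3, seed = 9)
  expect_identical(ph$truth$qc_fail, ph2$truth$qc_fail)
  expect_gt(mean(ph$truth$qc_fail), 0.25)
  expect_lt(mean(ph$truth$qc_fail), 0.35)
})

test_that("sequence generator respects composition and site bounds", {
  sq <- simulate_sequences(5, 100, composition = c(G = 1), seed = 1)
  expect_true(all(sq$sequences == strrep("G", 100)))
  expect_true(all(sq$sites$position >= 16 & sq$sites$position <= 85))
  expect_error(simulate_sequences(1, 20), "allow_edge")
  # 50/50 E/K draw reproduces under the same seed
  a <- simulate_sequences(1, 50, composition = c(E = 0.5, K = 0.5), seed = 7)
  b <- simulate_sequences(1, 50, composition = c(E = 0.5, K = 0.5), seed = 7)
  expect_identical(a$sequences, b$sequences)
  # boundary arithmetic: length 31, site at 16 spans the full sequence
  sq31 <- simulate_sequences(3, 31, seed = 2)
  expect_true(all(sq31$sites$position == 16))
  w <- extract_window(sq31$sequences[1], 16)
  expect_identical(w$window, unname(sq31$sequences[1]))
})

test_that("perturbation matrix plants the designed subgroup shift", {
  pm0 <- simulate_perturbation_matrix(500, 10, subgroup_shift = 0,
                                      subgroup_size = 50, seed = 1)
  sub <- pm0$subgroup == "insoluble"
  expect_lt(abs(mean(pm0$matrix[sub, 1]) - mean(pm0$matrix[, 1])), 0.5)
  # closed form z = shift / (sd / sqrt(n)) = 0.5 / (1/5) = 2.5 on average
  zs <- vapply(1:100, function(s) {
    pm <- simulate_perturbation_matrix(500, 1, subgroup_shift = 0.5,
                                       subgroup_size = 25, sd = 1, seed = s)
    site_activity(pm$matrix, pm$subgroup, "insoluble")$z
  }, numeric(1))
  expect_lt(abs(mean(zs) - 2.5), 3 * sd(zs) / sqrt(length(zs)) + 0.15)
})

test_that("image generator enforces geometry and records true K", {
  expect_error(simulate_image(c(200, 300),
    data.frame(cx = c(150, 160), cy = c(100, 100), r = c(20, 20),
               intensity = 300)), "overlap")
  expect_error(simulate_image(c(200, 300),
    data.frame(cx = 295, cy = 100, r = 20, intensity = 300)), "outside")
  img <- simulate_image(c(200, 300), data.frame(cx = 180, cy = 100, r = 25,
                                                intensity = 300),
                        nucleoplasm_intensity = 100, background = 50,
                        noise_sd = 0, seed = 1)
  expect_equal(img$truth$true_k, (300 - 50) / (100 - 50))
  img0 <- simulate_image(c(200, 300), data.frame(cx = 180, cy = 100, r = 25,
                                                 intensity = 300),
                         nucleoplasm_intensity = 100, background = 0, seed = 1)
  expect_equal(img0$truth$true_k, 3)
  # rasterized disk of radius 17 is below the 1000 px^2 gate
  img17 <- simulate_image(c(200, 300), data.frame(cx = 180, cy = 100, r = 17,
                                                  intensity = 300), seed = 1)
  area <- sum(img17$labels == 1)
  expect_lt(area, 1000)
  expect_gt(area, 850)
})
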