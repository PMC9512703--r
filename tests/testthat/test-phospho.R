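phospho_fixture <- function() {
  sam <- expand.grid(replicate = 1:3, detergent = c("NP40", "SDS"),
                     lysate = c("preserved", "digested"),
                     stringsAsFactors = FALSE)
  sam$sample <- paste(sam$detergent, sam$lysate, sam$replicate, sep = "_")
  sam <- sam[c("sample", "detergent", "lysate", "replicate")]
  mk_row <- function(id, prot, pattern, s2i, p2t, intensity, loc = 0.99) {
    row <- data.frame(peptide_id = id, protein_id = prot,
                      phospho_pattern = pattern, n_phospho = 1L,
                      localization_prob = loc,
                      signal_to_interference = s2i,
                      precursor_to_threshold = p2t,
                      stringsAsFactors = FALSE)
    for (s in sam$sample) row[[s]] <- intensity
    row
  }
  list(sam = sam, mk_row = mk_row)
}

test_that("collapsing sums modification variants and conserves intensity", {
  f <- phospho_fixture()
  raw <- rbind(f$mk_row("p1", "PROT1", "S362", 0.9, 10, 100),
               f$mk_row("p2", "PROT1", "S362", 0.8, 10, 50),
               f$mk_row("p3", "PROT1", "S400", 0.9, 10, 80))
  out <- qc_and_collapse(raw, f$sam)
  expect_equal(nrow(out), 2)
  collapsed <- out[out$phospho_pattern == "S362", ]
  expect_equal(unname(unlist(collapsed[f$sam$sample])),
               rep(150, 12))
  expect_equal(collapsed$member_ids, "p1;p2")
  # total intensity per (protein, pattern, sample) conserved
  for (s in f$sam$sample) {
    expect_equal(sum(out[[s]]), sum(raw[[s]]))
  }
})

test_that("QC gates remove failing and incompletely quantified peptides", {
  f <- phospho_fixture()
  raw <- rbind(f$mk_row("lowS2I", "P1", "S10", 0.4, 10, 100),
               f$mk_row("lowP2T", "P2", "S10", 0.9, 3, 100),
               f$mk_row("ok", "P3", "S10", 0.5, 4, 100),
               f$mk_row("hole", "P4", "S10", 0.9, 10, 100))
  raw[raw$peptide_id == "hole", f$sam$sample[1]] <- NA
  out <- qc_and_collapse(raw, f$sam)
  expect_identical(out$protein_id, "P3") # boundary values >= are kept
  expect_error(qc_and_collapse(raw[setdiff(names(raw),
                                           "signal_to_interference")],
                               f$sam), "QC columns")
})

test_that("reproducibility gate uses replicate-wise log2 solubility sd", {
  f <- phospho_fixture()
  stable <- f$mk_row("stable", "P1", "S10", 0.9, 10, 100)
  wobbly <- f$mk_row("wobbly", "P2", "S10", 0.9, 10, 100)
  # perturb NP40 preserved replicates to give solubility sd > 1
  np_cols <- f$sam$sample[f$sam$detergent == "NP40" &
                          f$sam$lysate == "preserved"]
  wobbly[np_cols] <- c(100, 800, 12.5)
  out <- qc_and_collapse(rbind(stable, wobbly), f$sam)
  # S values (0,0,0) have sd 0 < 1: retained; the wobbly one is dropped
  expect_identical(out$protein_id, "P1")
})

test_that("site categories follow the unanimity rules", {
  mk_res <- function(ids, fc, call) {
    structure(data.frame(feature_id = ids, logFC = fc, t = 0, p = 0.5,
                         padj = 0.5, call = call, stringsAsFactors = FALSE),
              class = c("differential_result", "data.frame"))
  }
  map <- data.frame(peptide_id = c("a", "b", "c", "d", "e", "f"),
                    protein_id = "P1",
                    site = c("S1", "S1", "S2", "S2", "S3", "S4"))
  sol <- mk_res(map$peptide_id,
                c(1, 1.2, 1, -1, 0, 0),
                c("up", "up", "up", "down", "not_changing", "not_changing"))
  rna <- mk_res(map$peptide_id,
                c(0, 0, 0, 0, -1, 0),
                c("not_changing", "not_changing", "not_changing",
                  "not_changing", "down", "not_changing"))
  cats <- assign_site_categories(sol, rna, map)
  get <- function(site) cats[cats$site == site, ]
  expect_equal(get("S1")$sol_category, "soluble")     # two peptides, both up
  expect_equal(get("S2")$sol_category, "ambiguous")   # significant conflict
  expect_equal(get("S3")$rna_category, "facilitates_RNA") # more RNA-bound
  expect_equal(get("S4")$category, "not_changing")
  # permutation invariance in peptide order
  perm <- sample(nrow(map))
  cats2 <- assign_site_categories(sol[perm, ], rna[perm, ], map[perm, ])
  cats2 <- cats2[order(cats2$site), ]
  expect_equal(cats[order(cats$site), c("site", "sol_category", "rna_category")],
               cats2[c("site", "sol_category", "rna_category")],
               ignore_attr = TRUE)
  # peptide absent from the map is an error
  expect_error(assign_site_categories(
    mk_res("zz", 0, "not_changing"), NULL,
    data.frame(peptide_id = "aa", protein_id = "P", site = "S1")),
    "zero sites")
})

test_that("low-localization peptides yield ambiguous-location site groups", {
  f <- phospho_fixture()
  raw <- rbind(f$mk_row("p1", "P1", "S218;T219", 0.9, 10, 100, loc = 0.5),
               f$mk_row("p2", "P2", "S100", 0.9, 10, 100, loc = 0.9))
  out <- qc_and_collapse(raw, f$sam)
  map <- peptide_site_map(out)
  expect_true("S218|T219" %in% map$site)
  expect_true("S100" %in% map$site)
  expect_equal(nrow(map[map$protein_id == "P1", ]), 1)
})

test_that("planted site categories are recovered on simulated data", {
  sim <- simulate_solubility_dataset(sim_config(500, noise_sd = 0.15, seed = 23))
  ph <- simulate_phospho_dataset(sim, n_peptides = 800, shift_frac = 0.2,
                                 rbf_shift_frac = 0.2, noise_sd = 0.15,
                                 qc_fail_fraction = 0, seed = 23)
  norm <- fit_apply_normalization(sim$table,
                                  select_calibration_subset(sim$table))
  prof <- compute_solubility(norm$table)
  collapsed <- qc_and_collapse(ph$table, ph$samples)
  pep_tab <- intensity_table(as.matrix(collapsed[ph$samples$sample]),
                             data.frame(feature_id = collapsed$peptide_id,
                                        protein_id = collapsed$protein_id),
                             ph$samples)
  pep_norm <- fit_apply_normalization(pep_tab,
                                      select_calibration_subset(pep_tab))
  pep_prof <- compute_solubility(pep_norm$table)
  map <- data.frame(peptide_id = collapsed$peptide_id,
                    protein_id = collapsed$protein_id)
  sol <- diff_phospho_vs_protein(pep_prof, prof, map, "solubility")
  rna <- diff_phospho_vs_protein(pep_prof, prof, map, "rna_bound")
  cats <- assign_site_categories(sol, rna, peptide_site_map(collapsed))
  truth_key <- paste(ph$truth$protein_id, ph$truth$phospho_pattern, sep = "@")
  idx <- match(cats$peptide_ids, truth_key)
  ok <- !is.na(idx)
  agree <- cats$sol_category[ok] == ph$truth$intended_sol_category[idx[ok]] &
    cats$rna_category[ok] == ph$truth$intended_rna_category[idx[ok]]
  expect_gt(mean(agree), 0.9)
})

test_that("monophospho representation test flags planted depletion", {
  is_mono <- rep(c(TRUE, FALSE), each = 100)
  in_cat <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(40, 60)))
  res <- monophospho_test(is_mono, in_cat)
  expect_lt(res$odds_ratio, 1)
  expect_lt(res$p, 0.01)
})
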