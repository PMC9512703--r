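# End-to-end orchestration and the command-line entry point.

.default_pipeline_config <- function() {
  list(
    n_proteins = 2000, n_replicates = 3,
    class_fractions = c(0.815, 0.055, 0.135),
    insoluble_effect = -1, rnase_rescue_effect = 1, noise_sd = 0.15,
    n_peptides = 2000, shift_frac = 0.1, shift_size = 1,
    rbf_shift_frac = 0.1, rbf_shift_size = 1, qc_fail_fraction = 0.1,
    # thresholds; the field defaults are recorded here and any override
    # is reported next to them in the run log
    fc_threshold = 0.5, p_threshold = 0.01,
    s2i_min = 0.5, p2t_min = 4, sd_max = 1,
    calibration_low = 0.8, calibration_high = 1.2,
    normalization = "glog",
    half_width = 15, phospho_charge = -2,
    min_area_px2 = 1000, intensity_floor = 20,
    seed = 1
  )
}

# small stable polynomial hash of a deparsed object, for run logging
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full simulated analysis pipeline
#'
#' Executes simulate -> normalize -> solubility statistics -> protein
#' classification -> phosphopeptide QC/collapse -> peptide-vs-protein
#' differential tests -> site categorization, and summarizes recovery
#' against the planted ground truth. Deterministic given `config$seed`.
#'
#' @param config named list; see the package defaults (any subset may be
#'   supplied, the rest is filled in). Paper-default thresholds are
#'   always recorded in the summary alongside overrides.
#' @param out optional output directory for stage TSVs and the JSON
#'   summary.
#' @return list with all stage results and `summary` (class counts,
#'   category counts, confusion matrices vs truth, config hash, seed).
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  defaults <- .default_pipeline_config()

  sim <- simulate_solubility_dataset(sim_config(
    n_proteins = cfg$n_proteins, n_replicates = cfg$n_replicates,
    class_fractions = cfg$class_fractions,
    insoluble_effect = cfg$insoluble_effect,
    rnase_rescue_effect = cfg$rnase_rescue_effect,
    noise_sd = cfg$noise_sd, seed = cfg$seed))

  calib <- select_calibration_subset(sim$table, cfg$calibration_low,
                                     cfg$calibration_high)
  norm <- fit_apply_normalization(sim$table, calib,
                                  method = cfg$normalization)
  prof <- compute_solubility(norm$table)
  pres <- solubility_diff(prof, "preserved", cfg$fc_threshold, cfg$p_threshold)
  dig <- solubility_diff(prof, "digested", cfg$fc_threshold, cfg$p_threshold)
  rna <- rnase_diff(prof, cfg$fc_threshold, cfg$p_threshold)
  classes <- classify_proteins(pres, dig, rna, cfg$fc_threshold, cfg$p_threshold)

  truth_class <- sim$truth$class[match(classes$feature_id, sim$truth$protein_id)]
  class_confusion <- table(truth = truth_class, called = classes$class)

  phos <- simulate_phospho_dataset(
    sim, n_peptides = cfg$n_peptides, shift_frac = cfg$shift_frac,
    shift_size = cfg$shift_size, rbf_shift_frac = cfg$rbf_shift_frac,
    rbf_shift_size = cfg$rbf_shift_size,
    qc_fail_fraction = cfg$qc_fail_fraction, noise_sd = cfg$noise_sd,
    seed = cfg$seed)
  collapsed <- qc_and_collapse(phos$table, phos$samples,
                               cfg$s2i_min, cfg$p2t_min, cfg$sd_max)
  pep_raw <- intensity_table(as.matrix(collapsed[phos$samples$sample]),
                             collapsed[c("peptide_id", "protein_id")] |>
                               stats::setNames(c("feature_id", "protein_id")),
                             phos$samples)
  pep_calib <- select_calibration_subset(pep_raw, cfg$calibration_low,
                                         cfg$calibration_high)
  pep_norm <- fit_apply_normalization(pep_raw, pep_calib,
                                      method = cfg$normalization)
  pep_prof <- compute_solubility(pep_norm$table)
  pep_map <- data.frame(peptide_id = collapsed$peptide_id,
                        protein_id = collapsed$protein_id,
                        stringsAsFactors = FALSE)
  sol_res <- diff_phospho_vs_protein(pep_prof, prof, pep_map, "solubility",
                                     cfg$fc_threshold, cfg$p_threshold)
  rna_res <- diff_phospho_vs_protein(pep_prof, prof, pep_map, "rna_bound",
                                     cfg$fc_threshold, cfg$p_threshold)
  site_map <- peptide_site_map(collapsed)
  categories <- assign_site_categories(sol_res, rna_res, site_map)

  # collapsed ids are protein@pattern, so single-peptide sites map back to
  # the planted truth by key; multi-peptide sites (no planted analog) drop out
  truth_key <- paste(phos$truth$protein_id, phos$truth$phospho_pattern, sep = "@")
  idx <- match(categories$peptide_ids, truth_key)
  cat_confusion_sol <- table(truth = phos$truth$intended_sol_category[idx],
                             called = categories$sol_category)
  cat_confusion_rna <- table(truth = phos$truth$intended_rna_category[idx],
                             called = categories$rna_category)

  overrides <- config[intersect(names(config), names(defaults))]
  summary <- list(
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("phosol")),
    thresholds = cfg[c("fc_threshold", "p_threshold", "s2i_min", "p2t_min",
                       "sd_max", "min_area_px2", "intensity_floor",
                       "half_width", "phospho_charge")],
    threshold_defaults = defaults[c("fc_threshold", "p_threshold", "s2i_min",
                                    "p2t_min", "sd_max", "min_area_px2",
                                    "intensity_floor", "half_width",
                                    "phospho_charge")],
    overrides = overrides,
    n_proteins = nrow(sim$truth),
    n_peptides_collapsed = nrow(collapsed),
    class_counts = as.list(table(classes$class)),
    class_confusion = as.data.frame(class_confusion),
    category_counts = as.list(table(categories$category)),
    category_confusion_solubility = as.data.frame(cat_confusion_sol),
    category_confusion_rna = as.data.frame(cat_confusion_rna)
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_intensity_table(sim$table, file.path(out, "proteins_raw"))
    write_intensity_table(norm$table, file.path(out, "proteins_normalized"))
    write_tsv_df(classes, file.path(out, "protein_classes.tsv"))
    write_tsv_df(as.data.frame(sol_res), file.path(out, "phospho_solubility_diff.tsv"))
    write_tsv_df(as.data.frame(rna_res), file.path(out, "phospho_rna_diff.tsv"))
    write_tsv_df(categories, file.path(out, "site_categories.tsv"))
    write_json_report(summary, file.path(out, "summary.json"))
  }

  list(proteome = sim, normalized = norm, profile = prof,
       preserved_diff = pres, digested_diff = dig, rnase = rna,
       classes = classes, phospho = phos, collapsed = collapsed,
       sol_results = sol_res, rna_results = rna_res,
       categories = categories, summary = summary)
}

.cli_args_to_list <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        out[[key]] <- TRUE; i <- i + 1L
      } else {
        out[[key]] <- args[i + 1]; i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate solubility|phospho|sequences|perturbations|image`,
#' `normalize`, `seqfeat`, `enrich`, `imaging partition|cv`, `run`.
#' Common flags: `--config FILE` (flat key: value), `--seed INT`,
#' `--out DIR`. Installed as the executable script `inst/cli/phosol`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the result of the dispatched operation.
#' @export
phosol_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- .cli_args_to_list(args)
  pos <- opts$positional
  if (!length(pos)) stop("usage: phosol <simulate|normalize|seqfeat|enrich|imaging|run> ...")
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else list()
  seed <- as.integer(if (!is.null(opts$seed)) opts$seed else cfg$seed %||% 1L)
  out <- opts$out %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  res <- switch(pos[1],
    simulate = {
      kind <- pos[2] %||% "solubility"
      switch(kind,
        solubility = {
          sim <- simulate_solubility_dataset(sim_config(
            n_proteins = cfg$n_proteins %||% 2000, seed = seed,
            noise_sd = cfg$noise_sd %||% 0.15))
          write_intensity_table(sim$table, file.path(out, "proteins_raw"))
          write_tsv_df(sim$truth, file.path(out, "proteins_truth.tsv"))
          sim
        },
        phospho = {
          sim <- simulate_solubility_dataset(sim_config(
            n_proteins = cfg$n_proteins %||% 2000, seed = seed,
            noise_sd = cfg$noise_sd %||% 0.15))
          ph <- simulate_phospho_dataset(sim,
            n_peptides = cfg$n_peptides %||% 2000, seed = seed)
          write_tsv_df(ph$table, file.path(out, "phosphopeptides_raw.tsv"))
          write_tsv_df(ph$truth, file.path(out, "phosphopeptides_truth.tsv"))
          ph
        },
        sequences = {
          sq <- simulate_sequences(cfg$n %||% 100, cfg$length %||% 200,
                                   seed = seed)
          write_fasta(sq$sequences, file.path(out, "sequences.fasta"))
          write_tsv_df(sq$sites, file.path(out, "sites.tsv"))
          sq
        },
        perturbations = {
          pm <- simulate_perturbation_matrix(
            cfg$n_sites %||% 500, cfg$n_conditions %||% 20,
            subgroup_shift = cfg$subgroup_shift %||% 0, seed = seed)
          write_tsv_df(as.data.frame(pm$matrix), file.path(out, "perturbations.tsv"))
          pm
        },
        image = {
          img <- simulate_image(
            shape = c(cfg$height %||% 300, cfg$width %||% 400),
            nucleoli = data.frame(cx = 220, cy = 150, r = 40, intensity = 300),
            seed = seed)
          write_image_tsv(img$intensity, file.path(out, "intensity.tsv"))
          write_image_tsv(img$labels, file.path(out, "labels.tsv"))
          write_tsv_df(img$truth, file.path(out, "image_truth.tsv"))
          img
        },
        stop("unknown simulate kind: ", kind))
    },
    normalize = {
      tab <- read_intensity_table(sub("\\.tsv$", "", opts$table))
      calib <- select_calibration_subset(tab,
        as.numeric(opts$low %||% 0.8), as.numeric(opts$high %||% 1.2))
      norm <- fit_apply_normalization(tab, calib,
                                      method = opts$method %||% "glog")
      write_intensity_table(norm$table, file.path(out, "normalized"))
      write_json_report(norm$model[c("scales", "glog_c", "method", "trend")],
                        file.path(out, "normalization_model.json"))
      norm
    },
    seqfeat = {
      seqs <- read_fasta(opts$fasta)
      sites <- read_tsv_df(opts$sites)
      props <- site_window_properties(seqs, sites,
        half_width = as.integer(opts$halfwidth %||% 15),
        phospho_charge = as.numeric(opts[["phospho-charge"]] %||% -2))
      write_tsv_df(props, file.path(out, "window_properties.tsv"))
      props
    },
    enrich = {
      sets <- read_gmt(opts$gmt)
      fg <- read_tsv_df(opts$foreground)[[1]]
      bg <- read_tsv_df(opts$background)[[1]]
      ora <- hypergeometric_ora(sets, fg, bg)
      write_tsv_df(ora, file.path(out, "ora.tsv"))
      ora
    },
    imaging = {
      kind <- pos[2] %||% "partition"
      intensity <- read_image_tsv(opts$intensity)
      if (kind == "partition") {
        labels <- read_image_tsv(opts$labels)
        roi <- as.numeric(strsplit(opts[["bg-roi"]] %||% "5,5,90,90", ",")[[1]])
        img <- list(intensity = intensity, labels = labels,
                    background_roi = roi,
                    pixel_size_nm = as.numeric(opts[["pixel-size"]] %||% 424 / 6))
        pr <- measure_partition_coefficients(img,
          min_area_px2 = as.numeric(opts[["min-area"]] %||% 1000),
          intensity_floor = as.numeric(opts$floor %||% 20))
        write_tsv_df(pr, file.path(out, "partition.tsv"))
        pr
      } else {
        mask <- read_image_tsv(opts$mask) > 0
        cv <- nuclear_cv(intensity, mask,
                         background = as.numeric(opts$background %||% 0))
        write_json_report(cv, file.path(out, "nuclear_cv.json"))
        cv
      }
    },
    run = {
      cfg$seed <- seed
      run_pipeline(cfg, out = out)
    },
    stop("unknown subcommand: ", pos[1]))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
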