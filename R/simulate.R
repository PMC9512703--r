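# Synthetic-data generators: every input the pipeline consumes, with
# recorded ground truth, so all downstream stages are testable without
# external downloads.

#' Simulation configuration for the solubility proteome generator
#'
#' Describes the stated world the generator draws from: a majority of
#' predominantly soluble proteins whose NP-40 and SDS abundances agree,
#' and minority classes that keep an insoluble subpool which is either
#' rescued by RNA digestion (RNase sensitive) or not (RNase insensitive).
#'
#' @param n_proteins number of proteins to simulate.
#' @param n_replicates biological replicates per condition (default 3).
#' @param class_fractions length-3 numeric, fractions of
#'   (predominantly_soluble, rnase_sensitive_insoluble,
#'   rnase_insensitive_insoluble); must be non-negative and sum to 1.
#'   Default `c(0.815, 0.055, 0.135)`, the observed proteome proportions.
#' @param insoluble_effect log2 depletion of NP-40 vs SDS for proteins with
#'   an insoluble subpool (negative, log2 units; default -1).
#' @param rnase_rescue_effect log2 solubility gain upon RNA digestion for
#'   RNase-sensitive proteins (default +1, cancelling the default effect).
#' @param noise_sd standard deviation of additive Gaussian noise on log2
#'   intensities (= lognormal multiplicative noise on the raw scale);
#'   default 0.15 log2 units, a calibration choice.
#' @param baseline_log_intensity_range interval (log2 units) from which
#'   per-protein baseline intensities are drawn log-uniformly.
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_proteins,
                       n_replicates = 3L,
                       class_fractions = c(0.815, 0.055, 0.135),
                       insoluble_effect = -1,
                       rnase_rescue_effect = 1,
                       noise_sd = 0.15,
                       baseline_log_intensity_range = c(14, 22),
                       seed = 1L) {
  .check_finite(n_proteins, "n_proteins")
  .check_finite(n_replicates, "n_replicates")
  .check_finite(class_fractions, "class_fractions")
  .check_finite(insoluble_effect, "insoluble_effect")
  .check_finite(rnase_rescue_effect, "rnase_rescue_effect")
  .check_finite(noise_sd, "noise_sd")
  .check_finite(baseline_log_intensity_range, "baseline_log_intensity_range")
  .check_finite(seed, "seed")
  if (length(class_fractions) != 3L || any(class_fractions < 0))
    stop("class_fractions must be 3 non-negative values")
  # the published proportions (0.815, 0.055, 0.135) sum to 1.005 as
  # printed; inputs within 1% of 1 are renormalized exactly, anything
  # further off is a user error
  if (abs(sum(class_fractions) - 1) > 0.01)
    stop("class_fractions must sum to 1 (within 1%)")
  class_fractions <- class_fractions / sum(class_fractions)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (diff(baseline_log_intensity_range) < 0)
    stop("baseline_log_intensity_range must be an increasing interval")
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    class_fractions = class_fractions,
    insoluble_effect = insoluble_effect,
    rnase_rescue_effect = rnase_rescue_effect,
    noise_sd = noise_sd,
    baseline_log_intensity_range = baseline_log_intensity_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct an intensity table
#'
#' The substrate of all differential statistics: a features x samples
#' matrix of non-negative reporter intensities plus complete sample
#' metadata (detergent, lysate, replicate) and per-feature metadata.
#'
#' @param values numeric matrix, features x samples, all values >= 0.
#' @param features data.frame with at least `feature_id`; protein tables
#'   also carry `protein_id` and `unique_peptide_count`.
#' @param samples data.frame with columns `sample`, `detergent`
#'   (`"NP40"`/`"SDS"`), `lysate` (`"preserved"`/`"digested"`),
#'   `replicate`.
#' @param log2 logical; whether `values` are on the log2 scale already.
#' @return object of class `intensity_table`.
#' @export
intensity_table <- function(values, features, samples, log2 = FALSE) {
  values <- as.matrix(values)
  if (!log2 && any(values < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (nrow(features) != nrow(values)) stop("features/values row mismatch")
  if (nrow(samples) != ncol(values)) stop("samples/values column mismatch")
  need <- c("sample", "detergent", "lysate", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample metadata must contain: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample)) stop("duplicate sample names")
  if (anyNA(samples[need])) stop("sample metadata incomplete")
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample
  structure(list(values = values, features = features, samples = samples,
                 log2 = isTRUE(log2)),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), if (x$log2) "log2" else "raw"))
  invisible(x)
}

.sample_sheet <- function(n_replicates) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      detergent = c("NP40", "SDS"),
                      lysate = c("preserved", "digested"),
                      stringsAsFactors = FALSE)
  grid$sample <- paste(grid$detergent, grid$lysate, grid$replicate, sep = "_")
  grid[c("sample", "detergent", "lysate", "replicate")]
}

#' Simulate a solubility proteome dataset
#'
#' Generates reporter intensities for the 2x2 design (NP-40/SDS x
#' RNA-preserved/RNA-digested) with `n_replicates` replicates each. SDS
#' channels carry baseline intensity times noise; NP-40 channels are
#' attenuated by `insoluble_effect` for insoluble-class proteins, and that
#' attenuation is relieved by `rnase_rescue_effect` in digested samples
#' for the RNase-sensitive class. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `table` (an [intensity_table()]) and `truth`
#'   (data.frame: `protein_id`, `class`, `s_preserved`, `s_digested` —
#'   the planted noise-free log2 NP-40/SDS per lysate).
#' @export
simulate_solubility_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "solubility"))
  n <- config$n_proteins
  cls <- sample(c("predominantly_soluble", "rnase_sensitive_insoluble",
                  "rnase_insensitive_insoluble"),
                n, replace = TRUE, prob = config$class_fractions)
  base <- stats::runif(n, config$baseline_log_intensity_range[1],
                       config$baseline_log_intensity_range[2])
  eff_pres <- ifelse(cls == "predominantly_soluble", 0, config$insoluble_effect)
  eff_dig <- eff_pres +
    ifelse(cls == "rnase_sensitive_insoluble", config$rnase_rescue_effect, 0)

  sam <- .sample_sheet(config$n_replicates)
  nlog <- matrix(0, n, nrow(sam))
  for (j in seq_len(nrow(sam))) {
    eff <- if (sam$detergent[j] == "SDS") 0 else
      if (sam$lysate[j] == "preserved") eff_pres else eff_dig
    nlog[, j] <- base + eff + stats::rnorm(n, 0, config$noise_sd)
  }
  feats <- data.frame(feature_id = sprintf("P%05d", seq_len(n)),
                      protein_id = sprintf("P%05d", seq_len(n)),
                      unique_peptide_count = 2L + stats::rpois(n, 4),
                      stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = feats$protein_id, class = cls,
                      s_preserved = eff_pres, s_digested = eff_dig,
                      baseline_log2 = base, stringsAsFactors = FALSE)
  list(table = intensity_table(2^nlog, feats, sam), truth = truth)
}

#' Simulate a phosphopeptide dataset on top of a simulated proteome
#'
#' Each phosphopeptide references an existing protein, carries a phospho
#' pattern (ordered residue positions), per-sample intensities consistent
#' with the parent protein's solubility plus a planted shift, and QC
#' fields drawn so a configurable fraction fails quality control.
#' Substoichiometric abundance is emulated by a log-uniform occupancy
#' factor. Planted effects: `sol_shift` moves the peptide's preserved-lysate
#' solubility relative to its parent; `rbf_shift` moves its RNA-bound
#' fraction (negative = more RNA-bound).
#'
#' @param proteome result of [simulate_solubility_dataset()].
#' @param n_peptides number of collapsed-pattern phosphopeptides.
#' @param shift_frac fraction of peptides with a planted solubility shift.
#' @param shift_size magnitude (log2) of the solubility shift; sign random.
#' @param rbf_shift_frac fraction with a planted RNA-bound shift (disjoint
#'   axis; a peptide may carry both).
#' @param rbf_shift_size magnitude (log2) of the RNA-bound shift.
#' @param qc_fail_fraction fraction drawn with signal-to-interference
#'   below 0.5 (QC failures).
#' @param noise_sd log2 noise sd for peptide intensities.
#' @param substoich_range occupancy range (fraction of parent protein
#'   signal), log-uniform.
#' @param variant_fraction fraction of peptides additionally emitted as two
#'   pre-collapse modification variants whose intensities sum to the
#'   collapsed row (exercises pattern collapsing).
#' @param sites_per_peptide maximum number of phosphosites per peptide
#'   (1 gives unambiguous site bookkeeping).
#' @param seed integer seed.
#' @return list with `table` (a data.frame phosphopeptide table: ids,
#'   pattern, localization probability, QC fields, one intensity column per
#'   sample) and `truth` (planted shifts and intended categories per
#'   peptide).
#' @export
simulate_phospho_dataset <- function(proteome,
                                     n_peptides = 3000L,
                                     shift_frac = 0.1,
                                     shift_size = 1,
                                     rbf_shift_frac = 0.1,
                                     rbf_shift_size = 1,
                                     qc_fail_fraction = 0.1,
                                     noise_sd = NULL,
                                     substoich_range = c(0.01, 0.2),
                                     variant_fraction = 0,
                                     sites_per_peptide = 1L,
                                     seed = 1L) {
  truth_prot <- proteome$truth
  if (is.null(truth_prot) || nrow(truth_prot) == 0L) stop("empty proteome")
  if (is.null(noise_sd)) noise_sd <- 0.15
  set.seed(derive_seed(seed, "phospho"))

  parent_idx <- sample(nrow(truth_prot), n_peptides, replace = TRUE)
  parent <- truth_prot[parent_idx, ]
  nsite <- sample(seq_len(max(1L, sites_per_peptide)), n_peptides, replace = TRUE)
  pattern <- vapply(seq_len(n_peptides), function(i) {
    pos <- sort(sample(20:480, nsite[i]))
    res <- sample(c("S", "T", "Y"), nsite[i], replace = TRUE, prob = c(.8, .15, .05))
    paste0(res, pos, collapse = ";")
  }, character(1))

  sol_shift <- ifelse(stats::runif(n_peptides) < shift_frac,
                      sample(c(-1, 1), n_peptides, replace = TRUE) * shift_size, 0)
  rbf_shift <- ifelse(stats::runif(n_peptides) < rbf_shift_frac,
                      sample(c(-1, 1), n_peptides, replace = TRUE) * rbf_shift_size, 0)

  occ <- 2^stats::runif(n_peptides, log2(substoich_range[1]), log2(substoich_range[2]))
  base_pep <- parent$baseline_log2 + log2(occ)
  # peptide planted solubility per lysate (see docs): preserved gets
  # sol_shift + rbf_shift-free parent S; digested subtracts rbf_shift so
  # RBF_pep - RBF_parent = rbf_shift.
  s_pres <- parent$s_preserved + sol_shift
  s_dig <- parent$s_digested + sol_shift - rbf_shift

  sam <- .sample_sheet(max(proteome$table$samples$replicate))
  vals <- matrix(0, n_peptides, nrow(sam))
  for (j in seq_len(nrow(sam))) {
    eff <- if (sam$detergent[j] == "SDS") 0 else
      if (sam$lysate[j] == "preserved") s_pres else s_dig
    vals[, j] <- 2^(base_pep + eff + stats::rnorm(n_peptides, 0, noise_sd))
  }
  colnames(vals) <- sam$sample

  fails <- stats::runif(n_peptides) < qc_fail_fraction
  s2i <- ifelse(fails, stats::runif(n_peptides, 0.05, 0.4999),
                stats::runif(n_peptides, 0.5, 1))
  p2t <- stats::runif(n_peptides, 4, 30)

  tab <- data.frame(
    peptide_id = sprintf("pep%05d", seq_len(n_peptides)),
    protein_id = parent$protein_id,
    phospho_pattern = pattern,
    n_phospho = nsite,
    localization_prob = stats::runif(n_peptides, 0.75, 1),
    signal_to_interference = s2i,
    precursor_to_threshold = p2t,
    variant = "v1",
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(vals))

  if (variant_fraction > 0) {
    pick <- which(stats::runif(n_peptides) < variant_fraction)
    if (length(pick)) {
      split_frac <- stats::runif(length(pick), 0.2, 0.8)
      extra <- tab[pick, ]
      extra$variant <- "v2_ox"
      extra[, sam$sample] <- tab[pick, sam$sample] * (1 - split_frac)
      tab[pick, sam$sample] <- tab[pick, sam$sample] * split_frac
      extra$peptide_id <- paste0(extra$peptide_id, "_ox")
      tab <- rbind(tab, extra)
    }
  }

  truth <- data.frame(
    peptide_id = sprintf("pep%05d", seq_len(n_peptides)),
    protein_id = parent$protein_id,
    phospho_pattern = pattern,
    sol_shift = sol_shift,
    rbf_shift = rbf_shift,
    qc_fail = fails,
    intended_sol_category = ifelse(sol_shift > 0, "soluble",
                            ifelse(sol_shift < 0, "insoluble", "not_changing")),
    intended_rna_category = ifelse(rbf_shift < 0, "facilitates_RNA",
                            ifelse(rbf_shift > 0, "represses_RNA", "not_changing")),
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth, samples = sam)
}

#' Simulate protein sequences with annotated phosphosite positions
#'
#' Sequences over the 20-residue alphabet with a controllable residue
#' composition; one annotated site per sequence, uniform in
#' `[half_width + 1, length - half_width]` unless edge cases are allowed.
#'
#' @param n number of sequences.
#' @param length sequence length (>= 31 unless `allow_edge_sites`).
#' @param composition named numeric vector of residue frequencies over
#'   (a subset of) the 20 amino acids; must sum to 1.
#' @param allow_edge_sites if TRUE, site positions are uniform over the
#'   whole sequence (exercising window clipping).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector) and `sites`
#'   (data.frame: `protein_id`, `position`, `residue`).
#' @export
simulate_sequences <- function(n, length, composition = NULL,
                               allow_edge_sites = FALSE, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(composition)) composition <- stats::setNames(rep(1 / 20, 20), aa)
  if (!all(names(composition) %in% aa)) stop("unknown residue in composition")
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (length < 31 && !allow_edge_sites)
    stop("length < 31 requires allow_edge_sites = TRUE")
  set.seed(derive_seed(seed, "sequences"))
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(names(composition), length, replace = TRUE, prob = composition),
           collapse = ""), character(1))
  names(seqs) <- sprintf("SIM%04d", seq_len(n))
  lo <- if (allow_edge_sites) 1L else 16L
  hi <- if (allow_edge_sites) length else length - 15L
  pos <- if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
  sites <- data.frame(protein_id = names(seqs), position = pos,
                      residue = substring(seqs, pos, pos),
                      stringsAsFactors = FALSE)
  list(sequences = seqs, sites = sites)
}

#' Simulate a phosphosite-by-condition perturbation fold-change matrix
#'
#' Background fold changes are Gaussian; a designated subgroup of sites has
#' its mean shifted by `subgroup_shift` in the designated conditions.
#'
#' @param n_sites,n_conditions matrix dimensions.
#' @param subgroup_shift log2 shift planted in the subgroup.
#' @param subgroup_size number of sites in the subgroup (first rows).
#' @param shifted_conditions integer indices of conditions carrying the
#'   shift (default: all).
#' @param sd background fold-change standard deviation.
#' @param seed integer seed.
#' @return list with `matrix` (sites x conditions), `subgroup` (character
#'   labels per site: `"insoluble"` for the subgroup, `"not_changing"`
#'   otherwise) and `shifted_conditions`.
#' @export
simulate_perturbation_matrix <- function(n_sites, n_conditions,
                                         subgroup_shift = 0,
                                         subgroup_size = max(5L, round(n_sites / 10)),
                                         shifted_conditions = seq_len(n_conditions),
                                         sd = 1, seed = 1L) {
  if (n_sites < subgroup_size) stop("n_sites must be >= subgroup_size")
  set.seed(derive_seed(seed, "perturbations"))
  m <- matrix(stats::rnorm(n_sites * n_conditions, 0, sd), n_sites, n_conditions,
              dimnames = list(sprintf("site%04d", seq_len(n_sites)),
                              sprintf("cond%03d", seq_len(n_conditions))))
  m[seq_len(subgroup_size), shifted_conditions] <-
    m[seq_len(subgroup_size), shifted_conditions] + subgroup_shift
  subgroup <- rep("not_changing", n_sites)
  subgroup[seq_len(subgroup_size)] <- "insoluble"
  list(matrix = m, subgroup = subgroup, shifted_conditions = shifted_conditions)
}

#' Simulate a nucleolus image with a label mask and known partition truth
#'
#' Builds an intensity image: a background field, a rectangular nucleus
#' region filled with nucleoplasm intensity, and disk-shaped nucleoli at
#' given centers/radii/intensities; Gaussian pixel noise on top. The true
#' partition coefficient per nucleolus is
#' `(nucleolus - background) / (nucleoplasm - background)`.
#'
#' Pixel coordinates are 0-based `(x, y)` with `x` the column index.
#'
#' @param shape `c(height, width)` in pixels.
#' @param nucleoli data.frame with columns `cx`, `cy`, `r`, `intensity`.
#' @param nucleoplasm_intensity,background intensity levels (a.u.).
#' @param noise_sd Gaussian pixel noise sd.
#' @param pixel_size_nm physical pixel size.
#' @param nucleus rectangle `c(x, y, w, h)` (0-based) for the nucleus;
#'   default leaves a 100-px-wide left strip for the background ROI.
#' @param seed integer seed.
#' @return list: `intensity` (matrix), `labels` (integer matrix, 0 =
#'   outside), `nucleus_mask` (logical matrix), `background_roi`
#'   (`c(x, y, w, h)`), `pixel_size_nm`, `truth` (data.frame with `label`,
#'   `true_k`, `background`).
#' @export
simulate_image <- function(shape, nucleoli,
                           nucleoplasm_intensity = 100,
                           background = 10,
                           noise_sd = 0,
                           pixel_size_nm = 424 / 6,
                           nucleus = NULL,
                           seed = 1L) {
  h <- shape[1]; w <- shape[2]
  nucleoli <- as.data.frame(nucleoli)
  stopifnot(all(c("cx", "cy", "r", "intensity") %in% names(nucleoli)))
  if (is.null(nucleus)) nucleus <- c(100, 5, w - 105, h - 10)
  nx <- nucleus[1]; ny <- nucleus[2]; nw <- nucleus[3]; nh <- nucleus[4]
  # disjointness and containment checks
  k <- nrow(nucleoli)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- sqrt((nucleoli$cx[i] - nucleoli$cx[j])^2 +
                (nucleoli$cy[i] - nucleoli$cy[j])^2)
      if (d <= nucleoli$r[i] + nucleoli$r[j])
        stop("overlapping nucleoli: ", i, " and ", j)
    }
  }
  if (any(nucleoli$cx - nucleoli$r < nx | nucleoli$cx + nucleoli$r > nx + nw - 1 |
          nucleoli$cy - nucleoli$r < ny | nucleoli$cy + nucleoli$r > ny + nh - 1))
    stop("nucleolus outside the nucleus region / image frame")

  set.seed(derive_seed(seed, "image"))
  xs <- matrix(rep(0:(w - 1), each = h), h, w)  # column = x
  ys <- matrix(rep(0:(h - 1), times = w), h, w) # row = y
  img <- matrix(background, h, w)
  nucleus_mask <- xs >= nx & xs < nx + nw & ys >= ny & ys < ny + nh
  img[nucleus_mask] <- nucleoplasm_intensity
  labels <- matrix(0L, h, w)
  for (i in seq_len(k)) {
    inside <- (xs - nucleoli$cx[i])^2 + (ys - nucleoli$cy[i])^2 <= nucleoli$r[i]^2
    img[inside] <- nucleoli$intensity[i]
    labels[inside] <- i
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  roi_side <- min(90, nx - 10, h - 10)
  truth <- data.frame(label = seq_len(k),
                      true_k = (nucleoli$intensity - background) /
                               (nucleoplasm_intensity - background),
                      background = background)
  list(intensity = img, labels = labels, nucleus_mask = nucleus_mask,
       background_roi = c(5, 5, roi_side, roi_side),
       pixel_size_nm = pixel_size_nm, truth = truth)
}
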