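# Phosphopeptide preprocessing and rule-based phosphosite categorization.

#' Quality-control filter and phospho-pattern collapsing
#'
#' Removes rows failing signal-to-interference / precursor-to-threshold
#' gates or not quantified in all replicates; collapses the survivors by
#' (protein, phospho pattern), summing intensities across modification
#' variants (labeling / oxidation / acetylation differences are ignored);
#' finally removes patterns whose replicate-wise log2 solubility standard
#' deviation reaches `sd_max` in any lysate.
#'
#' @param raw phosphopeptide data.frame with columns `peptide_id`,
#'   `protein_id`, `phospho_pattern`, `n_phospho`, `localization_prob`,
#'   `signal_to_interference`, `precursor_to_threshold`, plus one
#'   intensity column per sample in `samples$sample`.
#' @param samples sample sheet (`sample`, `detergent`, `lysate`,
#'   `replicate`).
#' @param s2i_min,p2t_min,sd_max gates; defaults 0.5, 4 and 1 (log2 units).
#' @param sd_on quantity the reproducibility gate is applied to:
#'   `"solubility"` (replicate-wise log2 NP-40/SDS; default) or
#'   `"intensity"` (log2 intensity across replicates within channel).
#' @return collapsed data.frame; one row per (protein, pattern), new
#'   `peptide_id` of the form `protein@pattern`, `member_ids` listing the
#'   collapsed variants.
#' @export
qc_and_collapse <- function(raw, samples, s2i_min = 0.5, p2t_min = 4,
                            sd_max = 1, sd_on = c("solubility", "intensity")) {
  sd_on <- match.arg(sd_on)
  need <- c("signal_to_interference", "precursor_to_threshold",
            "protein_id", "phospho_pattern")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing QC columns: ", paste(miss, collapse = ", "))
  scol <- samples$sample
  if (!all(scol %in% names(raw))) stop("missing intensity columns")

  keep <- raw$signal_to_interference >= s2i_min &
    raw$precursor_to_threshold >= p2t_min
  quant <- apply(raw[scol], 1, function(v) all(is.finite(v) & v > 0))
  raw <- raw[keep & quant, , drop = FALSE]

  key <- paste(raw$protein_id, raw$phospho_pattern, sep = "@")
  agg <- rowsum(as.matrix(raw[scol]), group = key, reorder = TRUE)
  first <- raw[!duplicated(key), , drop = FALSE]
  first <- first[match(rownames(agg), paste(first$protein_id,
                                            first$phospho_pattern, sep = "@")), ]
  out <- data.frame(
    peptide_id = rownames(agg),
    protein_id = first$protein_id,
    phospho_pattern = first$phospho_pattern,
    n_phospho = first$n_phospho,
    localization_prob = vapply(split(raw$localization_prob, key)[rownames(agg)],
                               max, numeric(1)),
    member_ids = vapply(split(raw$peptide_id, key)[rownames(agg)],
                        paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- cbind(out, as.data.frame(agg, row.names = NULL))

  # reproducibility gate
  rep_sd <- rep(0, nrow(out))
  for (ly in unique(samples$lysate)) {
    reps <- sort(unique(samples$replicate[samples$lysate == ly]))
    if (sd_on == "solubility") {
      s <- matrix(unlist(lapply(reps, function(r) {
        np <- samples$sample[samples$detergent == "NP40" &
                             samples$lysate == ly & samples$replicate == r]
        sd_ <- samples$sample[samples$detergent == "SDS" &
                              samples$lysate == ly & samples$replicate == r]
        log2(out[[np]]) - log2(out[[sd_]])
      })), nrow = nrow(out))
      rep_sd <- pmax(rep_sd, apply(s, 1, stats::sd))
    } else {
      for (det in unique(samples$detergent)) {
        cols <- samples$sample[samples$detergent == det & samples$lysate == ly]
        rep_sd <- pmax(rep_sd, apply(log2(as.matrix(out[cols])), 1, stats::sd))
      }
    }
  }
  out[rep_sd < sd_max, , drop = FALSE]
}

#' Expand collapsed phosphopeptides into a peptide-to-site map
#'
#' Patterns are `;`-separated residue+position tokens (e.g. `"S362;S365"`).
#' Peptides whose localization probability is below `loc_min` contribute a
#' single ambiguous-location site group joining the candidate residues
#' with `|` (e.g. `"S218|T219"`), rather than individual residues.
#'
#' @param table collapsed phosphopeptide table ([qc_and_collapse()]).
#' @param loc_min localization-probability gate (default 0.75).
#' @return data.frame `peptide_id`, `protein_id`, `site`.
#' @export
peptide_site_map <- function(table, loc_min = 0.75) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    sites <- strsplit(table$phospho_pattern[i], ";", fixed = TRUE)[[1]]
    if (length(sites) == 0L)
      stop("peptide ", table$peptide_id[i], " maps to zero sites")
    loc <- table$localization_prob[i]
    if (!is.na(loc) && loc < loc_min) sites <- paste(sites, collapse = "|")
    data.frame(peptide_id = table$peptide_id[i],
               protein_id = table$protein_id[i],
               site = sites, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.axis_category <- function(calls, up_label, down_label) {
  sig <- calls[calls != "not_changing"]
  if (length(sig) == 0L) return("not_changing")
  if (all(sig == "up")) return(up_label)
  if (all(sig == "down")) return(down_label)
  "ambiguous"
}

#' Assign phosphosites to solubility / RNA categories
#'
#' Every peptide covering a site must agree: a site is `soluble`
#' (`insoluble`) iff at least one supporting peptide is significant and
#' all significant ones are up (down) in solubility versus the unmodified
#' protein; `facilitates_RNA` (`represses_RNA`) iff all significant
#' RNA-axis peptides shift toward more (less) RNA-bound, i.e. negative
#' (positive) RBF log2FC; `not_changing` iff nothing is significant on
#' either axis; any conflict among significant calls makes the axis
#' `ambiguous`. A site carries one label per axis.
#'
#' @param sol_results `differential_result` in mode solubility (peptide vs
#'   parent protein).
#' @param rna_results `differential_result` in mode rna_bound (may be
#'   `NULL` if the RNA axis was not measured).
#' @param pattern_map data.frame `peptide_id`, `protein_id`, `site`
#'   ([peptide_site_map()]).
#' @return data.frame: `protein_id`, `site`, `sol_category`,
#'   `rna_category`, `category` (overall: `not_changing` when both axes
#'   are, `ambiguous` when either axis is, otherwise the significant
#'   labels joined by `+`), `peptide_ids`.
#' @export
assign_site_categories <- function(sol_results, rna_results, pattern_map) {
  stopifnot(all(c("peptide_id", "protein_id", "site") %in% names(pattern_map)))
  unknown <- setdiff(sol_results$feature_id, pattern_map$peptide_id)
  if (length(unknown))
    stop("peptide(s) mapping to zero sites: ", paste(utils::head(unknown, 3), collapse = ", "))
  sol_call <- stats::setNames(sol_results$call, sol_results$feature_id)
  rna_call <- if (!is.null(rna_results))
    stats::setNames(rna_results$call, rna_results$feature_id) else character(0)

  key <- paste(pattern_map$protein_id, pattern_map$site, sep = "@")
  groups <- split(pattern_map$peptide_id, key)
  out <- lapply(names(groups), function(k) {
    peps <- groups[[k]]
    sc <- sol_call[peps]; sc <- sc[!is.na(sc)]
    rc <- rna_call[peps]; rc <- rc[!is.na(rc)]
    sol_cat <- .axis_category(sc, "soluble", "insoluble")
    # sign convention: negative RBF logFC = more RNA-bound
    rna_cat <- .axis_category(rc, "represses_RNA", "facilitates_RNA")
    overall <- if (sol_cat == "ambiguous" || rna_cat == "ambiguous") "ambiguous"
      else if (sol_cat == "not_changing" && rna_cat == "not_changing") "not_changing"
      else paste(setdiff(c(sol_cat, rna_cat), "not_changing"), collapse = "+")
    parts <- strsplit(k, "@", fixed = TRUE)[[1]]
    data.frame(protein_id = parts[1], site = parts[2],
               sol_category = sol_cat, rna_category = rna_cat,
               category = overall,
               peptide_ids = paste(peps, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mono- vs multi-phosphopeptide representation test
#'
#' Two-sided Fisher exact test of whether monophosphorylated peptides are
#' over/under-represented among peptides in a category, relative to the
#' remaining peptides.
#'
#' @param is_mono logical per peptide (`n_phospho == 1`).
#' @param in_category logical per peptide.
#' @return list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
monophospho_test <- function(is_mono, in_category) {
  stopifnot(length(is_mono) == length(in_category))
  tab <- table(factor(is_mono, c(TRUE, FALSE)),
               factor(in_category, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
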