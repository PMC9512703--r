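# Pulldown (co-IP) quantification: bait-specific interactor definition
# and input/bait-efficiency-corrected mutant/WT ratios.

#' Define bait-specific interactors from a WT-vs-tag-only comparison
#'
#' Interactors are features enriched in the WT-bait eluate over the
#' tag-only control at `log2FC > fc_threshold` and adjusted p
#' `< p_threshold` (defaults 1 and 0.01).
#'
#' @param wt_vs_tag `differential_result` of WT eluate vs tag-only eluate
#'   (normalized intensities).
#' @param fc_threshold,p_threshold gates.
#' @return character vector of interactor feature ids.
#' @export
define_interactors <- function(wt_vs_tag, fc_threshold = 1, p_threshold = 0.01) {
  wt_vs_tag$feature_id[wt_vs_tag$logFC > fc_threshold &
                       wt_vs_tag$padj < p_threshold]
}

#' Input- and bait-corrected mutant/WT fold changes
#'
#' Per protein and replicate:
#' `corrected = (eluate_mut / eluate_wt) / (input_mut / input_wt) /
#' (bait_mut / bait_wt)`, reported as log2. The input correction removes
#' lysate-amount differences; the bait correction removes IP-efficiency
#' differences. The two corrections commute.
#'
#' @param eluate_mut,eluate_wt numeric matrices (proteins x replicates)
#'   of eluate intensities, same rownames.
#' @param input_ratio per-replicate mutant/WT input ratio (scalar or
#'   length-replicates vector).
#' @param bait_ratio per-replicate mutant/WT captured-bait ratio.
#' @return matrix of corrected log2 ratios (proteins x replicates); rows
#'   with a zero denominator are `NA` and listed in attribute
#'   `"flagged"`.
#' @export
corrected_fold_changes <- function(eluate_mut, eluate_wt,
                                   input_ratio = 1, bait_ratio = 1) {
  eluate_mut <- as.matrix(eluate_mut); eluate_wt <- as.matrix(eluate_wt)
  if (!identical(rownames(eluate_mut), rownames(eluate_wt)))
    stop("eluate matrices must share proteins, in order")
  if (any(bait_ratio <= 0) || any(input_ratio <= 0))
    stop("input and bait ratios must be > 0")
  raw <- eluate_mut / eluate_wt
  corr <- sweep(sweep(raw, 2, input_ratio, "/"), 2, bait_ratio, "/")
  bad <- !is.finite(corr) | corr <= 0
  corr[bad] <- NA
  out <- log2(corr)
  attr(out, "flagged") <- rownames(out)[apply(bad, 1, any)]
  out
}

#' Compare phosphodeficient vs phosphomimetic constructs
#'
#' Takes the per-replicate median of corrected log2 ratios over the
#' interactor set for each construct, then a two-sided two-sample t-test
#' between constructs. `mode = "per_protein"` instead takes per-protein
#' medians across replicates (the alternative reading of "distribution
#' of the median of corrected FCs").
#'
#' @param corrected_deficient,corrected_mimetic matrices of corrected
#'   log2 ratios (proteins x replicates) from
#'   [corrected_fold_changes()].
#' @param interactors character vector of interactor protein ids (must be
#'   non-empty after intersection with the rownames).
#' @param mode `"per_replicate"` (default) or `"per_protein"`.
#' @return list: `t`, `p`, `effect` (mean mimetic median minus mean
#'   deficient median; negative = mimetic binds less),
#'   `medians_deficient`, `medians_mimetic`.
#' @export
compare_pairs <- function(corrected_deficient, corrected_mimetic, interactors,
                          mode = c("per_replicate", "per_protein")) {
  mode <- match.arg(mode)
  ia <- intersect(interactors, rownames(corrected_deficient))
  ib <- intersect(interactors, rownames(corrected_mimetic))
  if (!length(ia) || !length(ib)) stop("interactor set is empty")
  f <- function(m, ids) {
    m <- m[ids, , drop = FALSE]
    if (mode == "per_replicate")
      apply(m, 2, stats::median, na.rm = TRUE)
    else
      apply(m, 1, stats::median, na.rm = TRUE)
  }
  a <- f(corrected_deficient, ia); b <- f(corrected_mimetic, ib)
  if (length(a) < 2 || length(b) < 2) stop("at least 2 replicates required")
  # effect is mimetic minus deficient: negative = mimetic binds less
  eff <- mean(b) - mean(a)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate zero-variance medians: identical -> no evidence
    tt <- list(statistic = if (eff == 0) 0 else sign(eff) * Inf,
               p.value = if (eff == 0) 1 else 0)
  } else {
    tt <- stats::t.test(b, a, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value, effect = eff,
       medians_deficient = a, medians_mimetic = b)
}
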