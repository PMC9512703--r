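# Solubility / RNA-bound-fraction quantities and moderated differential
# statistics.
#
# Solubility S = log2(NP-40) - log2(SDS) per replicate and lysate; low S
# means a larger insoluble (condensate-associated) subpool. The RNA-bound
# fraction RBF = S_preserved - S_digested; more negative RBF means more of
# the feature's insolubility depends on intact RNA.

#' Per-replicate solubility profiles from a normalized table
#'
#' @param norm_table log2-scale [intensity_table()] with matched NP40/SDS
#'   columns per (lysate, replicate).
#' @return object of class `solubility_profile`: list with `feature_id`
#'   and `S`, a list of features x replicates matrices per lysate.
#'   Replicates lacking either channel are `NA` (flagged, never zero).
#' @export
compute_solubility <- function(norm_table) {
  stopifnot(inherits(norm_table, "intensity_table"), norm_table$log2)
  sm <- norm_table$samples
  lysates <- unique(sm$lysate)
  S <- list()
  for (ly in lysates) {
    reps <- sort(unique(sm$replicate[sm$lysate == ly]))
    m <- matrix(NA_real_, nrow(norm_table$values), length(reps),
                dimnames = list(norm_table$features$feature_id,
                                paste0("rep", reps)))
    for (i in seq_along(reps)) {
      np <- sm$sample[sm$detergent == "NP40" & sm$lysate == ly & sm$replicate == reps[i]]
      sd_ <- sm$sample[sm$detergent == "SDS" & sm$lysate == ly & sm$replicate == reps[i]]
      if (length(np) != 1L || length(sd_) != 1L)
        stop("unmatched NP40/SDS columns for lysate ", ly, " replicate ", reps[i])
      m[, i] <- norm_table$values[, np] - norm_table$values[, sd_]
    }
    S[[ly]] <- m
  }
  structure(list(feature_id = norm_table$features$feature_id, S = S),
            class = "solubility_profile")
}

#' RNA-bound fraction per feature and replicate
#'
#' `RBF = S_preserved - S_digested` (log2); more negative means more
#' RNA-bound. Replicates missing either lysate are `NA`.
#'
#' @param profile a [compute_solubility()] result with both lysates.
#' @return features x replicates matrix of RBF values.
#' @export
compute_rna_bound <- function(profile) {
  stopifnot(inherits(profile, "solubility_profile"))
  if (!all(c("preserved", "digested") %in% names(profile$S)))
    stop("both lysate profiles (preserved, digested) are required")
  profile$S$preserved - profile$S$digested
}

# --- empirical-Bayes variance moderation -------------------------------

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6 & is.finite(y)
  hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- which(!lo & !hi & is.finite(y))
  if (length(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit on the log residual variances: assuming
#' `s^2 ~ s0^2 * F(df, d0)`, matches mean and variance of `log(s^2)`
#' using digamma/trigamma moments and returns the prior degrees of
#' freedom `d0` and prior variance `s02`. `d0 = Inf` when the observed
#' spread of log variances is no larger than expected under a common
#' variance.
#'
#' @param s2 per-feature residual variances (positive, finite).
#' @param df residual degrees of freedom (scalar or per-feature).
#' @return list(d0, s02).
#' @export
estimate_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0
  s2 <- s2[keep]
  df <- if (length(df) > 1L) df[keep] else rep(df, length(s2))
  if (length(s2) < 2L) return(list(d0 = Inf, s02 = if (length(s2)) s2 else NA_real_))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s02 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

.moderate <- function(effect, s2, df, unscaled, prior_df = NULL) {
  if (is.null(prior_df)) {
    pr <- estimate_variance_prior(s2, df)
  } else if (!is.finite(prior_df) || prior_df > 0) {
    pr <- list(d0 = prior_df,
               s02 = if (is.finite(prior_df))
                 estimate_variance_prior(s2, df)$s02 else mean(s2, na.rm = TRUE))
  } else {
    pr <- list(d0 = 0, s02 = 0)
  }
  d0 <- pr$d0; s02 <- pr$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  tt <- effect / (sqrt(s2_post) * unscaled)
  df_total <- df + d0
  # degenerate zero-variance features: t undefined; zero effect -> p = 1
  degen <- !is.finite(tt)
  tt[degen & effect == 0] <- 0
  tt[degen & effect != 0] <- sign(effect[degen & effect != 0]) * Inf
  p <- 2 * stats::pt(-abs(tt), df = pmin(df_total, 1e300))
  list(t = tt, p = p, d0 = d0, s02 = s02, df_total = df_total)
}

#' Moderated differential test between two groups of replicate values
#'
#' Per-feature linear-model effect with residual variances shrunk toward a
#' common prior (moderated t with augmented degrees of freedom); the
#' hyperparameters are estimated from the distribution of log residual
#' variances across features. P values are Benjamini-Hochberg adjusted
#' across all tested features.
#'
#' @param group_a,group_b numeric matrices (features x replicates) with
#'   identical rownames (feature ids).
#' @param paired if TRUE (default), replicates are paired by column index
#'   (matched TMT design) and a one-sample test on the per-replicate
#'   differences is performed; otherwise a pooled two-sample test.
#' @param fc_threshold,p_threshold call thresholds: `up`/`down` require
#'   `|log2FC| > fc_threshold` and adjusted p `< p_threshold`
#'   (defaults 0.5, 0.01).
#' @param prior_df force the prior degrees of freedom (0 recovers the
#'   ordinary t-test; `Inf` fully pools variances); `NULL` estimates it.
#' @return data.frame of class `differential_result`: `feature_id`,
#'   `logFC`, `t`, `p`, `padj`, `call`, with hyperparameters `d0`, `s02`
#'   as attributes. Features with zero residual df are excluded with a
#'   warning.
#' @export
moderated_diff <- function(group_a, group_b, paired = TRUE,
                           fc_threshold = 0.5, p_threshold = 0.01,
                           prior_df = NULL) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (!identical(rownames(group_a), rownames(group_b)))
    stop("group_a and group_b must cover the same features, in order")
  if (ncol(group_a) < 2L || ncol(group_b) < 2L)
    stop("at least 2 replicates per group required")

  if (paired) {
    if (ncol(group_a) != ncol(group_b)) stop("paired groups need equal replicates")
    d <- group_a - group_b
    n_ok <- rowSums(is.finite(d))
    effect <- rowMeans(d, na.rm = TRUE)
    s2 <- apply(d, 1, stats::var, na.rm = TRUE)
    df <- n_ok - 1
    unscaled <- 1 / sqrt(n_ok)
  } else {
    na_ok <- rowSums(is.finite(group_a)); nb_ok <- rowSums(is.finite(group_b))
    effect <- rowMeans(group_a, na.rm = TRUE) - rowMeans(group_b, na.rm = TRUE)
    va <- apply(group_a, 1, stats::var, na.rm = TRUE)
    vb <- apply(group_b, 1, stats::var, na.rm = TRUE)
    df <- na_ok + nb_ok - 2
    s2 <- ((na_ok - 1) * va + (nb_ok - 1) * vb) / df
    unscaled <- sqrt(1 / na_ok + 1 / nb_ok)
    n_ok <- pmin(na_ok, nb_ok)
  }
  usable <- is.finite(effect) & df > 0
  if (any(!usable)) {
    warning(sum(!usable), " feature(s) with zero residual df excluded")
  }
  fid <- rownames(group_a)[usable]
  mod <- .moderate(effect[usable], s2[usable], df[usable], unscaled[usable],
                   prior_df = prior_df)
  padj <- bh_adjust(mod$p)
  call <- ifelse(abs(effect[usable]) > fc_threshold & padj < p_threshold,
                 ifelse(effect[usable] > 0, "up", "down"), "not_changing")
  res <- data.frame(feature_id = fid, logFC = effect[usable], t = mod$t,
                    p = mod$p, padj = padj, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- mod$d0
  attr(res, "s02") <- mod$s02
  attr(res, "excluded") <- rownames(group_a)[!usable]
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Test whether per-feature solubility differs from zero
#'
#' Convenience wrapper: moderated one-sample test of NP-40 vs SDS, i.e. of
#' the per-replicate S values against 0, for one lysate.
#'
#' @param profile a [compute_solubility()] result.
#' @param lysate `"preserved"` or `"digested"`.
#' @inheritParams moderated_diff
#' @return a `differential_result` (negative logFC = insoluble subpool).
#' @export
solubility_diff <- function(profile, lysate = "preserved",
                            fc_threshold = 0.5, p_threshold = 0.01,
                            prior_df = NULL) {
  stopifnot(inherits(profile, "solubility_profile"))
  s <- profile$S[[lysate]]
  if (is.null(s)) stop("no profile for lysate ", lysate)
  zero <- s; zero[] <- 0
  moderated_diff(s, zero, paired = TRUE, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, prior_df = prior_df)
}

#' Test the RNase effect on solubility (preserved vs digested)
#'
#' Moderated paired test of `S_preserved` vs `S_digested`; the effect is
#' the mean RBF. Negative logFC = solubility gained upon RNA digestion
#' (RNA-dependent insolubility).
#'
#' @param profile a [compute_solubility()] result with both lysates.
#' @inheritParams moderated_diff
#' @return a `differential_result`.
#' @export
rnase_diff <- function(profile, fc_threshold = 0.5, p_threshold = 0.01,
                       prior_df = NULL) {
  stopifnot(inherits(profile, "solubility_profile"))
  moderated_diff(profile$S$preserved, profile$S$digested, paired = TRUE,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 prior_df = prior_df)
}

#' Classify proteins into solubility classes
#'
#' A protein maintains an insoluble subpool iff its preserved-lysate S is
#' significantly below zero (`logFC <= -fc_threshold`, adjusted p
#' `< p_threshold`); it is RNase-sensitive iff it additionally gains
#' solubility significantly upon RNA digestion (negative RBF effect).
#'
#' @param preserved_diff,digested_diff `differential_result`s of NP40 vs
#'   SDS per lysate (digested is carried for the flags).
#' @param rnase `differential_result` of S_preserved vs S_digested.
#' @param fc_threshold,p_threshold thresholds (defaults 0.5, 0.01).
#' @return data.frame: `feature_id`, `class` (one of
#'   `predominantly_soluble`, `rnase_sensitive_insoluble`,
#'   `rnase_insensitive_insoluble`), `gained_solubility`,
#'   `lost_solubility` flags.
#' @export
classify_proteins <- function(preserved_diff, digested_diff, rnase,
                              fc_threshold = 0.5, p_threshold = 0.01) {
  ids <- preserved_diff$feature_id
  if (!identical(ids, rnase$feature_id) ||
      !identical(ids, digested_diff$feature_id))
    stop("result lists must share feature ids, in order")
  insol <- preserved_diff$logFC <= -fc_threshold & preserved_diff$padj < p_threshold
  gained <- rnase$logFC <= -fc_threshold & rnase$padj < p_threshold
  lost <- rnase$logFC >= fc_threshold & rnase$padj < p_threshold
  cls <- ifelse(!insol, "predominantly_soluble",
                ifelse(gained, "rnase_sensitive_insoluble",
                       "rnase_insensitive_insoluble"))
  data.frame(feature_id = ids, class = cls,
             gained_solubility = gained, lost_solubility = lost,
             stringsAsFactors = FALSE)
}

#' Differential solubility (or RNA-bound fraction) of phosphopeptides vs
#' their parent proteins
#'
#' The parent protein's profile is a proxy for the unmodified proteoforms;
#' each peptide's per-replicate S (mode `"solubility"`, preserved lysate)
#' or RBF (mode `"rna_bound"`) is compared to its parent's by a paired
#' moderated test (replicates matched by index, same plex).
#'
#' @param peptide_profile [compute_solubility()] result for peptides.
#' @param protein_profile [compute_solubility()] result for proteins.
#' @param peptide_map data.frame `peptide_id`, `protein_id`.
#' @param mode `"solubility"` or `"rna_bound"`.
#' @inheritParams moderated_diff
#' @return `differential_result` keyed by peptide id; orphan peptides
#'   (no protein profile) are excluded and listed in attribute
#'   `"orphans"`.
#' @export
diff_phospho_vs_protein <- function(peptide_profile, protein_profile,
                                    peptide_map,
                                    mode = c("solubility", "rna_bound"),
                                    fc_threshold = 0.5, p_threshold = 0.01,
                                    prior_df = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(peptide_profile, "solubility_profile"),
            inherits(protein_profile, "solubility_profile"))
  pep_mat <- if (mode == "solubility") peptide_profile$S$preserved else
    compute_rna_bound(peptide_profile)
  prot_mat <- if (mode == "solubility") protein_profile$S$preserved else
    compute_rna_bound(protein_profile)

  idx <- match(peptide_map$peptide_id, rownames(pep_mat))
  pidx <- match(peptide_map$protein_id, rownames(prot_mat))
  orphan <- is.na(pidx) | is.na(idx)
  if (all(orphan)) stop("no peptide maps to a protein profile")
  a <- pep_mat[idx[!orphan], , drop = FALSE]
  b <- prot_mat[pidx[!orphan], , drop = FALSE]
  rownames(a) <- rownames(b) <- peptide_map$peptide_id[!orphan]
  res <- moderated_diff(a, b, paired = TRUE, fc_threshold = fc_threshold,
                        p_threshold = p_threshold, prior_df = prior_df)
  attr(res, "orphans") <- peptide_map$peptide_id[orphan]
  res
}
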