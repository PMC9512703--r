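# Over-representation analysis and phosphosite-activity inference.

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the foreground contains at
#' least the observed number of set members by the upper-tail
#' hypergeometric probability, with the user-supplied background as the
#' universe (sets are intersected with the background before testing).
#' Q values are Benjamini-Hochberg across all tested sets.
#'
#' @param sets named list of character vectors (e.g. read from GMT).
#' @param foreground,background character identifier vectors; the
#'   foreground must be a subset of the background.
#' @param q_threshold enrichment call threshold (default 0.05).
#' @return data.frame: `set_id`, `overlap`, `set_size` (in background),
#'   `foreground_size`, `background_size`, `p`, `q`, `enriched`. Sets
#'   disjoint from the background are reported with `NA` p (untestable).
#' @export
hypergeometric_ora <- function(sets, foreground, background,
                               q_threshold = 0.05) {
  foreground <- unique(foreground); background <- unique(background)
  if (!length(foreground) || !length(background))
    stop("foreground and background must be non-empty")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  N <- length(background); n <- length(foreground)
  res <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), background)
    K <- length(members)
    if (K == 0L)
      return(data.frame(set_id = id, overlap = 0L, set_size = 0L,
                        foreground_size = n, background_size = N,
                        p = NA_real_, stringsAsFactors = FALSE))
    k <- length(intersect(members, foreground))
    # P(X >= k), X ~ Hypergeometric(K successes, N - K failures, n draws)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = K,
               foreground_size = n, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  testable <- !is.na(out$p)
  out$q[testable] <- bh_adjust(out$p[testable])
  out$enriched <- !is.na(out$q) & out$q < q_threshold
  out
}

#' Phosphosite activity across perturbation conditions
#'
#' For each condition, the fold changes of a subgroup of sites are
#' compared against the overall fold-change distribution by a Z-test:
#' `z = (mean_subgroup - mean_all) / (sd_all / sqrt(n_subgroup))`, with a
#' two-sided normal p value reported as signed `-log10(p)` (sign of z).
#' Conditions are significant when `|signed -log10 p| > threshold`
#' (default 2) in either direction; conditions with fewer than
#' `min_sites` mapped subgroup sites are untestable (`NA`), never zero.
#'
#' @param matrix sites x conditions numeric matrix of log fold changes
#'   (NAs allowed).
#' @param subgroup_labels character per site.
#' @param subgroup label to test.
#' @param threshold significance threshold on `|-log10 p|` (default 2).
#' @param min_sites minimum mapped subgroup sites per condition
#'   (default 5).
#' @return data.frame per condition: `condition`, `n_subgroup`, `z`,
#'   `minus_log10_p` (signed), `significant`.
#' @export
site_activity <- function(matrix, subgroup_labels, subgroup,
                          threshold = 2, min_sites = 5L) {
  stopifnot(nrow(matrix) == length(subgroup_labels))
  in_sub <- subgroup_labels == subgroup
  if (!any(in_sub)) stop("subgroup '", subgroup, "' has no sites")
  conds <- colnames(matrix)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(matrix)))
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    v <- matrix[, j]
    vs <- v[in_sub & is.finite(v)]
    va <- v[is.finite(v)]
    n <- length(vs)
    if (n < min_sites || length(va) < 2 || stats::sd(va) == 0)
      return(data.frame(condition = conds[j], n_subgroup = n,
                        z = NA_real_, minus_log10_p = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    z <- (mean(vs) - mean(va)) / (stats::sd(va) / sqrt(n))
    p <- 2 * stats::pnorm(-abs(z))
    slp <- sign(z) * -log10(p)
    data.frame(condition = conds[j], n_subgroup = n, z = z,
               minus_log10_p = slp, significant = abs(slp) > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Permutation-null phosphosite activity (sensitivity analysis)
#'
#' Alternative to the closed-form Z-test: the subgroup-mean shift is
#' compared against the null distribution of means of random site
#' subsets of the same size.
#'
#' @inheritParams site_activity
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame per condition with `perm_p`.
#' @export
site_activity_permutation <- function(matrix, subgroup_labels, subgroup,
                                      n_perm = 1000L, min_sites = 5L,
                                      seed = 1L) {
  in_sub <- subgroup_labels == subgroup
  set.seed(derive_seed(seed, "perturbations"))
  conds <- colnames(matrix)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(matrix)))
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    v <- matrix[, j]
    ok <- is.finite(v)
    vs <- v[in_sub & ok]; va <- v[ok]
    n <- length(vs)
    if (n < min_sites)
      return(data.frame(condition = conds[j], n_subgroup = n,
                        perm_p = NA_real_, stringsAsFactors = FALSE))
    obs <- abs(mean(vs) - mean(va))
    null <- replicate(n_perm, abs(mean(sample(va, n)) - mean(va)))
    data.frame(condition = conds[j], n_subgroup = n,
               perm_p = (sum(null >= obs) + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
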