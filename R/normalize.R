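# Calibration-subset variance-stabilizing normalization.
#
# Technical variation is removed by fitting per-sample parameters on a
# "predominantly soluble" calibration subset only (proteins whose raw
# NP-40/SDS ratio is near 1), then applying them to all features. Fitting
# on all features would absorb genuine insolubility signal into the
# normalization (see the tests for a demonstration).

#' Select the predominantly-soluble calibration subset
#'
#' Features whose mean raw NP-40/SDS ratio across replicates lies inside
#' `[low, high]` (defaults 0.8-1.2). Zeros are treated as missing for the
#' ratio; features with any missing NP-40/SDS pair are excluded from
#' calibration (but are still normalized later).
#'
#' @param table an [intensity_table()] on the raw scale with matched NP40
#'   and SDS columns per replicate.
#' @param low,high ratio bounds.
#' @param per_replicate if TRUE, require every replicate-wise ratio in
#'   range rather than the mean ratio.
#' @return character vector of calibration feature ids.
#' @export
select_calibration_subset <- function(table, low = 0.8, high = 1.2,
                                      per_replicate = FALSE) {
  stopifnot(inherits(table, "intensity_table"), !table$log2)
  sm <- table$samples
  ratios <- NULL
  for (ly in unique(sm$lysate)) {
    for (r in unique(sm$replicate[sm$lysate == ly])) {
      np <- sm$sample[sm$detergent == "NP40" & sm$lysate == ly & sm$replicate == r]
      sd_ <- sm$sample[sm$detergent == "SDS" & sm$lysate == ly & sm$replicate == r]
      if (length(np) != 1L || length(sd_) != 1L) next
      num <- table$values[, np]; den <- table$values[, sd_]
      num[num == 0] <- NA; den[den == 0] <- NA
      ratios <- cbind(ratios, num / den)
    }
  }
  if (is.null(ratios)) stop("no matched NP40/SDS sample pairs found")
  ok_pairs <- stats::complete.cases(ratios)
  inside <- if (per_replicate) {
    ok_pairs & apply(ratios >= low & ratios <= high, 1, all)
  } else {
    m <- rowMeans(ratios)
    ok_pairs & m >= low & m <= high
  }
  ids <- table$features$feature_id[inside]
  if (length(ids) == 0L)
    stop("no feature qualifies for calibration; widen the [low, high] bounds")
  ids
}

# generalized log2: log2((x + sqrt(x^2 + c^2)) / 2); c = 0 gives log2(x).
glog2 <- function(x, c) {
  if (c == 0) return(log2(x))
  log2((x + sqrt(x^2 + c^2)) / 2)
}

# variance-vs-mean trend statistic on a log2-scale matrix restricted to
# calibration rows: |Spearman correlation| of row means vs row sds.
.trend_stat <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  keep <- is.finite(mu) & is.finite(sdv)
  if (sum(keep) < 3 || stats::sd(sdv[keep]) == 0) return(0)
  abs(stats::cor(mu[keep], sdv[keep], method = "spearman"))
}

#' Fit a normalization model on a calibration subset and apply it to all
#' features
#'
#' Per-sample scale factors are estimated ONLY on calibration features
#' (median ratio to the across-sample reference), then a shared
#' generalized-log transform parameter is chosen to flatten the
#' variance-vs-mean trend of the calibration features; the smallest
#' parameter within tolerance of the optimum is kept, so clean data
#' reduces to an exact `log2`. The fitted model is applied to every
#' feature; output is on the log2 scale.
#'
#' @param table raw-scale [intensity_table()].
#' @param calibration character vector of calibration feature ids.
#' @param method `"glog"` (default) or `"median"` (pure median scaling,
#'   exact log2; used for exactness checks).
#' @return list with `table` (normalized, log2 scale) and `model`
#'   (per-sample scales, glog parameter, calibration ids, trend diagnostic).
#' @export
fit_apply_normalization <- function(table, calibration, method = c("glog", "median")) {
  stopifnot(inherits(table, "intensity_table"), !table$log2)
  method <- match.arg(method)
  if (length(calibration) == 0L) stop("calibration subset is empty")
  idx <- match(calibration, table$features$feature_id)
  if (anyNA(idx)) stop("calibration ids missing from table")
  cal <- table$values[idx, , drop = FALSE]
  cal[cal == 0] <- NA
  if (any(colSums(!is.na(cal)) == 0))
    stop("a sample has all-zero calibration intensities")

  # per-sample median of calibration intensities, centred to geometric
  # mean 1 so the overall intensity scale is preserved; this makes the
  # across-sample calibration medians exactly equal after normalization
  med <- apply(cal, 2, stats::median, na.rm = TRUE)
  scales <- med / exp(mean(log(med)))
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("non-positive fitted scale")
  scaled_cal <- sweep(cal, 2, scales, "/")

  cpar <- 0
  if (method == "glog") {
    # candidate glog parameters on the scale of the low-intensity tail
    qlow <- stats::quantile(scaled_cal, 0.05, na.rm = TRUE)
    cand <- c(0, qlow * c(0.01, 0.1, 0.5, 1, 2, 5, 10))
    obj <- vapply(cand, function(cc) .trend_stat(glog2(scaled_cal, cc)),
                  numeric(1))
    best <- min(obj)
    cpar <- min(cand[obj <= best + 0.02]) # smallest c near the optimum
  }
  vals <- glog2(sweep(table$values, 2, scales, "/"), cpar)
  vals[!is.finite(vals)] <- NA

  model <- list(scales = scales, glog_c = cpar, calibration = calibration,
                method = method,
                trend = .trend_stat(glog2(scaled_cal, cpar)))
  out <- intensity_table(vals, table$features, table$samples, log2 = TRUE)
  list(table = out, model = model)
}

#' Apply a previously fitted normalization model
#'
#' @param table raw-scale [intensity_table()] with the same samples the
#'   model was fitted on.
#' @param model the `model` element returned by [fit_apply_normalization()].
#' @return normalized log2-scale [intensity_table()].
#' @export
apply_normalization <- function(table, model) {
  stopifnot(inherits(table, "intensity_table"), !table$log2)
  if (!all(colnames(table$values) == names(model$scales)))
    stop("sample mismatch between table and model")
  vals <- glog2(sweep(table$values, 2, model$scales, "/"), model$glog_c)
  vals[!is.finite(vals)] <- NA
  intensity_table(vals, table$features, table$samples, log2 = TRUE)
}
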