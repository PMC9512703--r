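# Condensate image quantification: rim construction, background
# subtraction, partition coefficients, reference normalization, nuclear
# coefficient of variation. Images are plain numeric matrices; label
# masks are integer matrices (0 = background). Pixel coordinates are
# 0-based (x = column, y = row).

#' Build nucleoplasmic rims around labeled nucleoli
#'
#' For each label, the rim is the set of pixels whose Euclidean distance
#' to the label's region lies in `(inner - 1, outer]` (defaults 1 and 6
#' px, i.e. distance in `(0, 6]`). Rims exclude every labeled pixel of
#' any label; where rims of adjacent labels overlap, each pixel is
#' assigned to the nearer label. Labels whose rim reaches the image
#' border are flagged as clipped.
#'
#' @param labels integer label matrix (0 = background).
#' @param inner,outer ring distances in px (`inner < outer`).
#' @return list: `rim` (integer matrix, rim pixels carry their label) and
#'   `clipped` (labels whose rim touched the border).
#' @export
make_rim <- function(labels, inner = 1, outer = 6) {
  if (inner >= outer) stop("inner must be < outer")
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) stop("label mask is empty")
  h <- nrow(labels); w <- ncol(labels)
  rim <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  pad <- ceiling(outer)
  clipped <- integer(0)
  for (lab in labs) {
    pix <- which(labels == lab, arr.ind = TRUE)
    # region boundary pixels (any 4-neighbour outside the region, or at
    # the image border) are the nearest points for any exterior pixel
    on_border <- pix[, 1] == 1 | pix[, 1] == h | pix[, 2] == 1 | pix[, 2] == w
    inb <- function(r, c) r >= 1 & r <= h & c >= 1 & c <= w
    nb_out <- rep(FALSE, nrow(pix))
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- pix[, 1] + d[1]; cc <- pix[, 2] + d[2]
      ok <- inb(rr, cc)
      out <- rep(TRUE, nrow(pix))
      out[ok] <- labels[cbind(rr[ok], cc[ok])] != lab
      nb_out <- nb_out | out
    }
    bnd <- pix[nb_out | on_border, , drop = FALSE]
    r0 <- max(1, min(pix[, 1]) - pad); r1 <- min(h, max(pix[, 1]) + pad)
    c0 <- max(1, min(pix[, 2]) - pad); c1 <- min(w, max(pix[, 2]) + pad)
    if (min(pix[, 1]) - pad < 1 || max(pix[, 1]) + pad > h ||
        min(pix[, 2]) - pad < 1 || max(pix[, 2]) + pad > w)
      clipped <- c(clipped, lab)
    cand_r <- rep(r0:r1, times = c1 - c0 + 1)
    cand_c <- rep(c0:c1, each = r1 - r0 + 1)
    # min distance from each candidate pixel to the region boundary
    d2 <- base::outer(cand_r, bnd[, 1], "-")^2 +
      base::outer(cand_c, bnd[, 2], "-")^2
    dmin <- sqrt(apply(d2, 1, min))
    dmin[labels[cbind(cand_r, cand_c)] == lab] <- 0
    sel <- dmin > (inner - 1) & dmin <= outer &
      labels[cbind(cand_r, cand_c)] == 0
    take <- sel & dmin < best[cbind(cand_r, cand_c)]
    rim[cbind(cand_r[take], cand_c[take])] <- lab
    best[cbind(cand_r[take], cand_c[take])] <-
      dmin[take]
  }
  list(rim = rim, clipped = clipped)
}

#' Measure per-nucleolus partition coefficients
#'
#' Background is the mean intensity of a rectangular ROI outside the cell
#' area and is subtracted from both means; `K = (nucleolus mean - bg) /
#' (rim mean - bg)`. Nucleoli are kept only if their area exceeds
#' `min_area_px2` (default 1000 px^2) and their mean intensity exceeds
#' `intensity_floor` times the background (default 20x, skipped when the
#' background is 0).
#'
#' @param img a labeled image: list with `intensity`, `labels`,
#'   `background_roi` (`c(x, y, w, h)`, 0-based) and optional
#'   `pixel_size_nm` (as produced by [simulate_image()]).
#' @param min_area_px2 area gate (strictly greater than).
#' @param intensity_floor multiple of background the nucleolus mean must
#'   exceed.
#' @param inner,outer rim distances (px).
#' @return data.frame: `label`, `nucleolus_mean`, `rim_mean`,
#'   `background`, `K`, `area_px2`, `area_um2`, `passed_filters`,
#'   `reason`.
#' @export
measure_partition_coefficients <- function(img, min_area_px2 = 1000,
                                           intensity_floor = 20,
                                           inner = 1, outer = 6) {
  intensity <- img$intensity; labels <- img$labels
  roi <- img$background_roi
  h <- nrow(intensity); w <- ncol(intensity)
  cols <- (roi[1] + 1):(roi[1] + roi[3]) # x -> column, 0-based -> 1-based
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  if (max(cols) > w || max(rows) > h || min(cols) < 1 || min(rows) < 1)
    stop("background ROI outside the image frame")
  if (any(labels[rows, cols] != 0))
    stop("background ROI overlaps a labeled region")
  bg <- mean(intensity[rows, cols])

  rims <- make_rim(labels, inner = inner, outer = outer)
  labs <- sort(unique(labels[labels > 0]))
  res <- lapply(labs, function(lab) {
    in_nuc <- labels == lab
    in_rim <- rims$rim == lab
    area <- sum(in_nuc)
    nuc_mean <- mean(intensity[in_nuc])
    rim_mean <- if (any(in_rim)) mean(intensity[in_rim]) else NA_real_
    reasons <- character(0)
    if (area <= min_area_px2) reasons <- c(reasons, "area")
    if (bg > 0 && nuc_mean <= intensity_floor * bg)
      reasons <- c(reasons, "intensity_floor")
    K <- NA_real_
    if (!is.na(rim_mean) && rim_mean > bg && nuc_mean > bg) {
      K <- (nuc_mean - bg) / (rim_mean - bg)
    } else reasons <- c(reasons, "rim_not_above_background")
    area_um2 <- if (!is.null(img$pixel_size_nm))
      px_to_physical(area, img$pixel_size_nm, area = TRUE) else NA_real_
    data.frame(label = lab, nucleolus_mean = nuc_mean, rim_mean = rim_mean,
               background = bg, K = K, area_px2 = area, area_um2 = area_um2,
               passed_filters = length(reasons) == 0L,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normalize partition coefficients to a reference (WT) median
#'
#' @param results [measure_partition_coefficients()] output for the
#'   construct of interest.
#' @param reference same, for the wild-type reference of the same
#'   experiment; only entries passing filters contribute to the median.
#' @return `results` with an added `relative_K` column.
#' @export
normalize_k <- function(results, reference) {
  ref <- reference$K[reference$passed_filters & !is.na(reference$K)]
  if (!length(ref)) stop("reference is empty after filters")
  results$relative_K <- results$K / stats::median(ref)
  results
}

#' Coefficient of variation of the nuclear signal
#'
#' `CV = sd / mean` of the background-subtracted intensities inside the
#' nucleus mask; sample (n-1) standard deviation by default.
#'
#' @param intensity numeric image matrix.
#' @param nucleus_mask logical matrix.
#' @param background scalar to subtract (default 0).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list: `cv` (`NA` when the subtracted mean is not positive),
#'   `mean`, `sd`, `n`.
#' @export
nuclear_cv <- function(intensity, nucleus_mask, background = 0,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!any(nucleus_mask)) stop("nucleus mask is empty")
  v <- intensity[nucleus_mask] - background
  m <- mean(v); n <- length(v)
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(cv = if (m > 0) s / m else NA_real_, mean = m, sd = s, n = n)
}

#' Convert pixel measures to physical units
#'
#' @param pixels count (linear) or px^2 (with `area = TRUE`).
#' @param pixel_size_nm physical pixel size in nm (the reference imaging
#'   setup has 424/6 nm per px).
#' @param area treat `pixels` as an area.
#' @return micrometers (linear) or square micrometers (area).
#' @export
px_to_physical <- function(pixels, pixel_size_nm, area = FALSE) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  um <- pixel_size_nm / 1000
  if (area) pixels * um^2 else pixels * um
}

#' Naive Otsu threshold segmentation (convenience plumbing)
#'
#' NOT a faithful reimplementation of the adaptive segmentation used for
#' real micrographs; provided only so the pipeline can run end-to-end on
#' an intensity image without an external mask. Thresholds by Otsu's
#' criterion and labels 4-connected components above the threshold.
#'
#' @param intensity numeric image matrix.
#' @param n_bins histogram bins (default 256).
#' @return integer label matrix.
#' @export
naive_threshold_labels <- function(intensity, n_bins = 256L) {
  v <- as.vector(intensity)
  br <- seq(min(v), max(v), length.out = n_bins + 1L)
  hist_ <- tabulate(findInterval(v, br, all.inside = TRUE), n_bins)
  p <- hist_ / sum(hist_)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  thr <- mids[which.max(between)]
  mask <- intensity > thr
  # 4-connected component labeling (iterative flood fill)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% h + 1L; c <- (i - 1L) %/% h + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          j <- (cc - 1L) * h + rr
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}
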