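# Independent oracles. These deliberately use naive scalar loops and a
# different enumeration strategy than the package so that agreement is a
# genuine cross-check, not a shared code path.

# ---- kappa ------------------------------------------------------------

oracle_sigma <- function(ch) {
  fp <- sum(ch > 0) / length(ch)
  fm <- sum(ch < 0) / length(ch)
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

oracle_delta <- function(ch, g) {
  n <- length(ch) - g + 1
  sg <- oracle_sigma(ch)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (oracle_sigma(ch[i:(i + g - 1)]) - sg)^2
  acc / n
}

# all distinct arrangements of a charge multiset by recursive expansion
oracle_arrangements <- function(counts) {
  # counts: named c(p = n_plus, m = n_minus, z = n_zero)
  if (sum(counts) == 0) return(list(integer(0)))
  out <- list()
  for (cls in names(counts)) {
    if (counts[[cls]] == 0) next
    rest <- counts
    rest[[cls]] <- rest[[cls]] - 1
    val <- switch(cls, p = 1L, m = -1L, z = 0L)
    for (tail in oracle_arrangements(rest))
      out[[length(out) + 1]] <- c(val, tail)
  }
  out
}

.oracle_dmax_cache <- new.env(parent = emptyenv())
oracle_delta_max <- function(ch, g) {
  counts <- c(p = sum(ch > 0), m = sum(ch < 0), z = sum(ch == 0))
  key <- paste(counts, g, collapse = "_")
  hit <- .oracle_dmax_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- max(vapply(oracle_arrangements(counts), oracle_delta, numeric(1), g = g))
  .oracle_dmax_cache[[key]] <- val
  val
}

oracle_kappa <- function(ch, blob_sizes = c(5, 6)) {
  if (all(ch == 0)) return(NA_real_)
  ks <- vapply(blob_sizes, function(g) {
    dmax <- oracle_delta_max(ch, g)
    if (dmax == 0) return(NA_real_)
    oracle_delta(ch, g) / dmax
  }, numeric(1))
  if (all(is.na(ks))) NA_real_ else mean(ks, na.rm = TRUE)
}

seq_to_charges <- function(s) {
  r <- strsplit(s, "")[[1]]
  ifelse(r %in% c("K", "R"), 1L, ifelse(r %in% c("D", "E"), -1L, 0L))
}

# ---- statistics -------------------------------------------------------

# brute-force BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# exact upper-tail hypergeometric by factorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ---- imaging ----------------------------------------------------------

# per-pixel distance scan: rim = pixels with euclidean distance to the
# label region in (inner-1, outer], excluding all labeled pixels,
# nearest label wins
oracle_rim <- function(labels, inner, outer) {
  h <- nrow(labels); w <- ncol(labels)
  labs <- sort(unique(labels[labels > 0]))
  regions <- lapply(labs, function(l) which(labels == l, arr.ind = TRUE))
  rim <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (labels[r, c] != 0) next
    dbest <- Inf; lbest <- 0L
    for (li in seq_along(labs)) {
      reg <- regions[[li]]
      d <- sqrt(min((reg[, 1] - r)^2 + (reg[, 2] - c)^2))
      if (d < dbest) { dbest <- d; lbest <- labs[li] }
    }
    if (dbest > inner - 1 && dbest <= outer) rim[r, c] <- lbest
  }
  rim
}

# draw a valid random nucleolus geometry for partition tests; the
# background ("outside the cell") is kept near zero, as in real
# micrographs, so the 20x-background intensity gate is meaningful
random_geometry <- function(seed, r_min = 19, r_max = 32) {
  set.seed(seed)
  h <- 260; w <- 360
  r <- sample(r_min:r_max, 1)
  margin <- r + 10
  cx <- sample((100 + margin):(w - 6 - margin), 1)
  cy <- sample((5 + margin):(h - 6 - margin), 1)
  list(shape = c(h, w),
       nucleoli = data.frame(cx = cx, cy = cy, r = r,
                             intensity = runif(1, 150, 400)),
       nucleoplasm = runif(1, 60, 120),
       background = runif(1, 0, 5))
}
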