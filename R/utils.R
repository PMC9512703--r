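#' @keywords internal
"_PACKAGE"

# Stage ids used for child-seed derivation. One global seed expands into
# per-stage child seeds by this fixed arithmetic so each stage is
# independently reproducible.
.stage_ids <- c(
  solubility = 1L, phospho = 2L, sequences = 3L, perturbations = 4L,
  image = 5L, pipeline = 6L
)

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic expansion of one user-facing seed into independent
#' per-stage seeds, so e.g. re-running only the phosphopeptide simulation
#' reproduces the same draws as a full pipeline run. The derivation is
#' `(seed * 2654435761 + stage_id) mod (2^31 - 1)` (Knuth multiplicative
#' constant), kept strictly below 2^31.
#'
#' @param seed integer global seed.
#' @param stage one of `"solubility"`, `"phospho"`, `"sequences"`,
#'   `"perturbations"`, `"image"`, `"pipeline"`, or an integer stage id.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  id <- if (is.character(stage)) {
    if (!stage %in% names(.stage_ids)) stop("unknown stage: ", stage)
    .stage_ids[[stage]]
  } else as.integer(stage)
  m <- 2147483647 # 2^31 - 1
  as.integer(((seed %% m) * (2654435761 %% m) + id) %% m)
}

.check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite value in field '", name, "'", call. = FALSE)
  invisible(x)
}

# Benjamini-Hochberg step-up, kept as a named internal so tests can compare
# against a brute-force oracle; identical to p.adjust(method = "BH").
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
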