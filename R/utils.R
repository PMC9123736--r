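#' Nearest-rank percentile
#'
#' Percentile of a numeric vector under the nearest-rank definition: the
#' smallest element with at least `p` of the sample at or below it. Used for
#' all significance thresholds so that results are reproducible across
#' platforms, unlike interpolating quantile types.
#'
#' @param x numeric vector (non-empty, NAs dropped).
#' @param p probability in (0, 1].
#' @return a single numeric value, an element of `x`.
#' @export
quantile_nearest_rank <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("quantile_nearest_rank: empty input")
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]")
  xs <- sort(x)
  n <- length(xs)
  xs[pmin(pmax(ceiling(p * n), 1L), n)]
}

# Validate a DNA string: A/C/G/T/N only (either case). Returns the sequence
# uppercased; anything else is an error.
normalize_dna <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("seq must be a single character string")
  }
  up <- toupper(seq)
  if (grepl("[^ACGTN]", up)) {
    stop("sequence contains non-DNA characters (allowed: A, C, G, T, N)")
  }
  up
}

# Seed derivation: one run seed fans out to per-stage seeds so that stages
# are individually reproducible. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
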