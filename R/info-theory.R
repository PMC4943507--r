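#' Equal-width discretization of an expression vector
#'
#' Bins a real vector into `n_bins` equal-width intervals spanning
#' `[min, max]`; the maximum value is assigned to the top bin, and a
#' constant vector collapses to a single bin. Bin codes are 0-based,
#' in `[0, n_bins)`.
#'
#' Mutual information, symmetric uncertainty and all three filters operate
#' on these discretized codes; class labels are categorical already and are
#' used as-is.
#'
#' @param values Finite numeric vector (non-empty).
#' @param n_bins Number of bins (default 10, the classic filter-selection
#'   default for expression intensities).
#' @return Integer vector of bin codes with attribute `n_bins`.
#' @export
discretize <- function(values, n_bins = 10L) {
  if (length(values) == 0L) abort("cannot discretize an empty vector")
  if (!all(is.finite(values))) abort("values must be finite")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) abort("n_bins must be a positive integer")
  lo <- min(values); hi <- max(values)
  if (hi == lo || n_bins == 1L) {
    codes <- rep(0L, length(values))
  } else {
    width <- (hi - lo) / n_bins
    codes <- as.integer(floor((values - lo) / width))
    codes[codes >= n_bins] <- n_bins - 1L   # max value into top bin
  }
  structure(codes, n_bins = n_bins)
}

as_codes <- function(x) {
  # accept numeric (discretized on the fly not allowed here), integer codes,
  # factors and character labels
  if (is.factor(x)) return(as.integer(x) - 1L)
  if (is.character(x)) return(as.integer(factor(x)) - 1L)
  if (is.logical(x)) return(as.integer(x))
  as.integer(x)
}

#' Shannon entropy of a discrete vector, in bits
#'
#' `H(x) = -sum(p * log2(p))` over empirical symbol frequencies; empty cells
#' contribute zero (the `p log p -> 0` limit convention).
#'
#' @param x Integer codes, factor or character vector.
#' @return Entropy in bits, in `[0, log2(#symbols)]`.
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0L) abort("entropy of an empty vector is undefined")
  p <- tabulate(as_codes(x) + 1L)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Mutual information between two discrete vectors, in bits
#'
#' Computed as `I(x; y) = H(x) + H(y) - H(x, y)` on the empirical joint
#' table; symmetric, non-negative and bounded by `min(H(x), H(y))`.
#'
#' @param x,y Equal-length discrete vectors (codes, factor or character).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  cx <- as_codes(x); cy <- as_codes(y)
  if (length(cx) != length(cy)) abort("x and y must have equal length")
  if (length(cx) == 0L) abort("mutual information of empty vectors is undefined")
  kx <- max(cx) + 1L
  joint <- cx + kx * cy
  hx <- entropy_bits(cx); hy <- entropy_bits(cy); hxy <- entropy_bits(joint)
  max(hx + hy - hxy, 0)
}

#' Symmetric uncertainty between two discrete vectors
#'
#' `SU(a; b) = 2 I(a; b) / (H(a) + H(b))`, a normalized mutual information
#' in `[0, 1]`; defined as 0 when both entropies are zero (two constant
#' vectors carry no information either way).
#'
#' @param a,b Equal-length discrete vectors.
#' @return Symmetric uncertainty in `[0, 1]`.
#' @export
symmetric_uncertainty <- function(a, b) {
  ca <- as_codes(a); cb <- as_codes(b)
  if (length(ca) != length(cb)) abort("a and b must have equal length")
  ha <- entropy_bits(ca); hb <- entropy_bits(cb)
  if (ha + hb == 0) return(0)
  2 * mutual_information(ca, cb) / (ha + hb)
}

# Equal-width discretization of every column of a matrix at once; same
# binning rule as discretize(). Returns an integer matrix of 0-based codes.
discretize_matrix <- function(x, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  width <- (hi - lo) / n_bins
  codes <- floor(sweep(x, 2L, lo) / rep(pmax(width, .Machine$double.xmin),
                                        each = nrow(x)))
  codes[codes >= n_bins] <- n_bins - 1L
  codes[, width == 0] <- 0L
  storage.mode(codes) <- "integer"
  codes
}

ent_from_counts <- function(cnt, n) {
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

# Column-wise MI of every (discretized) feature against a label vector.
# x: numeric matrix (samples x features); y: codes/factor/character.
# Returns a numeric vector of MI scores in bits, one per column.
mi_profile <- function(x, y, n_bins = 10L) {
  cy <- as_codes(y)
  ky <- max(cy) + 1L
  n <- nrow(x)
  codes <- discretize_matrix(x, n_bins)
  hy <- ent_from_counts(tabulate(cy + 1L, ky), n)
  vapply(seq_len(ncol(codes)), function(j) {
    cx <- codes[, j]
    hx <- ent_from_counts(tabulate(cx + 1L, n_bins), n)
    hxy <- ent_from_counts(tabulate(cx + n_bins * cy + 1L, n_bins * ky), n)
    max(hx + hy - hxy, 0)
  }, numeric(1))
}

# Pairwise MI between discretized feature columns (used by mRMR).
feature_mi <- function(xi_codes, xj_codes) mutual_information(xi_codes, xj_codes)
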