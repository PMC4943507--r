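# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (double sums over contingency tables,
# all-ordered-pairs scans, O(n^2) rank comparisons) and share no code with
# the package implementations they check.

# entropy in bits from raw symbol vector, direct -sum p log2 p
oracle_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log2(p))
}

# mutual information by the double sum over the joint contingency table
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) s <- s + pij * log2(pij / (px[i] * py[j]))
    }
  }
  unname(s)
}

oracle_su <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (ha + hb == 0) return(0)
  2 * oracle_mi(a, b) / (ha + hb)
}

# equal-width binning re-derived with cut()
oracle_discretize <- function(v, n_bins) {
  if (min(v) == max(v) || n_bins == 1) return(rep(0L, length(v)))
  br <- seq(min(v), max(v), length.out = n_bins + 1)
  as.integer(cut(v, breaks = br, include.lowest = TRUE, right = FALSE,
                 labels = FALSE)) - 1L
}

# FCBF from scratch: full SU matrix over all ordered pairs, rank walk with
# retained-feature removers
oracle_fcbf <- function(x, y, delta, n_bins = 10L) {
  p <- ncol(x)
  dx <- lapply(seq_len(p), function(j) oracle_discretize(x[, j], n_bins))
  # scores are compared after rounding to 10 decimals — the package's
  # documented tie-stabilization policy
  su_c <- round(vapply(dx, function(c1) oracle_su(c1, y), numeric(1)), 10)
  su_ff <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) su_ff[i, j] <- round(oracle_su(dx[[i]], dx[[j]]), 10)
  }
  ord <- order(-su_c, seq_len(p))
  lst <- ord[su_c[ord] >= delta]
  if (length(lst) == 0) return(integer(0))
  survivors <- lst[1]
  for (fi in lst[-1]) {
    dominated <- FALSE
    for (fj in survivors) {
      if (su_c[fj] >= su_c[fi] && su_ff[fi, fj] >= su_c[fi]) {
        dominated <- TRUE
        break
      }
    }
    if (!dominated) survivors <- c(survivors, fi)
  }
  survivors
}

# mRMR from scratch: exhaustive per-step maximization of the incremental
# criterion over the whole pool
oracle_mrmr <- function(x, y, n, n_bins = 10L) {
  p <- ncol(x)
  dx <- lapply(seq_len(p), function(j) oracle_discretize(x[, j], n_bins))
  rel <- round(vapply(dx, function(c1) oracle_mi(c1, y), numeric(1)), 10)
  mi_ff <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    mi_ff[i, j] <- round(oracle_mi(dx[[i]], dx[[j]]), 10)
  }
  S <- integer(0)
  for (m in seq_len(n)) {
    cand <- setdiff(seq_len(p), S)
    scores <- round(vapply(cand, function(j) {
      if (m == 1) rel[j] else rel[j] - mean(mi_ff[S, j])
    }, numeric(1)), 10)
    S <- c(S, cand[order(-scores, cand)][1])
  }
  S
}

# binary ROC AUC by all-pairs comparison, ties counted half
oracle_auc <- function(is_pos, scores) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# does point s lie on the segment base + u*(nn - base), u in [0,1)?
on_segment <- function(s, base, nn, tol = 1e-9) {
  d <- nn - base
  r <- s - base
  if (all(abs(d) < tol)) return(all(abs(r) < tol))
  j <- which.max(abs(d))
  u <- r[j] / d[j]
  if (u < -tol || u >= 1) return(FALSE)
  all(abs(r - u * d) <= tol * pmax(1, abs(d)))
}

# a small random binary-labelled instance with a mix of informative,
# redundant and noise features (interesting for FCBF/mRMR)
random_binary_instance <- function(n = 40, p = 12, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
  x <- matrix(rnorm(n * p), n, p)
  # a few label-driven columns and one near-duplicate pair
  k_inf <- max(2L, p %/% 4L)
  for (j in seq_len(k_inf)) x[, j] <- x[, j] + 1.5 * y
  x[, k_inf + 1L] <- x[, 1L] + rnorm(n, sd = 0.05)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
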