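#' Rank features by mutual-information relevance to the class
#'
#' Scores every feature by the mutual information between its discretized
#' values and the class label, then ranks in descending order. Ties are
#' broken by ascending original feature position, so the ranking is fully
#' deterministic.
#'
#' @param data A data frame of numeric feature columns (an expression tibble
#'   is accepted: its `sample_id`/`class` columns are used or dropped as
#'   appropriate), or a numeric matrix.
#' @param labels Class label per row; defaults to `data$class` when present.
#' @param n Number of top features to return; default all.
#' @param n_bins Discretization bins (see [discretize()]).
#' @return A tibble with columns `feature` (name), `index` (original column
#'   position) and `score` (MI in bits), sorted by decreasing score.
#' @examples
#' sim <- simulate_expression(class_sizes = c(10, 10), n_features = 20, seed = 1)
#' rank_by_relevance(sim$data, n = 5)
#' @export
rank_by_relevance <- function(data, labels = NULL, n = NULL, n_bins = 10L) {
  fs <- feature_frame(data, labels)
  n_feat <- ncol(fs$x)
  if (is.null(n)) n <- n_feat
  if (n < 1L || n > n_feat) {
    abort(paste0("n must be in [1, ", n_feat, "], got ", n))
  }
  scores <- round(mi_profile(fs$x, fs$y, n_bins = n_bins), 10)
  ord <- order(-scores, seq_along(scores))
  tibble(
    feature = colnames(fs$x)[ord],
    index = ord,
    score = scores[ord]
  )[seq_len(n), ]
}

#' Fast correlation-based filter (FCBF) selection
#'
#' Ranks features by symmetric uncertainty with the class, `SU(c; f)`, in
#' descending order, drops those below the threshold `delta`, then walks the
#' surviving list from the top: a lower-ranked feature `f_i` is removed when
#' some retained, better-ranked `f_j` satisfies both
#' `SU(c; f_j) >= SU(c; f_i)` and `SU(f_i; f_j) >= SU(f_i; c)` — that is,
#' `f_j` predicts the class at least as well and `f_i` resembles `f_j` more
#' than it resembles the class.
#'
#' @inheritParams rank_by_relevance
#' @param delta Relevance threshold on `SU(c; f)`, `>= 0`.
#' @return A tibble of survivors in rank order with columns `feature`,
#'   `index` and `score` (`SU(c; f)`), carrying attributes `method = "fcbf"`
#'   and `delta`.
#' @export
fcbf_select <- function(data, labels = NULL, delta = 0, n_bins = 10L) {
  if (delta < 0) abort("delta must be >= 0")
  fs <- feature_frame(data, labels)
  codes <- discretize_matrix(fs$x, n_bins)
  cy <- as_codes(fs$y)
  su_c <- round(unname(apply(codes, 2L, symmetric_uncertainty, b = cy)), 10)
  ord <- order(-su_c, seq_along(su_c))
  keep <- ord[su_c[ord] >= delta]
  if (length(keep) == 0L) {
    abort(paste0("no feature reaches delta = ", format(delta),
                 "; maximum observed SU(c; f) is ", format(max(su_c))))
  }
  retained <- logical(length(keep))
  retained[1] <- TRUE
  for (i in seq_along(keep)[-1]) {
    fi <- keep[i]
    removed <- FALSE
    for (j in which(retained)) {
      fj <- keep[j]
      # list is SU(c;f)-sorted so SU(c;fj) >= SU(c;fi) holds by position
      if (round(symmetric_uncertainty(codes[, fi], codes[, fj]), 10) >= su_c[fi]) {
        removed <- TRUE
        break
      }
    }
    retained[i] <- !removed
  }
  idx <- keep[retained]
  structure(
    tibble(feature = colnames(fs$x)[idx], index = idx, score = su_c[idx]),
    method = "fcbf", delta = delta
  )
}

#' FCBF tuned to a target signature size
#'
#' FCBF controls its output size only through the threshold `delta`, which
#' acts on the grid of observed `SU(c; f)` values. This helper binary-searches
#' that grid for the largest survivor count that does not exceed `n`. When
#' even `delta = 0` yields fewer than `n` survivors (heavy redundancy), the
#' `delta = 0` result is returned with attribute `short = TRUE`.
#'
#' @inheritParams rank_by_relevance
#' @param n Target number of features, in `[1, n_features]`.
#' @return As [fcbf_select()], with attributes `short` and `delta`.
#' @export
fcbf_select_n <- function(data, labels = NULL, n, n_bins = 10L) {
  fs <- feature_frame(data, labels)
  n_feat <- ncol(fs$x)
  if (n < 1L || n > n_feat) abort(paste0("n must be in [1, ", n_feat, "]"))
  base <- fcbf_select(fs$x, fs$y, delta = 0, n_bins = n_bins)
  if (nrow(base) <= n) {
    attr(base, "short") <- nrow(base) < n
    return(base)
  }
  # survivor count is non-increasing in delta; search the sorted grid of
  # distinct SU(c;f) values for the largest count <= n
  grid <- sort(unique(base$score))   # survivors' SU values cover the useful range
  lo <- 1L; hi <- length(grid)
  best <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    res <- fcbf_select(fs$x, fs$y, delta = grid[mid], n_bins = n_bins)
    if (nrow(res) <= n) {
      best <- res
      hi <- mid - 1L    # smaller delta => more survivors, still <= n?
    } else {
      lo <- mid + 1L
    }
  }
  attr(best, "short") <- nrow(best) < n
  best
}

#' Minimum-redundancy maximum-relevance (mRMR) selection
#'
#' Greedy forward selection over a candidate pool of the `window` most
#' class-relevant features. The first pick maximizes the relevance
#' `phi(f, c)` (mutual information with the class); each subsequent m-th
#' pick maximizes
#' `phi(f_j, c) - (1/(m-1)) * sum_{f_i in S} phi(f_i, f_j)`
#' over pool members not yet selected, penalizing redundancy with the
#' already-selected set S. Ties break to the lower original feature index.
#'
#' @inheritParams rank_by_relevance
#' @param n Number of features to select.
#' @param window Candidate-pool size for the linear forward search
#'   (default 50); use `Inf` or `>= n_features` for a full search.
#' @return A tibble of selected features in selection order with columns
#'   `feature`, `index` and `score` (the criterion value at selection time),
#'   attribute `method = "mrmr"`.
#' @export
mrmr_select <- function(data, labels = NULL, n, window = 50L, n_bins = 10L) {
  fs <- feature_frame(data, labels)
  n_feat <- ncol(fs$x)
  if (n < 1L || n > n_feat) abort(paste0("n must be in [1, ", n_feat, "]"))
  w <- min(as.numeric(window), n_feat)
  if (n > w) abort(paste0("n (", n, ") exceeds the candidate pool size (", w, ")"))
  codes <- discretize_matrix(fs$x, n_bins)
  cy <- as_codes(fs$y)
  rel <- round(mi_profile(fs$x, cy, n_bins = n_bins), 10)
  pool <- order(-rel, seq_along(rel))[seq_len(w)]
  # pairwise MI among pool members, computed lazily and cached
  pw <- matrix(NA_real_, w, w)
  pair_mi <- function(a, b) {
    if (is.na(pw[a, b])) {
      v <- round(mutual_information(codes[, pool[a]], codes[, pool[b]]), 10)
      pw[a, b] <<- v; pw[b, a] <<- v
    }
    pw[a, b]
  }
  selected <- integer(0)       # positions within pool
  crit <- numeric(0)
  avail <- seq_len(w)
  for (m in seq_len(n)) {
    if (m == 1L) {
      scores <- rel[pool[avail]]
    } else {
      scores <- round(vapply(avail, function(a) {
        red <- mean(vapply(selected, function(s) pair_mi(s, a), numeric(1)))
        rel[pool[a]] - red
      }, numeric(1)), 10)
    }
    best <- avail[order(-scores, pool[avail])][1]
    selected <- c(selected, best)
    crit <- c(crit, scores[match(best, avail)])
    avail <- setdiff(avail, best)
  }
  idx <- pool[selected]
  structure(
    tibble(feature = colnames(fs$x)[idx], index = idx, score = crit),
    method = "mrmr", window = w
  )
}

#' Set-level relevance and redundancy diagnostics
#'
#' `subset_relevance()` is the mean mutual information between the selected
#' features and the class, `D(S, c) = (1/|S|) sum phi(f_i, c)`;
#' `subset_redundancy()` is the mean pairwise mutual information within the
#' set, `R(S) = (1/|S|^2) sum phi(f_i, f_j)` (self-pairs included, as the
#' `1/|S|^2` normalization implies). These score a finished signature; the
#' greedy search itself uses the incremental criterion of [mrmr_select()].
#'
#' @inheritParams rank_by_relevance
#' @param features Character names or integer positions of the subset S.
#' @return A single number (bits).
#' @export
subset_relevance <- function(data, labels = NULL, features, n_bins = 10L) {
  fs <- feature_frame(data, labels)
  idx <- resolve_features(fs$x, features)
  cy <- as_codes(fs$y)
  mean(vapply(idx, function(i)
    mutual_information(discretize(fs$x[, i], n_bins), cy), numeric(1)))
}

#' @rdname subset_relevance
#' @export
subset_redundancy <- function(data, labels = NULL, features, n_bins = 10L) {
  fs <- feature_frame(data, labels)
  idx <- resolve_features(fs$x, features)
  codes <- lapply(idx, function(i) discretize(fs$x[, i], n_bins))
  s <- length(idx)
  total <- 0
  for (i in seq_len(s)) for (j in seq_len(s)) {
    total <- total + mutual_information(codes[[i]], codes[[j]])
  }
  total / s^2
}

resolve_features <- function(x, features) {
  if (is.numeric(features)) return(as.integer(features))
  idx <- match(features, colnames(x))
  if (anyNA(idx)) {
    abort(paste0("unknown feature(s): ",
                 paste(features[is.na(idx)], collapse = ", ")))
  }
  idx
}

# Normalize (data, labels) into a numeric matrix + label vector. Accepts an
# expression tibble (labels from its class column), a plain data frame of
# features, or a matrix.
feature_frame <- function(data, labels = NULL) {
  if (is.matrix(data)) {
    x <- data
  } else {
    data <- as_tibble(data)
    if (is.null(labels) && "class" %in% names(data)) labels <- data$class
    drop <- intersect(c("sample_id", "class"), names(data))
    x <- as.matrix(data[setdiff(names(data), drop)])
  }
  if (is.null(labels)) abort("labels are required (none found in `data`)")
  if (length(labels) != nrow(x)) abort("labels length must match row count")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  list(x = x, y = labels)
}
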