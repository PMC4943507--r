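#' One-versus-all binary tasks
#'
#' `binarize()` restricts a multiclass dataset to one binary sub-problem:
#' samples of `target_class` become the positive class and every other
#' sample the negative class. Sample count and order are preserved. The
#' result is a `binary_task` object holding the feature matrix, a
#' positive/negative label factor, the original class name and a provenance
#' tag per sample (`"original"`; SMOTE appends `"synthetic"` rows).
#'
#' @param data A validated expression tibble (see [as_expression_dataset()]).
#' @param target_class Class to treat as positive.
#' @return A `binary_task` object.
#' @export
binarize <- function(data, target_class) {
  data <- as_expression_dataset(data)
  if (!target_class %in% data$class) {
    abort(paste0("unknown class: ", target_class))
  }
  new_binary_task(
    x = dataset_matrix(data),
    positive = data$class == target_class,
    positive_class = target_class
  )
}

new_binary_task <- function(x, positive, positive_class,
                            provenance = rep("original", nrow(x))) {
  structure(
    list(
      x = x,
      y = factor(ifelse(positive, "pos", "neg"), levels = c("neg", "pos")),
      positive_class = positive_class,
      provenance = provenance
    ),
    class = "binary_task"
  )
}

#' @export
print.binary_task <- function(x, ...) {
  cat("<binary_task> positive class:", x$positive_class, "\n")
  cat("  ", sum(x$y == "pos"), "positive /", sum(x$y == "neg"),
      "negative samples,", ncol(x$x), "features\n")
  if (any(x$provenance == "synthetic")) {
    cat("  ", sum(x$provenance == "synthetic"), "synthetic (SMOTE) samples\n")
  }
  invisible(x)
}

task_counts <- function(task) {
  c(pos = sum(task$y == "pos"), neg = sum(task$y == "neg"))
}

# majority / minority sizes of a task
task_sizes <- function(task) {
  n <- task_counts(task)
  list(S_M = max(n), S_m = min(n),
       majority = if (n[["neg"]] >= n[["pos"]]) "neg" else "pos")
}

#' Random undersampling of the majority class
#'
#' Removes exactly `n_remove` majority-class samples, chosen uniformly at
#' random without replacement; minority samples are never touched. With
#' `n_remove = S_M - S_m` the classes end up equal-sized. Deterministic for
#' a fixed `seed`.
#'
#' @param task A `binary_task`.
#' @param n_remove Number of majority samples to drop, in
#'   `[0, S_M - S_m]` (removal never undershoots balance).
#' @param seed Integer seed.
#' @return The undersampled `binary_task`.
#' @export
random_undersample <- function(task, n_remove, seed = 0L) {
  stopifnot(inherits(task, "binary_task"))
  sz <- task_sizes(task)
  if (n_remove < 0 || n_remove > sz$S_M - sz$S_m) {
    abort(paste0("n_remove must be in [0, ", sz$S_M - sz$S_m,
                 "] (majority - minority), got ", n_remove))
  }
  if (n_remove == 0) return(task)
  maj_idx <- which(task$y == sz$majority)
  drop <- with_task_seed(seed, sample(maj_idx, n_remove))
  keep <- setdiff(seq_len(nrow(task$x)), drop)
  new_binary_task(task$x[keep, , drop = FALSE],
                  task$y[keep] == "pos",
                  task$positive_class,
                  provenance = task$provenance[keep])
}

#' SMOTE oversampling of the minority class
#'
#' Appends `n_new` synthetic minority samples. Each synthetic point is
#' `x + u * (x_nn - x)` with `u ~ Uniform[0, 1)`, where the base `x` is a
#' minority sample chosen round-robin (so per-base synthetic counts differ
#' by at most one) and `x_nn` is one of its `k` nearest minority neighbours
#' by Euclidean distance in the task's current feature space. `k` is capped
#' at minority size minus one. Majority samples are never touched.
#' Synthetic rows are tagged `"synthetic"` and count as minority samples
#' (so later oversampling rounds may interpolate from them).
#'
#' @param task A `binary_task` with at least 2 minority samples.
#' @param n_new Number of synthetic samples to generate.
#' @param k Number of nearest neighbours (default 5).
#' @param seed Integer seed.
#' @return The oversampled `binary_task`.
#' @export
smote_oversample <- function(task, n_new, k = 5L, seed = 0L) {
  stopifnot(inherits(task, "binary_task"))
  if (n_new < 0) abort("n_new must be >= 0")
  if (n_new == 0) return(task)
  sz <- task_sizes(task)
  minority <- setdiff(c("neg", "pos"), sz$majority)
  min_idx <- which(task$y == minority)
  n_min <- length(min_idx)
  if (n_min < 2L) {
    abort(paste0("SMOTE needs at least 2 minority samples to interpolate; class ",
                 task$positive_class, " task has ", n_min))
  }
  k <- min(as.integer(k), n_min - 1L)
  xm <- task$x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  # k nearest minority neighbours of each minority sample (ties: lower row)
  nn <- t(apply(d, 1L, function(row) {
    order(row, seq_along(row))[2:(k + 1L)]
  }))
  if (k == 1L) nn <- matrix(nn, ncol = 1L)
  synth <- with_task_seed(seed, {
    out <- matrix(0, n_new, ncol(task$x))
    for (i in seq_len(n_new)) {
      b <- ((i - 1L) %% n_min) + 1L            # round-robin base
      nb <- nn[b, sample.int(k, 1L)]
      u <- runif(1)
      out[i, ] <- xm[b, ] + u * (xm[nb, ] - xm[b, ])
    }
    out
  })
  colnames(synth) <- colnames(task$x)
  rownames(synth) <- paste0("synthetic_", task$positive_class, "_",
                            seq_len(n_new) + sum(task$provenance == "synthetic"))
  new_binary_task(
    rbind(task$x, synth),
    c(task$y == "pos", rep(minority == "pos", n_new)),
    task$positive_class,
    provenance = c(task$provenance, rep("synthetic", n_new))
  )
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_task_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
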