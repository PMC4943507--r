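#' Stratified cross-validation folds
#'
#' Spreads each class's samples across `k` folds as evenly as possible
#' (shuffled within class under `seed`, then dealt round-robin). With
#' `k = "auto"` the fold count follows the small-class rule: 3 folds when
#' the smallest class has fewer than 10 samples, otherwise 10. A class
#' smaller than the fold count triggers a fall back to leave-one-out with a
#' warning, since such a class cannot appear in every fold.
#'
#' @param labels Class label per sample.
#' @param k Number of folds, or `"auto"`.
#' @param seed Integer seed.
#' @return A list of `k` elements, each `list(train =, test =)` integer
#'   index vectors; test sets are disjoint and exhaustive.
#' @export
stratified_folds <- function(labels, k = "auto", seed = 0L) {
  labels <- as.character(labels)
  n <- length(labels)
  min_class <- min(table(labels))
  if (identical(k, "auto")) {
    k <- if (min_class < 10) 3L else 10L
    if (min_class < k) {
      warning("smallest class (", min_class,
              " samples) is below the fold count; falling back to leave-one-out")
      k <- n
    }
  } else {
    k <- as.integer(k)
    if (k < 2L) abort("need at least 2 folds")
    if (min_class < k && k < n) {
      abort(paste0("a class has only ", min_class, " samples, fewer than k = ",
                   k, " folds; use k = \"auto\""))
    }
  }
  fold_of <- integer(n)
  if (k == n) {
    fold_of <- seq_len(n)   # leave-one-out
  } else {
    with_task_seed(seed, {
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Classification accuracy as a percentage
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return `100 * #correct / n`.
#' @export
accuracy_pct <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  100 * mean(as.character(y_true) == as.character(y_pred))
}

# rank-based binary AUC with ties counted half (Mann-Whitney form)
binary_auc <- function(is_pos, scores) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged one-vs-rest AUC, in percent
#'
#' Computes a rank-based ROC AUC (ties counted half) for each class against
#' the rest using that class's confidence column, then averages unweighted
#' over the classes present in `y_true`. Macro averaging weights minority
#' classes equally with majority classes — the point of using AUC on
#' imbalanced data. Classes with a confidence column but no true samples
#' are skipped with a warning.
#'
#' @param y_true Class label per sample.
#' @param confidence A numeric matrix or data frame, one column per class
#'   (named by class, or `conf_<class>` as produced by
#'   [predict.iefs_ensemble()]).
#' @return Macro AUC in `[0, 100]`; attribute `per_class` holds the
#'   per-class AUCs (in percent).
#' @export
multiclass_auc <- function(y_true, confidence) {
  y_true <- as.character(y_true)
  conf <- as.matrix(as.data.frame(confidence))
  cls <- colnames(conf)
  if (is.null(cls)) abort("confidence matrix must have class column names")
  cls_clean <- sub("^conf_", "", cls)
  colnames(conf) <- cls_clean
  present <- cls_clean %in% y_true
  if (any(!present)) {
    warning("no true samples for class(es): ",
            paste(cls_clean[!present], collapse = ", "), "; skipped")
  }
  per <- vapply(cls_clean[present], function(cl) {
    100 * binary_auc(y_true == cl, conf[, cl])
  }, numeric(1))
  structure(mean(per), per_class = per)
}

#' Per-class recall (sensitivity), in percent
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return A named numeric vector, one entry per class present in `y_true`.
#' @export
per_class_recall <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  vapply(sort(unique(y_true)), function(cl) {
    100 * mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
}

#' Cross-validated evaluation of one configuration
#'
#' Runs stratified cross-validation: the ensemble is fitted on each
#' training fold only (sampling and selection never see the test fold,
#' which is evaluated in its original, unresampled distribution) and scored
#' on the held-out fold. Accuracy and macro AUC are means over folds.
#'
#' @param data A validated expression tibble.
#' @param config A [run_config()].
#' @param folds Optional precomputed folds from [stratified_folds()];
#'   default derives them from `config$cv_folds` and `config$seed`.
#' @return A one-row tibble with accuracy, AUC (both %), the per-class
#'   recall (list-column) and the configuration fields.
#' @export
iefs_cv <- function(data, config = run_config(), folds = NULL) {
  data <- as_expression_dataset(data)
  if (is.null(folds)) {
    folds <- stratified_folds(data$class, k = config$cv_folds,
                              seed = config$seed)
  }
  classes <- sort(unique(data$class))
  acc <- auc <- numeric(length(folds))
  rec <- matrix(NA_real_, length(folds), length(classes),
                dimnames = list(NULL, classes))
  for (f in seq_along(folds)) {
    cfg <- config
    cfg$seed <- config$seed + 100000L * f
    fit <- iefs_fit(data[folds[[f]]$train, ], cfg)
    test <- data[folds[[f]]$test, ]
    pred <- predict(fit, test)
    acc[f] <- accuracy_pct(test$class, pred$predicted)
    confs <- as.matrix(pred[paste0("conf_", fit$class_order)])
    colnames(confs) <- fit$class_order
    auc[f] <- suppressWarnings(multiclass_auc(test$class, confs))
    r <- per_class_recall(test$class, pred$predicted)
    rec[f, names(r)] <- r
  }
  mean_rec <- colMeans(rec, na.rm = TRUE)
  tibble(
    selector = config$selector, sampler = config$sampler,
    T = config$T_steps, n_features = config$n_features,
    classifier = config$classifier, fold_scheme = length(folds),
    accuracy = mean(acc), auc = mean(auc),
    per_class_recall = list(mean_rec),
    seed = config$seed
  )
}

#' Benchmark grid over selectors, samplers and signature sizes
#'
#' Evaluates every combination of the supplied selectors, samplers, step
#' counts, signature sizes and classifiers by stratified cross-validation
#' (one shared fold split per dataset), and appends an all-features
#' baseline row per classifier (no selection, no sampling). Failures in a
#' single cell are recorded in that row's `error` column and the run
#' continues.
#'
#' @param data A validated expression tibble.
#' @param selectors,samplers,T_steps,n_features,classifiers Grid axes;
#'   defaults mirror the classic design (signature sizes 5 to 100 in steps
#'   of 5; `T` of 1 and 4 for the ranking selector, 1 for FCBF/mRMR).
#' @param cv_folds `"auto"` or an integer.
#' @param seed Base seed; each cell derives its own sub-seed.
#' @param baseline Include the all-features baseline rows?
#' @param progress Print one line per cell?
#' @return An `iefs_benchmark` tibble: one row per grid cell with accuracy,
#'   macro AUC (both %), per-class recall and the cell's configuration.
#' @export
iefs_benchmark <- function(data,
                           selectors = c("ranking", "fcbf", "mrmr"),
                           samplers = c("none", "undersample", "oversample"),
                           T_steps = c(1L, 4L),
                           n_features = seq(5L, 100L, by = 5L),
                           classifiers = "knn",
                           cv_folds = "auto", seed = 0L,
                           baseline = TRUE, progress = FALSE) {
  data <- as_expression_dataset(data)
  n_feat_avail <- length(dataset_features(data))
  n_features <- n_features[n_features <= n_feat_avail]
  folds <- stratified_folds(data$class, k = cv_folds, seed = seed)
  grid <- tidyr::expand_grid(
    selector = selectors, sampler = samplers, T = T_steps,
    n_features = n_features, classifier = classifiers
  )
  # multi-step alternation only concerns the size-controlled ranking
  # selector; FCBF and mRMR run with T = 1
  grid <- dplyr::filter(grid, .data$selector == "ranking" | .data$T == 1L)
  rows <- vector("list", nrow(grid) + length(classifiers) * baseline)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- run_config(selector = g$selector, sampler = g$sampler,
                      T_steps = g$T, n_features = g$n_features,
                      classifier = g$classifier, cv_folds = cv_folds,
                      seed = seed + 13L * i)
    if (progress) {
      message(sprintf("[%d/%d] %s + %s, T=%d, N_n=%d, %s", i, nrow(grid),
                      g$selector, g$sampler, g$T, g$n_features, g$classifier))
    }
    rows[[i]] <- tryCatch(
      dplyr::mutate(iefs_cv(data, cfg, folds = folds), error = NA_character_),
      error = function(e) {
        dplyr::mutate(g, fold_scheme = length(folds),
                      accuracy = NA_real_, auc = NA_real_,
                      per_class_recall = list(NULL), seed = cfg$seed,
                      error = conditionMessage(e))
      }
    )
  }
  if (baseline) {
    for (j in seq_along(classifiers)) {
      cfg <- run_config(selector = "ranking", sampler = "none", T_steps = 1L,
                        n_features = n_feat_avail, classifier = classifiers[j],
                        cv_folds = cv_folds, seed = seed)
      base <- iefs_cv(data, cfg, folds = folds)
      base$selector <- "baseline-all-features"
      base$error <- NA_character_
      rows[[nrow(grid) + j]] <- base
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iefs_benchmark", class(out))
  out
}

#' Write a benchmark report as TSV
#'
#' The list-column of per-class recalls is flattened to
#' `class=recall;class=recall;...` so the report is a plain delimited
#' table.
#'
#' @param report An [iefs_benchmark()] tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(report, path) {
  flat <- report
  flat$per_class_recall <- vapply(report$per_class_recall, function(r) {
    if (is.null(r)) return(NA_character_)
    paste(sprintf("%s=%.4f", names(r), r), collapse = ";")
  }, character(1))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
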