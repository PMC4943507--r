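#' Iteration schedule for alternating sampling and selection
#'
#' The framework bridges two gaps over `T` steps: the sample gap between the
#' majority and minority class sizes (`S_M - S_m`) and the feature gap
#' between the full feature count and the target signature size
#' (`N_M - N_n`). The per-step intervals are the even splits
#' `M_i = (S_M - S_m) / T` and `N_i = (N_M - N_n) / T`, realised as integer
#' floors with the last step absorbing the rounding remainder so the sums
#' bridge each gap exactly.
#'
#' @param S_M Majority-class size (`>= S_m`).
#' @param S_m Minority-class size (`>= 1`).
#' @param N_M Total number of features.
#' @param N_n Target number of features (`1 <= N_n <= N_M`).
#' @param T_steps Number of iterations `T >= 1`.
#' @return A list with integer vectors `M` and `N` of length `T`, class
#'   `iefs_schedule`.
#' @examples
#' build_schedule(S_M = 30, S_m = 10, N_M = 1000, N_n = 30, T_steps = 4)
#' @export
build_schedule <- function(S_M, S_m, N_M, N_n, T_steps = 1L) {
  if (S_m < 1 || S_M < S_m) abort("need S_M >= S_m >= 1")
  if (N_n < 1 || N_M < N_n) abort("need N_M >= N_n >= 1")
  if (T_steps < 1) abort("need T >= 1")
  split_gap <- function(gap, T_steps) {
    base <- rep(gap %/% T_steps, T_steps)
    base[T_steps] <- base[T_steps] + gap %% T_steps
    as.integer(base)
  }
  structure(
    list(
      M = split_gap(as.integer(S_M - S_m), as.integer(T_steps)),
      N = split_gap(as.integer(N_M - N_n), as.integer(T_steps)),
      T = as.integer(T_steps),
      S_M = as.integer(S_M), S_m = as.integer(S_m),
      N_M = as.integer(N_M), N_n = as.integer(N_n)
    ),
    class = "iefs_schedule"
  )
}

#' @export
print.iefs_schedule <- function(x, ...) {
  cat("<iefs_schedule> T =", x$T, "\n")
  cat("  sample intervals M:", paste(x$M, collapse = " "),
      sprintf("(gap %d)\n", x$S_M - x$S_m))
  cat("  feature intervals N:", paste(x$N, collapse = " "),
      sprintf("(%d -> %d features)\n", x$N_M, x$N_n))
  invisible(x)
}

#' Run configuration
#'
#' Bundles the tunables of one framework run: which filter selector, which
#' sampler, how many alternation steps `T`, the target signature size, the
#' classifier, and the seeds/neighbour counts behind them.
#'
#' @param selector `"ranking"`, `"fcbf"` or `"mrmr"`.
#' @param sampler `"none"`, `"undersample"` or `"oversample"` (SMOTE).
#' @param T_steps Alternation steps `T` (default 1).
#' @param n_features Target signature size `N_n` per class (default 30).
#' @param classifier `"knn"` or `"svm"`.
#' @param knn_k Neighbours for KNN (default 3).
#' @param smote_k Neighbours for SMOTE (default 5).
#' @param mrmr_window Candidate-pool size for mRMR (default 50).
#' @param n_bins Discretization bins for the information measures.
#' @param seed Base seed; per-class sub-seeds are derived from it.
#' @param cv_folds `"auto"` or an integer fold count, used by evaluation
#'   helpers.
#' @param zscore Standardise genes before distance computations?
#' @return A `run_config` list.
#' @export
run_config <- function(selector = c("ranking", "fcbf", "mrmr"),
                       sampler = c("none", "undersample", "oversample"),
                       T_steps = 1L, n_features = 30L,
                       classifier = c("knn", "svm"),
                       knn_k = 3L, smote_k = 5L, mrmr_window = 50L,
                       n_bins = 10L, seed = 0L, cv_folds = "auto",
                       zscore = FALSE) {
  selector <- arg_match(selector)
  sampler <- arg_match(sampler)
  classifier <- arg_match(classifier)
  stopifnot(T_steps >= 1, n_features >= 1, knn_k >= 1, smote_k >= 1)
  structure(
    list(selector = selector, sampler = sampler, T_steps = as.integer(T_steps),
         n_features = as.integer(n_features), classifier = classifier,
         knn_k = as.integer(knn_k), smote_k = as.integer(smote_k),
         mrmr_window = mrmr_window, n_bins = as.integer(n_bins),
         seed = as.integer(seed), cv_folds = cv_folds, zscore = isTRUE(zscore)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$selector, "+", x$sampler,
      sprintf("| T = %d, N_n = %d, %s | seed %d\n",
              x$T_steps, x$n_features, x$classifier, x$seed))
  invisible(x)
}

# select top-n features of a task under the configured selector; returns
# a tibble (feature, index, score) with possible `short` attribute
select_features <- function(task, config, n) {
  switch(config$selector,
    ranking = rank_by_relevance(task$x, task$y, n = n, n_bins = config$n_bins),
    mrmr = mrmr_select(task$x, task$y, n = n,
                       window = max(config$mrmr_window, n),
                       n_bins = config$n_bins),
    fcbf = fcbf_select_n(task$x, task$y, n = n, n_bins = config$n_bins)
  )
}

#' Fit one binary signature model by iterative sampling and selection
#'
#' For each of the `T` schedule steps: (a) the sampler moves the class sizes
#' toward balance by the step's sample interval `M_i` (undersampling removes
#' `M_i` majority samples; oversampling adds `M_i` synthetic minority
#' samples; `"none"` skips); (b) the configured filter retains the top
#' `current_features - N_i` features, discarding the rest from the working
#' task, so later sampling distances are computed in the surviving feature
#' space only. After `T` steps the classes are balanced (when a sampler is
#' active) and exactly `N_n` features remain (ranking/mRMR; FCBF may return
#' fewer, flagged `short`). A binary classifier is then trained on the
#' final filtered, sampled data.
#'
#' @param task A `binary_task` (see [binarize()]).
#' @param config A [run_config()].
#' @return A `signature_model`: selected features in rank order, the trained
#'   classifier, the schedule used and the positive class name.
#' @export
iefs_fit_binary <- function(task, config = run_config()) {
  stopifnot(inherits(task, "binary_task"), inherits(config, "run_config"))
  sz <- task_sizes(task)
  n_feat <- ncol(task$x)
  if (config$n_features > n_feat) {
    abort(paste0("n_features (", config$n_features, ") exceeds available features (",
                 n_feat, ")"))
  }
  sched <- build_schedule(sz$S_M, sz$S_m, n_feat, config$n_features,
                          config$T_steps)
  short <- FALSE
  for (i in seq_len(sched$T)) {
    if (config$sampler == "undersample" && sched$M[i] > 0) {
      task <- random_undersample(task, sched$M[i], seed = config$seed + 1000L * i)
    } else if (config$sampler == "oversample" && sched$M[i] > 0) {
      task <- smote_oversample(task, sched$M[i], k = config$smote_k,
                               seed = config$seed + 1000L * i)
    }
    n_keep <- ncol(task$x) - sched$N[i]
    if (n_keep < ncol(task$x)) {
      sel <- tryCatch(
        select_features(task, config, n_keep),
        error = function(e) {
          abort(paste0("feature selection failed at step ", i, " (class ",
                       task$positive_class, "): ", conditionMessage(e)))
        }
      )
      if (nrow(sel) == 0L) {
        abort(paste0("selector returned an empty set at step ", i))
      }
      short <- short || isTRUE(attr(sel, "short"))
      task$x <- task$x[, sel$index, drop = FALSE]
    }
  }
  clf <- train_binary_classifier(task, config)
  structure(
    list(
      positive_class = task$positive_class,
      selected_features = colnames(task$x),
      short = short,
      classifier = clf,
      schedule = sched,
      config = config,
      n_train = nrow(task$x)
    ),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> class", x$positive_class, "|",
      length(x$selected_features), "features |", x$config$classifier, "\n")
  if (x$short) cat("  (short signature: FCBF redundancy removal undershot the target)\n")
  invisible(x)
}

train_binary_classifier <- function(task, config) {
  if (config$classifier == "knn") {
    list(
      type = "knn",
      k = min(config$knn_k, nrow(task$x)),
      train_x = task$x,
      train_y = task$y
    )
  } else {
    fit <- with_task_seed(config$seed, {
      e1071::svm(x = task$x, y = task$y, kernel = "linear", scale = FALSE)
    })
    list(type = "svm", fit = fit)
  }
}

# score new samples with a trained binary classifier; returns positive-class
# confidence in [0, 1]; a vote is confidence > 0.5
score_binary <- function(clf, newx) {
  if (clf$type == "knn") {
    pred <- class::knn(train = clf$train_x, test = newx, cl = clf$train_y,
                       k = clf$k, prob = TRUE)
    p_win <- attr(pred, "prob")
    ifelse(pred == "pos", p_win, 1 - p_win)
  } else {
    dvm <- attr(predict(clf$fit, newx, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1]
    # e1071 names the column "<first>/<second>"; a positive value favours
    # the first class. Orient toward "pos", then squash monotonically into
    # [0, 1] so 0.5 is the decision boundary.
    if (!startsWith(colnames(dvm)[1], "pos")) dv <- -dv
    stats::plogis(dv)
  }
}

#' Fit the one-versus-all ensemble
#'
#' Builds one binary signature model per class with [iefs_fit_binary()],
#' each on its own binarized task and its own derived sub-seed
#' (`seed + class position`), so adding a class never perturbs the others.
#'
#' @param data A validated expression tibble.
#' @param config A [run_config()].
#' @return An `iefs_ensemble` with one member per class.
#' @examples
#' sim <- simulate_expression(class_sizes = c(20, 10), n_features = 50,
#'                            effect_size = 3, seed = 1)
#' fit <- iefs_fit(sim$data, run_config(n_features = 5))
#' predict(fit, sim$data)
#' @export
iefs_fit <- function(data, config = run_config()) {
  data <- as_expression_dataset(data)
  zstats <- NULL
  if (config$zscore) {
    m <- dataset_matrix(data)
    zstats <- list(center = colMeans(m), scale = apply(m, 2L, stats::sd))
    data <- zscore_dataset(data)
  }
  classes <- sort(unique(data$class))
  members <- lapply(seq_along(classes), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    task <- binarize(data, classes[k])
    tryCatch(
      iefs_fit_binary(task, cfg),
      error = function(e) {
        abort(paste0("fitting class ", classes[k], " failed: ",
                     conditionMessage(e)))
      }
    )
  })
  names(members) <- classes
  structure(
    list(
      members = members,
      class_order = classes,
      class_sizes = as.integer(table(factor(data$class, levels = classes))),
      tie_policy = "confidence, then training class size, then class order",
      config = config,
      zscore_stats = zstats
    ),
    class = "iefs_ensemble"
  )
}

#' @export
print.iefs_ensemble <- function(x, ...) {
  cat("<iefs_ensemble>", length(x$members), "one-vs-all members |",
      x$config$selector, "+", x$config$sampler,
      sprintf("| T = %d, N_n = %d, %s\n", x$config$T_steps,
              x$config$n_features, x$config$classifier))
  for (m in x$members) {
    cat(sprintf("  %-12s %3d features%s\n", m$positive_class,
                length(m$selected_features), if (m$short) " (short)" else ""))
  }
  invisible(x)
}

#' Predict classes by majority vote of the one-vs-all members
#'
#' Each member projects the samples onto its own signature and returns a
#' positive-class confidence; a member votes for its class when its
#' confidence exceeds 0.5. The class with the most votes wins. Ties —
#' including the zero-vote case — fall back to the highest confidence,
#' then the largest training class, then canonical class order.
#'
#' @param object An `iefs_ensemble`.
#' @param newdata An expression tibble (or plain data frame / matrix of
#'   features) containing every feature used by any member.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `predicted`, `votes`, `tie_broken`,
#'   and one `conf_<class>` confidence column per class.
#' @export
predict.iefs_ensemble <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    x <- newdata
    ids <- rownames(x) %||% paste0("sample_", seq_len(nrow(x)))
  } else {
    newdata <- as_tibble(newdata)
    ids <- if ("sample_id" %in% names(newdata)) {
      as.character(newdata$sample_id)
    } else {
      paste0("sample_", seq_len(nrow(newdata)))
    }
    x <- as.matrix(newdata[setdiff(names(newdata), c("sample_id", "class"))])
  }
  storage.mode(x) <- "double"
  needed <- unique(unlist(lapply(object$members, `[[`, "selected_features")))
  missing_f <- setdiff(needed, colnames(x))
  if (length(missing_f)) {
    abort(paste0("input is missing required feature(s): ",
                 paste(head(missing_f, 5), collapse = ", "),
                 if (length(missing_f) > 5) " ..." else ""))
  }
  if (!is.null(object$zscore_stats)) {
    zs <- object$zscore_stats
    common <- intersect(colnames(x), names(zs$center))
    sc <- ifelse(zs$scale[common] > 0, zs$scale[common], 1)
    x[, common] <- sweep(sweep(x[, common, drop = FALSE], 2L,
                               zs$center[common]), 2L, sc, "/")
  }
  K <- length(object$members)
  conf <- vapply(object$members, function(m) {
    score_binary(m$classifier, x[, m$selected_features, drop = FALSE])
  }, numeric(nrow(x)))
  if (is.null(dim(conf))) conf <- matrix(conf, nrow = 1)
  colnames(conf) <- object$class_order
  votes <- conf > 0.5
  predicted <- character(nrow(x))
  tie_broken <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L || max(v) == 0) {
      cand <- if (max(v) == 0) seq_len(K) else top
      tie_broken[i] <- TRUE
      # confidence, then training class size, then class order
      o <- order(-conf[i, cand], -object$class_sizes[cand], cand)
      predicted[i] <- object$class_order[cand[o[1]]]
    } else {
      predicted[i] <- object$class_order[top]
    }
  }
  out <- tibble(sample_id = ids, predicted = predicted,
                votes = rowSums(votes), tie_broken = tie_broken)
  conf_tbl <- as_tibble(as.data.frame(conf))
  names(conf_tbl) <- paste0("conf_", object$class_order)
  dplyr::bind_cols(out, conf_tbl)
}

#' Extract the per-class gene signatures of a fitted ensemble
#'
#' @param object An `iefs_ensemble`.
#' @return A tibble with one row per (class, feature), feature rank within
#'   the signature included.
#' @export
signatures <- function(object) {
  stopifnot(inherits(object, "iefs_ensemble"))
  purrr::map_dfr(object$members, function(m) {
    tibble(class = m$positive_class,
           feature = m$selected_features,
           rank = seq_along(m$selected_features),
           short = m$short)
  })
}
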