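#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted one-vs-all ensemble
#'
#' Returns the per-class signatures as a tibble, one row per selected
#' feature (class, feature, rank within the signature, short flag).
#'
#' @param x An `iefs_ensemble`.
#' @param ... Unused.
#' @export
tidy.iefs_ensemble <- function(x, ...) signatures(x)

#' One-row summary of a fitted ensemble
#'
#' @param x An `iefs_ensemble`.
#' @param ... Unused.
#' @export
glance.iefs_ensemble <- function(x, ...) {
  tibble(
    n_classes = length(x$members),
    selector = x$config$selector,
    sampler = x$config$sampler,
    T = x$config$T_steps,
    n_features = x$config$n_features,
    classifier = x$config$classifier,
    any_short = any(vapply(x$members, `[[`, logical(1), "short")),
    seed = x$config$seed
  )
}

#' Tidy a benchmark report
#'
#' Unnests the per-class recalls into long form (one row per cell and
#' class).
#'
#' @param x An `iefs_benchmark` tibble.
#' @param ... Unused.
#' @export
tidy.iefs_benchmark <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x$per_class_recall[[i]]
    base <- dplyr::select(x[i, ], -"per_class_recall")
    if (is.null(r)) return(dplyr::mutate(base, class = NA_character_, recall = NA_real_))
    dplyr::bind_cols(
      base[rep(1, length(r)), ],
      tibble(class = names(r), recall = unname(r))
    )
  })
}

#' Accuracy / AUC curves over signature size
#'
#' Plots the benchmark metrics against the number of selected features,
#' one line per selector + sampler combination, faceted by classifier and
#' metric — the standard presentation for signature-size sweeps.
#'
#' @param object An `iefs_benchmark` tibble.
#' @param metrics Which metrics to draw (subset of `c("accuracy", "auc")`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iefs_benchmark <- function(object, metrics = c("accuracy", "auc"), ...) {
  df <- dplyr::filter(object, .data$selector != "baseline-all-features",
                      is.na(.data$error))
  long <- tidyr::pivot_longer(
    dplyr::select(df, "selector", "sampler", "T", "n_features", "classifier",
                  dplyr::all_of(metrics)),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  long$method <- paste0(long$selector, "+", long$sampler, " (T=", long$T, ")")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n_features, y = .data$value,
                                          colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(metric ~ classifier, scales = "free_y") +
    ggplot2::labs(x = "number of selected gene signatures", y = "%",
                  colour = NULL) +
    ggplot2::theme_bw()
  base <- dplyr::filter(object, .data$selector == "baseline-all-features")
  if (nrow(base) > 0) {
    bl <- tidyr::pivot_longer(
      dplyr::select(base, "classifier", dplyr::all_of(metrics)),
      cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
    )
    p <- p + ggplot2::geom_hline(data = bl,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot per-class signature sizes and top features
#'
#' A quick bar chart of MI relevance scores for the top-ranked features of
#' one ranked list, as returned by [rank_by_relevance()].
#'
#' @param ranked A tibble from [rank_by_relevance()].
#' @param top Number of features to show.
#' @return A ggplot object.
#' @export
plot_relevance <- function(ranked, top = 20L) {
  df <- head(ranked, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mutual information with class (bits)", y = NULL) +
    ggplot2::theme_bw()
}
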