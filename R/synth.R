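#' Simulate an imbalanced multiclass expression dataset
#'
#' Generates a samples-by-genes Gaussian expression matrix (log-intensity
#' scale) with planted class-informative genes. Background genes are
#' `Normal(0, noise_sd)` for every sample; each class owns a disjoint block
#' of `n_informative` genes whose mean is shifted by
#' `effect_size * noise_sd` in that class's samples only. An optional
#' equicorrelation within each informative block is induced through a
#' shared per-sample factor. The class-size vector encodes the imbalance
#' directly (e.g. `c(100, 20, 20, 20, 20)`).
#'
#' @param class_sizes Positive integer sizes, one per class (`K >= 2`).
#' @param n_features Total number of genes.
#' @param n_informative Informative genes per class;
#'   `K * n_informative <= n_features`.
#' @param effect_size Mean shift of informative genes, in units of
#'   `noise_sd`.
#' @param noise_sd Residual standard deviation.
#' @param correlation Within-block equicorrelation in `[0, 1)`.
#' @param seed Integer seed; the generator is fully deterministic per seed.
#' @return A list of class `sim_expression`: `data` (a validated expression
#'   tibble with classes `C1..CK`) and `truth` (tibble mapping each class
#'   to its planted informative genes).
#' @examples
#' sim <- simulate_expression(c(30, 10), n_features = 100, seed = 1)
#' dplyr::count(sim$data, class)
#' @export
simulate_expression <- function(class_sizes,
                                n_features = 1000L,
                                n_informative = 15L,
                                effect_size = 1.5,
                                noise_sd = 1,
                                correlation = 0,
                                seed = 0L) {
  K <- length(class_sizes)
  if (K < 2L) abort("need at least 2 classes")
  if (any(class_sizes < 1)) abort("class sizes must be positive")
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (correlation < 0 || correlation >= 1) abort("correlation must be in [0, 1)")
  if (K * n_informative > n_features) {
    abort("K * n_informative exceeds n_features (informative blocks are disjoint)")
  }
  n <- sum(class_sizes)
  classes <- paste0("C", seq_len(K))
  labels <- rep(classes, class_sizes)
  genes <- sprintf("g%04d", seq_len(n_features))
  x <- with_task_seed(seed, {
    m <- matrix(rnorm(n * n_features, 0, noise_sd), n, n_features)
    for (k in seq_len(K)) {
      block <- ((k - 1L) * n_informative + 1L):(k * n_informative)
      if (correlation > 0) {
        shared <- rnorm(n, 0, noise_sd)
        m[, block] <- sqrt(correlation) * shared +
          sqrt(1 - correlation) * m[, block]
      }
      m[labels == classes[k], block] <-
        m[labels == classes[k], block] + effect_size * noise_sd
    }
    m
  })
  colnames(x) <- genes
  data <- dplyr::bind_cols(
    tibble(sample_id = sprintf("s%04d", seq_len(n)), class = labels),
    as_tibble(as.data.frame(x))
  )
  truth <- purrr::map_dfr(seq_len(K), function(k) {
    tibble(class = classes[k],
           feature = genes[((k - 1L) * n_informative + 1L):(k * n_informative)])
  })
  structure(
    list(data = as_expression_dataset(data), truth = truth,
         spec = list(class_sizes = class_sizes, n_features = n_features,
                     n_informative = n_informative, effect_size = effect_size,
                     noise_sd = noise_sd, correlation = correlation,
                     seed = seed)),
    class = "sim_expression"
  )
}

#' @export
print.sim_expression <- function(x, ...) {
  s <- x$spec
  cat("<sim_expression>", length(s$class_sizes), "classes, sizes",
      paste(s$class_sizes, collapse = " "), "\n")
  cat("  ", s$n_features, "genes,", s$n_informative,
      "informative/class, effect", s$effect_size, "SD, seed", s$seed, "\n")
  invisible(x)
}

# class-size rows of the published benchmark collection, used for
# desk-scale look-alike datasets
.preset_sizes <- list(
  "gcm-like" = c(11, 10, 11, 11, 22, 11, 10, 10, 30, 11, 11, 11, 11, 20),
  "lung-like" = c(139, 17, 6, 21, 20),
  "allaml3-like" = c(38, 9, 25),
  "allaml4-like" = c(38, 9, 21, 4),
  "thyroid-like" = c(58, 28, 40, 42)
)

#' Simulate a benchmark-shaped dataset
#'
#' Presets reproduce the class-size structure of classic multiclass
#' microarray benchmarks (tumour panels with 3-14 classes and strong
#' imbalance, e.g. 9 vs 38 samples) at a desk-scale feature count
#' (default 2000 genes).
#'
#' @param name One of `"gcm-like"` (14 classes, 190 samples),
#'   `"lung-like"` (5 classes, 203), `"allaml3-like"` (3 classes, 72),
#'   `"allaml4-like"` (4 classes, 72) or `"thyroid-like"` (4 classes, 168).
#' @param seed Integer seed.
#' @param n_features Genes to simulate (default 2000).
#' @param ... Further arguments to [simulate_expression()].
#' @return A `sim_expression` list (see [simulate_expression()]).
#' @export
simulate_preset <- function(name = names(.preset_sizes), seed = 0L,
                            n_features = 2000L, ...) {
  name <- arg_match(name)
  simulate_expression(class_sizes = .preset_sizes[[name]],
                      n_features = n_features, seed = seed, ...)
}
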