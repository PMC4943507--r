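#' Read a run configuration from a YAML file
#'
#' The file holds `run_config()` fields as top-level keys; `overrides`
#' (typically parsed CLI flags) take precedence over file values.
#'
#' @param path YAML config path, or `NULL` for defaults.
#' @param overrides Named list of field overrides.
#' @return A [run_config()].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    vals <- yaml::read_yaml(path)
  }
  vals <- modifyList(vals, overrides[!vapply(overrides, is.null, logical(1))])
  do.call(run_config, vals)
}

#' Save / load a fitted ensemble
#'
#' `iefs_save()` writes a model directory: one plain-text signature file
#' per class (`signature_<class>.txt`, one feature id per line — the
#' interchange surface for downstream biology), the serialized ensemble
#' (`model.rds`) and a JSON manifest recording the configuration, seed and
#' package version. `iefs_load()` restores the ensemble.
#'
#' @param object An `iefs_ensemble`.
#' @param dir Directory to create/write.
#' @return `iefs_save()`: the written paths, invisibly. `iefs_load()`: the
#'   ensemble.
#' @export
iefs_save <- function(object, dir) {
  stopifnot(inherits(object, "iefs_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in object$members) {
    p <- file.path(dir, paste0("signature_", make.names(m$positive_class), ".txt"))
    writeLines(m$selected_features, p)
    paths <- c(paths, p)
  }
  manifest <- list(
    config = unclass(object$config),
    classes = object$class_order,
    class_sizes = object$class_sizes,
    tie_policy = object$tie_policy,
    short = setNames(vapply(object$members, `[[`, logical(1), "short"),
                     object$class_order),
    package_version = as.character(utils::packageVersion("iefs"))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  rp <- file.path(dir, "model.rds")
  saveRDS(object, rp)
  invisible(c(paths, mp, rp))
}

#' @rdname iefs_save
#' @export
iefs_load <- function(dir) {
  p <- file.path(dir, "model.rds")
  if (!file.exists(p)) abort(paste0("no model.rds under ", dir))
  readRDS(p)
}

cmd_result <- function(exit_code, artifacts = character(0), log = character(0)) {
  list(exit_code = exit_code, artifacts = artifacts, log = log)
}

#' Command-layer entry points
#'
#' Thin, scriptable wrappers used by the `iefs` command-line interface
#' (`inst/cli/iefs.R`); each reads its inputs, delegates to the package
#' functions, writes its artifacts and returns a result list
#' (`exit_code`, `artifacts`, `log`). `cmd_select` writes one signature
#' file per class plus a JSON run manifest; `cmd_fit` fits and saves an
#' ensemble; `cmd_predict` writes a predictions TSV (sample, predicted
#' class, per-class confidences); `cmd_benchmark` writes the evaluation
#' grid TSV; `cmd_simulate` writes a synthetic dataset and its
#' ground-truth sidecar.
#'
#' @param dataset_path Input dataset file (TSV/CSV/GCT).
#' @param out_dir,out Output directory / file.
#' @param config A [run_config()].
#' @param format Dataset format passed to [read_dataset()].
#' @param label_column Label column name or GCT sidecar path.
#' @name cmd
NULL

#' @rdname cmd
#' @export
cmd_select <- function(dataset_path, out_dir, config = run_config(),
                       format = "auto", label_column = "class") {
  data <- read_dataset(dataset_path, format = format, label_column = label_column)
  fit <- iefs_fit(data, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in fit$members) {
    p <- file.path(out_dir, paste0("signature_", make.names(m$positive_class), ".txt"))
    writeLines(m$selected_features, p)
    paths <- c(paths, p)
  }
  manifest <- list(
    command = "select", input = dataset_path,
    config = unclass(config),
    short = setNames(vapply(fit$members, `[[`, logical(1), "short"),
                     fit$class_order),
    package_version = as.character(utils::packageVersion("iefs"))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  cmd_result(0L, c(paths, mp))
}

#' @rdname cmd
#' @export
cmd_fit <- function(dataset_path, out_dir, config = run_config(),
                    format = "auto", label_column = "class") {
  data <- read_dataset(dataset_path, format = format, label_column = label_column)
  fit <- iefs_fit(data, config)
  paths <- iefs_save(fit, out_dir)
  cmd_result(0L, paths)
}

#' @rdname cmd
#' @param model_dir Directory written by `cmd_fit` / [iefs_save()].
#' @export
cmd_predict <- function(model_dir, dataset_path, out,
                        format = "auto", label_column = "class") {
  fit <- iefs_load(model_dir)
  data <- tryCatch(
    read_dataset(dataset_path, format = format, label_column = label_column),
    error = function(e) {
      # prediction inputs may lack labels entirely; retry as plain table
      d <- readr::read_tsv(dataset_path, show_col_types = FALSE, progress = FALSE)
      if (!"sample_id" %in% names(d)) abort(conditionMessage(e))
      d
    }
  )
  pred <- predict(fit, data)
  readr::write_tsv(pred, out, progress = FALSE)
  cmd_result(0L, out)
}

#' @rdname cmd
#' @param ... Grid axes forwarded to [iefs_benchmark()].
#' @export
cmd_benchmark <- function(dataset_path, out, config = run_config(),
                          format = "auto", label_column = "class", ...) {
  data <- read_dataset(dataset_path, format = format, label_column = label_column)
  report <- iefs_benchmark(data, cv_folds = config$cv_folds,
                           seed = config$seed,
                           classifiers = config$classifier, ...)
  write_benchmark(report, out)
  cmd_result(0L, out)
}

#' @rdname cmd
#' @param class_sizes,n_features,n_informative,effect_size,seed Forwarded
#'   to [simulate_expression()].
#' @export
cmd_simulate <- function(out, class_sizes = c(100, 20, 20, 20, 20),
                         n_features = 1000L, n_informative = 15L,
                         effect_size = 1.5, seed = 0L) {
  sim <- simulate_expression(class_sizes = class_sizes, n_features = n_features,
                             n_informative = n_informative,
                             effect_size = effect_size, seed = seed)
  write_dataset(sim$data, out, format = "tsv")
  truth_path <- paste0(out, ".truth.tsv")
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  cmd_result(0L, c(out, truth_path))
}
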