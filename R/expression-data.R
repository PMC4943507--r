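#' Expression dataset tibbles
#'
#' An expression dataset is an ordinary tibble in sample-major orientation:
#' one row per sample, a `sample_id` character column, a `class` column with
#' the sample's category, and one numeric column per gene. All package
#' functions that take a dataset take such a tibble first, so calls chain
#' with the pipe.
#'
#' `as_expression_dataset()` validates (and lightly coerces) a data frame
#' into this shape. Validation enforces:
#' * unique, non-missing sample and gene identifiers;
#' * all expression cells numeric and finite (no `NA`; see `impute`);
#' * at least two classes, each with at least two samples (stratified
#'   cross-validation and SMOTE interpolation both need a second sample).
#'
#' @param data A data frame with `sample_id`, a label column and numeric
#'   gene columns.
#' @param class_col Name of the label column (default `"class"`). It is
#'   renamed to `class` in the result.
#' @param impute Handling of missing expression values: `"reject"` (default)
#'   errors on any `NA`; `"mean"` replaces each gene's missing entries by
#'   that gene's mean over the non-missing samples.
#' @return A validated expression tibble with columns
#'   `sample_id`, `class`, then genes; feature and sample order preserved.
#' @examples
#' d <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s3", "s4"),
#'   class = c("A", "A", "B", "B"),
#'   g1 = c(1, 2, 3, 4), g2 = c(0, 0, 1, 1)
#' )
#' as_expression_dataset(d)
#' @export
as_expression_dataset <- function(data, class_col = "class",
                                  impute = c("reject", "mean")) {
  impute <- arg_match(impute)
  data <- as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    abort("dataset must have a `sample_id` column")
  }
  if (!class_col %in% names(data)) {
    abort(paste0("label column `", class_col, "` not found"))
  }
  if (class_col != "class") {
    if ("class" %in% names(data)) {
      abort("dataset already has a `class` column; cannot rename label column onto it")
    }
    names(data)[names(data) == class_col] <- "class"
  }
  data <- dplyr::relocate(data, "sample_id", "class")
  genes <- setdiff(names(data), c("sample_id", "class"))
  if (length(genes) == 0L) abort("dataset has no gene columns")
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate feature identifiers: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  ids <- as.character(data$sample_id)
  if (anyNA(ids) || anyDuplicated(ids)) {
    abort(paste0("sample identifiers must be unique and non-missing",
                 if (anyDuplicated(ids))
                   paste0(": duplicated ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
                 else ""))
  }
  data$sample_id <- ids
  bad <- genes[!vapply(data[genes], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric expression column(s): ", paste(bad, collapse = ", ")))
  }
  x <- as.matrix(data[genes])
  if (anyNA(x)) {
    if (impute == "reject") {
      nas <- genes[colSums(is.na(x)) > 0]
      abort(paste0("missing expression values in: ", paste(nas, collapse = ", "),
                   " (use impute = \"mean\" to impute per gene)"))
    }
    for (j in which(colSums(is.na(x)) > 0)) {
      v <- x[, j]
      if (all(is.na(v))) abort(paste0("gene ", genes[j], " is entirely missing"))
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      data[[genes[j]]] <- v
      x[, j] <- v
    }
  }
  if (any(!is.finite(x))) abort("non-finite expression values present")
  labs <- as.character(data$class)
  if (anyNA(labs)) abort("missing class labels")
  tab <- table(labs)
  if (length(tab) < 2L) abort("dataset must contain at least 2 classes")
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    abort(paste0("class with fewer than 2 samples: ", paste(small, collapse = ", ")))
  }
  data$class <- labs
  data
}

#' @rdname as_expression_dataset
#' @export
dataset_features <- function(data) {
  setdiff(names(data), c("sample_id", "class"))
}

#' @rdname as_expression_dataset
#' @export
dataset_matrix <- function(data) {
  genes <- dataset_features(data)
  m <- as.matrix(data[genes])
  rownames(m) <- data$sample_id
  m
}

#' Read an expression dataset from TSV, CSV or GCT
#'
#' Delimited files are sample-major: a header row with `sample_id`, the label
#' column and gene identifiers, one data row per sample. GCT 1.2 files are
#' gene-major (`#1.2` version line, a dimension line, then `NAME` and
#' `Description` columns and one column per sample); they are transposed on
#' load and class labels are supplied through a two-column sidecar file
#' (`sample_id <tab> class`, no header required unless present).
#'
#' @param path File to read.
#' @param format `"tsv"`, `"csv"` or `"gct"`; default guessed from extension.
#' @param label_column For delimited formats, the name of the label column
#'   (default `"class"`). For GCT, the path to the label sidecar file.
#' @param impute Missing-value policy passed to [as_expression_dataset()].
#' @return A validated expression tibble (see [as_expression_dataset()]).
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "csv", "gct"),
                         label_column = "class", impute = "reject") {
  format <- arg_match(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gct") {
    return(read_gct(path, label_sidecar = label_column, impute = impute))
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  data <- reader(path, show_col_types = FALSE, progress = FALSE,
                 name_repair = "minimal")
  if (anyDuplicated(names(data))) {
    abort(paste0("duplicate column names in ", path, ": ",
                 paste(unique(names(data)[duplicated(names(data))]), collapse = ", ")))
  }
  gene_cols <- setdiff(names(data), c("sample_id", label_column))
  for (g in gene_cols) {
    if (!is.numeric(data[[g]])) {
      abort(paste0("non-numeric expression cell(s) in column ", g, " of ", path))
    }
  }
  as_expression_dataset(data, class_col = label_column, impute = impute)
}

read_gct <- function(path, label_sidecar, impute = "reject") {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "#1.2") {
    abort(paste0(path, " is not a GCT 1.2 file (missing #1.2 version line)"))
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    abort(paste0("malformed GCT dimension line in ", path))
  }
  n_genes <- dims[1]; n_samples <- dims[2]
  body <- lines[-(1:2)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2L) {
    abort(paste0("GCT header declares ", length(header) - 2L,
                 " samples but dimension line says ", n_samples))
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows) != n_genes) {
    abort(paste0("GCT dimension line declares ", n_genes, " genes but file has ",
                 length(rows), " data rows"))
  }
  cells <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(cells) != n_samples + 2L)) {
    abort(paste0("GCT data row with wrong number of fields in ", path))
  }
  gene_ids <- vapply(cells, `[[`, character(1), 1L)
  vals <- vapply(cells, function(r) {
    v <- suppressWarnings(as.numeric(r[-(1:2)]))
    v
  }, numeric(n_samples))
  # vals: n_samples x n_genes after vapply
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = n_samples)
  if (anyNA(vals)) {
    bad <- gene_ids[colSums(is.na(vals)) > 0]
    abort(paste0("non-numeric or missing expression cell(s) for gene(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  sample_ids <- header[-(1:2)]
  if (is.null(label_sidecar) || !file.exists(label_sidecar)) {
    abort("GCT input needs a label sidecar file (sample_id<TAB>class); pass its path as label_column")
  }
  side <- readr::read_tsv(label_sidecar, show_col_types = FALSE, progress = FALSE,
                          col_names = c("sample_id", "class"), skip = 0)
  if (identical(tolower(as.character(side[1, 1])), "sample_id")) side <- side[-1, ]
  side$sample_id <- as.character(side$sample_id)
  missing_lab <- setdiff(sample_ids, side$sample_id)
  if (length(missing_lab)) {
    abort(paste0("no class label for sample(s): ", paste(missing_lab, collapse = ", ")))
  }
  labs <- side$class[match(sample_ids, side$sample_id)]
  out <- as_tibble(as.data.frame(vals))
  names(out) <- gene_ids
  out <- dplyr::bind_cols(tibble(sample_id = sample_ids, class = as.character(labs)), out)
  as_expression_dataset(out, impute = impute)
}

#' Write an expression dataset to TSV, CSV or GCT
#'
#' The written file round-trips through [read_dataset()] into a dataset equal
#' field-for-field (values at full `write_tsv` double precision). GCT output
#' starts with the `#1.2` version line and a dimension line matching the
#' matrix, and is accompanied by a `<path>.labels.tsv` sidecar holding the
#' class labels.
#'
#' @param data A validated expression tibble.
#' @param path Output file.
#' @param format `"tsv"`, `"csv"` or `"gct"`; default guessed from extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("auto", "tsv", "csv", "gct")) {
  format <- arg_match(format)
  data <- as_expression_dataset(data)
  if (length(dataset_features(data)) == 0L) abort("cannot write a dataset with 0 features")
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  }
  res <- tryCatch({
    if (format == "gct") {
      write_gct(data, path)
    } else if (format == "csv") {
      readr::write_csv(data, path, progress = FALSE)
    } else {
      readr::write_tsv(data, path, progress = FALSE)
    }
  }, error = function(e) {
    abort(paste0("failed writing ", path, ": ", conditionMessage(e)))
  })
  invisible(path)
}

write_gct <- function(data, path) {
  genes <- dataset_features(data)
  m <- t(dataset_matrix(data))     # genes x samples
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(length(genes), nrow(data), sep = "\t"), con)
  writeLines(paste(c("NAME", "Description", data$sample_id), collapse = "\t"), con)
  body <- vapply(seq_along(genes), function(i) {
    paste(c(genes[i], "na",
            format(m[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  side <- paste0(path, ".labels.tsv")
  readr::write_tsv(tibble(sample_id = data$sample_id, class = data$class),
                   side, progress = FALSE)
  invisible(path)
}

#' Z-score the gene columns of a dataset
#'
#' Optional per-gene standardisation (mean 0, SD 1 over samples) before
#' distance-based steps (KNN, SMOTE). Constant genes are left at 0.
#'
#' @param data A validated expression tibble.
#' @return The dataset with each gene column standardised.
#' @export
zscore_dataset <- function(data) {
  data <- as_expression_dataset(data)
  genes <- dataset_features(data)
  for (g in genes) {
    v <- data[[g]]
    s <- stats::sd(v)
    data[[g]] <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  }
  data
}
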