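#' Assemble an expression dataset from a matrix and sample labels
#'
#' A dataset couples a probe-by-sample expression matrix with a table of
#' sample labels. The label table must describe exactly the samples present
#' as matrix columns; it is reordered so that its rows follow the matrix
#' column order, which defines the canonical sample order for all
#' downstream analysis.
#'
#' @param exprs numeric matrix, rows = probes, columns = samples, with
#'   unique non-empty dimnames and no missing values.
#' @param labels data.frame with at least columns `sample_id` and the class
#'   column; the class column holds binary codes 0 (control) / 1
#'   (treatment). Extra columns are carried along untouched.
#' @param class_column name of the class-label column (default `"type"`).
#' @return An object of class `"apkl_dataset"`: a list with elements
#'   `exprs`, `labels` and `class_column`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' lab <- data.frame(sample_id = c("s1", "s2"), title = c("a", "b"),
#'                   type = c(0, 1))
#' d <- apkl_dataset(m, lab)
#' d
#' @export
apkl_dataset <- function(exprs, labels, class_column = "type") {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))]), collapse = ", "))
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]), collapse = ", "))
  if (anyNA(exprs))
    stop("'exprs' contains missing values")
  labels <- validate_labels(labels, class_column)
  miss_lab <- setdiff(colnames(exprs), labels$sample_id)
  miss_mat <- setdiff(labels$sample_id, colnames(exprs))
  if (length(miss_lab) || length(miss_mat))
    stop("sample-id mismatch between matrix and labels; ",
         "missing from labels: {", paste(miss_lab, collapse = ", "), "}; ",
         "missing from matrix: {", paste(miss_mat, collapse = ", "), "}")
  labels <- labels[match(colnames(exprs), labels$sample_id), , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(exprs = exprs, labels = labels, class_column = class_column),
            class = "apkl_dataset")
}

validate_labels <- function(labels, class_column) {
  if (!is.data.frame(labels))
    stop("'labels' must be a data.frame")
  if (!"sample_id" %in% names(labels))
    stop("labels need a 'sample_id' column")
  if (!class_column %in% names(labels))
    stop("class column '", class_column, "' not found in labels")
  if (anyDuplicated(labels$sample_id))
    stop("duplicate sample ids in labels")
  cls <- labels[[class_column]]
  cls_num <- suppressWarnings(as.numeric(as.character(cls)))
  bad <- is.na(cls_num) | !cls_num %in% c(0, 1)
  if (any(bad))
    stop("class values outside {0,1}: ",
         paste(unique(as.character(cls)[bad]), collapse = ", "))
  labels[[class_column]] <- as.integer(cls_num)
  labels$sample_id <- as.character(labels$sample_id)
  labels
}

#' Class codes of a dataset, in canonical sample order
#' @param data an `apkl_dataset`.
#' @return integer vector of 0/1 codes named by sample id.
#' @export
class_codes <- function(data) {
  stopifnot(inherits(data, "apkl_dataset"))
  stats::setNames(data$labels[[data$class_column]], data$labels$sample_id)
}

#' Restrict a dataset to a subset of probes and/or samples
#' @param data an `apkl_dataset`.
#' @param probes,samples character vectors of ids to keep (default all).
#' @return a new `apkl_dataset`.
#' @export
subset_dataset <- function(data, probes = rownames(data$exprs),
                           samples = colnames(data$exprs)) {
  stopifnot(inherits(data, "apkl_dataset"))
  missing_p <- setdiff(probes, rownames(data$exprs))
  if (length(missing_p))
    stop("probes not in dataset: ", paste(missing_p, collapse = ", "))
  missing_s <- setdiff(samples, colnames(data$exprs))
  if (length(missing_s))
    stop("samples not in dataset: ", paste(missing_s, collapse = ", "))
  apkl_dataset(data$exprs[probes, samples, drop = FALSE],
               data$labels[data$labels$sample_id %in% samples, , drop = FALSE],
               data$class_column)
}

#' @export
print.apkl_dataset <- function(x, ...) {
  cls <- class_codes(x)
  cat("apkl_dataset:", nrow(x$exprs), "probes x", ncol(x$exprs), "samples\n")
  cat("  class 0 (control):  ", sum(cls == 0), "samples\n")
  cat("  class 1 (treatment):", sum(cls == 1), "samples\n")
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' The file layout is one header line naming the samples (the first field
#' names the probe-id column and may be empty) followed by one line per
#' probe: probe id, then one numeric intensity per sample. Delimiter is
#' strictly TAB with "." as the decimal point; missing or non-numeric
#' cells are an error, not NA.
#'
#' @param path path to the file.
#' @return numeric matrix with probe rownames and sample colnames,
#'   preserving the file's row and column order.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, colClasses = "character",
                      comment.char = ""),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("'", path, "' holds no expression values")
  probe_ids <- df[[1L]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s) in '", path, "': ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing cell in '", path, "' at probe '",
         probe_ids[bad[1L]], "', sample '", sample_ids[bad[2L]], "'")
  }
  dimnames(vals) <- list(probe_ids, sample_ids)
  vals
}

#' Write a tab-delimited expression matrix
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("ID", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a tab-delimited sample-label table
#'
#' The first column holds the sample ids; the header must include `title`
#' and the class column (default `"type"`), whose values are the binary
#' class codes 0/1. Any further columns are kept as opaque metadata.
#'
#' @param path path to the file.
#' @param class_column name of the class column.
#' @return data.frame with columns `sample_id`, `title`, the class column
#'   (integer 0/1) and any extras.
#' @export
read_class_labels <- function(path, class_column = "type") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("'", path, "' holds no samples")
  names(df)[1L] <- "sample_id"
  if (!"title" %in% names(df))
    stop("'", path, "' lacks the required 'title' column")
  if (!class_column %in% names(df))
    stop("'", path, "' lacks the class column '", class_column, "'")
  validate_labels(df, class_column)
}

#' Write a sample-label table
#' @param labels data.frame as returned by [read_class_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_class_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an aligned expression dataset from a pair of files
#'
#' Reads the expression matrix and the label table and couples them into a
#' dataset; the two files must describe the same sample set, and label rows
#' are reordered to follow the matrix column order.
#'
#' @param exprs_path path to the expression-matrix file.
#' @param labels_path path to the label file.
#' @param class_column name of the class column in the label file.
#' @return an [apkl_dataset()].
#' @export
load_dataset <- function(exprs_path, labels_path, class_column = "type") {
  exprs <- read_expression_matrix(exprs_path)
  labels <- read_class_labels(labels_path, class_column)
  apkl_dataset(exprs, labels, class_column)
}
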