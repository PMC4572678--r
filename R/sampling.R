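#' Seeded stratified train/validation split
#'
#' Partitions a two-class dataset into a training and a validation
#' (hold-out) set, stratified by class: each class `c` with `n_c` samples
#' contributes `round-half-up(val_percent/100 * n_c)` samples to the
#' validation set, drawn without replacement from a single seeded
#' generator, classes processed in ascending class-code order. The split
#' is fully reproducible given `(data, val_percent, seed)`.
#'
#' The minimum validation share is 10%; the maximum is 90% so that
#' training is never empty. Within each set the original column order of
#' the input matrix is preserved.
#'
#' @param data an [apkl_dataset()]; each class needs at least 2 samples.
#' @param val_percent percentage of each class held out for validation,
#'   in \[10, 90\].
#' @param seed integer seed driving the random picks.
#' @return An object of class `"apkl_split"`: list with `train` and `test`
#'   datasets plus the `val_percent` and `seed` used.
#' @examples
#' sim <- synth_dataset(synth_spec(n_genes = 50, n0 = 20, n1 = 10, seed = 7))
#' sp <- stratified_split(sim$data, val_percent = 40, seed = 135)
#' sp
#' @export
stratified_split <- function(data, val_percent, seed) {
  stopifnot(inherits(data, "apkl_dataset"))
  if (!is.numeric(val_percent) || length(val_percent) != 1L)
    stop("'val_percent' must be a single number")
  if (val_percent < 10)
    stop("'val_percent' below the 10% minimum")
  if (val_percent > 90)
    stop("'val_percent' above the 90% maximum (training would starve)")
  cls <- class_codes(data)
  classes <- sort(unique(cls))
  if (any(table(cls) < 2L))
    stop("each class needs at least 2 samples")
  set.seed(as.integer(seed))
  val_ids <- character(0)
  for (cc in classes) {
    ids <- names(cls)[cls == cc]
    n_val <- floor(val_percent / 100 * length(ids) + 0.5)  # round half up
    if (n_val == 0L)
      stop("class ", cc, " would receive 0 validation samples")
    if (n_val == length(ids))
      stop("class ", cc, " would receive 0 training samples")
    val_ids <- c(val_ids, sample(ids, n_val))
  }
  all_ids <- colnames(data$exprs)
  test_ids <- all_ids[all_ids %in% val_ids]
  train_ids <- setdiff(all_ids, val_ids)
  structure(list(train = subset_dataset(data, samples = train_ids),
                 test = subset_dataset(data, samples = test_ids),
                 val_percent = val_percent, seed = as.integer(seed)),
            class = "apkl_split")
}

#' @export
print.apkl_split <- function(x, ...) {
  ctr <- table(class_codes(x$train))
  cte <- table(class_codes(x$test))
  cat("apkl_split (", x$val_percent, "% validation, seed ", x$seed, ")\n",
      sep = "")
  cat("  train:", ncol(x$train$exprs), "samples (",
      paste(sprintf("class %s: %d", names(ctr), ctr), collapse = ", "), ")\n")
  cat("  test: ", ncol(x$test$exprs), "samples (",
      paste(sprintf("class %s: %d", names(cte), cte), collapse = ", "), ")\n")
  invisible(x)
}
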