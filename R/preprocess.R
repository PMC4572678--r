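#' @name preprocess
#' @title Normalization and transformation of expression matrices
#' @description
#' The preprocessing unit offers a log2 transformation and four
#' array-level normalization methods (mean-centering, z-score, quantile,
#' cyclic loess), applied per sample column. [preprocess_all()] combines
#' them into the nine named variants `rawdata`, `mc`, `z`, `q`, `cl`,
#' `mcL2`, `zL2`, `qL2`, `clL2`, where the `L2` variants log2-transform
#' first and then normalize.
NULL

PREPROCESS_KEYS <- c("rawdata", "mc", "z", "q", "cl",
                     "mcL2", "zL2", "qL2", "clL2")

#' Elementwise log2 transformation
#' @param m numeric matrix with strictly positive values.
#' @return matrix of base-2 logarithms, same shape and dimnames.
#' @export
log2_transform <- function(m) {
  if (any(m <= 0))
    stop("log2 transform needs strictly positive values; ",
         "offset the data or skip the L2 variants")
  log2(m)
}

#' Mean-center each sample column
#' @param m numeric matrix.
#' @return matrix whose columns have mean 0.
#' @export
mean_center <- function(m) {
  sweep(m, 2L, colMeans(m), "-")
}

#' Z-score each sample column
#'
#' Columns are centered and scaled to unit standard deviation, using the
#' sample (n-1) standard deviation.
#'
#' @param m numeric matrix; no column may be constant.
#' @return matrix whose columns have mean 0 and sd 1.
#' @export
zscore_normalize <- function(m) {
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s), z-score undefined: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  sweep(mean_center(m), 2L, sds, "/")
}

#' Quantile-normalize sample columns
#'
#' After normalization every column carries the identical sorted value
#' vector: the row-wise mean of the per-column order statistics. Tied
#' values within a column receive the mean of the means at their tied
#' ranks.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return quantile-normalized matrix.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L)
    stop("quantile normalization needs at least 2 columns")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Cyclic-loess normalize sample columns
#'
#' For each unordered column pair (j, k) the difference M = col_j - col_k
#' is regressed on the average A = (col_j + col_k)/2 by local regression;
#' half the fitted curve is subtracted from col_j and added to col_k. All
#' pairs are visited once per iteration.
#'
#' @param m numeric matrix with at least 2 columns.
#' @param span loess span (default 0.7).
#' @param iterations number of passes over all pairs (default 1).
#' @return normalized matrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 1) {
  if (ncol(m) < 2L)
    stop("cyclic loess needs at least 2 columns")
  out <- tryCatch(
    limma::normalizeCyclicLoess(m, span = span, iterations = iterations,
                                method = "pairs"),
    error = function(e) stop("cyclic loess fit failed (too few probes ",
                             "for span ", span, "?): ", conditionMessage(e)))
  dimnames(out) <- dimnames(m)
  out
}

#' Produce the full bundle of preprocessed matrices
#'
#' @param m numeric matrix (probes x samples) with dimnames.
#' @param enabled subset of the nine variant names to compute; default all.
#' @param span,iterations cyclic-loess tuning, see
#'   [cyclic_loess_normalize()].
#' @return An object of class `"preprocess_bundle"`: a named list with one
#'   matrix per enabled key.
#' @examples
#' m <- matrix(2^rnorm(60, 7), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' b <- preprocess_all(m)
#' names(b)
#' @export
preprocess_all <- function(m, enabled = PREPROCESS_KEYS,
                           span = 0.7, iterations = 1) {
  bad <- setdiff(enabled, PREPROCESS_KEYS)
  if (length(bad))
    stop("unknown preprocessing key(s): ", paste(bad, collapse = ", "))
  l2 <- NULL
  need_l2 <- any(c("mcL2", "zL2", "qL2", "clL2") %in% enabled)
  stage <- function(key, expr) {
    tryCatch(expr, error = function(e)
      stop(key, ": ", conditionMessage(e), call. = FALSE))
  }
  if (need_l2) l2 <- stage("L2", log2_transform(m))
  out <- list()
  for (key in intersect(PREPROCESS_KEYS, enabled)) {
    out[[key]] <- switch(key,
      rawdata = m,
      mc   = stage(key, mean_center(m)),
      z    = stage(key, zscore_normalize(m)),
      q    = stage(key, quantile_normalize(m)),
      cl   = stage(key, cyclic_loess_normalize(m, span, iterations)),
      mcL2 = stage(key, mean_center(l2)),
      zL2  = stage(key, zscore_normalize(l2)),
      qL2  = stage(key, quantile_normalize(l2)),
      clL2 = stage(key, cyclic_loess_normalize(l2, span, iterations)))
  }
  structure(out, class = "preprocess_bundle")
}

#' @export
print.preprocess_bundle <- function(x, ...) {
  cat("preprocess_bundle with", length(x), "matrices:",
      paste(names(x), collapse = ", "), "\n")
  d <- dim(x[[1L]])
  cat("  each", d[1L], "probes x", d[2L], "samples\n")
  invisible(x)
}

#' Pooled density curves per preprocessing variant
#'
#' Computes a kernel density estimate of the pooled values of each matrix
#' in the bundle, all evaluated on one shared grid spanning the range of
#' every variant, for overlay/panel plotting of the kind used to compare
#' normalization schemes.
#'
#' @param bundle a [preprocess_all()] result (or any named list of
#'   matrices).
#' @param n_grid number of grid points (default 4096; generous because the
#'   shared grid must resolve both wide raw-intensity and narrow z-score
#'   distributions).
#' @return An object of class `"density_profiles"`: list with `grid` and a
#'   named list `density` of curves, one per key.
#' @export
density_profiles <- function(bundle, n_grid = 4096) {
  if (length(bundle) == 0L) stop("empty bundle")
  rngs <- range(unlist(lapply(bundle, range)))
  pad <- 0.05 * diff(rngs)
  lo <- rngs[1L] - pad
  hi <- rngs[2L] + pad
  dens <- lapply(bundle, function(m)
    stats::density(as.vector(m), from = lo, to = hi, n = n_grid)$y)
  grid <- stats::density(as.vector(bundle[[1L]]), from = lo, to = hi,
                         n = n_grid)$x
  structure(list(grid = grid, density = dens), class = "density_profiles")
}

#' @export
plot.density_profiles <- function(x, ...) {
  keys <- names(x$density)
  nk <- length(keys)
  nc <- ceiling(sqrt(nk))
  nr <- ceiling(nk / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (k in keys) {
    graphics::plot(x$grid, x$density[[k]], type = "l", main = k,
                   xlab = "", ylab = "", ...)
  }
  invisible(x)
}
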