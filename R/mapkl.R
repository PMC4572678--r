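#' Fit the hybrid exemplar-selection model to a two-class dataset
#'
#' `mapkl()` is the package's core estimator. Starting from a (typically
#' normalized) training dataset it
#' 1. ranks every probe by permutation-adjusted significance
#'    ([maxt_adjusted()], Westfall-Young step-down maxT over `B` seeded
#'    label permutations);
#' 2. keeps the `N` top-ranked probes ([select_top_n()]);
#' 3. estimates the number of gene clusters among them with the
#'    Krzanowski-Lai index ([kl_cluster_count()]);
#' 4. partitions the top genes into that many clusters by affinity
#'    propagation on negative squared Euclidean similarities, with the
#'    shared preference bisected to hit the estimated count
#'    ([ap_with_target_k()]);
#' 5. returns the cluster exemplars — one representative gene per
#'    cluster — as the selected signature, together with exemplar-only
#'    training (and optionally validation) datasets.
#'
#' The premise is that the significant end of a ranked gene list contains
#' clusters of co-behaving genes; one exemplar per cluster summarizes the
#' list with a handful of genes while retaining its discriminative power.
#'
#' @param train an [apkl_dataset()] of training samples.
#' @param test optional validation [apkl_dataset()]; its probe set must
#'   contain the training probes. When given, exemplar submatrices of the
#'   validation data are returned alongside the training ones.
#' @param N number of top-ranked genes carried into clustering
#'   (default 200, capped at the probe count with a warning).
#' @param B number of label permutations for the maxT ranking
#'   (default 1000, minimum 100).
#' @param seed integer seed for the permutation draw.
#' @param k_max largest cluster count scanned by the Krzanowski-Lai index
#'   (default 30, capped at N - 2).
#' @param lambda affinity-propagation damping in \[0.5, 1) (default 0.9).
#' @param max_iters,conv_window affinity-propagation iteration cap and
#'   convergence window (defaults 1000 and 100).
#' @return An object of class `"mapkl"`: list with `ranked` (the
#'   [maxt_adjusted()] table), `top_matrix`, `kl` (the `"kl_profile"`),
#'   `clusters` (the `"ap_solution"`), `exemplars` (character vector of
#'   probe ids), `exempl_train` / `exempl_test` (exemplar-row datasets)
#'   and `params`.
#' @examples
#' sim <- synth_dataset(synth_spec(n_genes = 300, k_true = 3,
#'                                 genes_per_cluster = 15, seed = 11))
#' fit <- mapkl(sim$data, N = 60, B = 100, k_max = 10, seed = 1)
#' fit
#' @export
mapkl <- function(train, test = NULL, N = 200, B = 1000, seed = 1,
                  k_max = 30, lambda = 0.9, max_iters = 1000,
                  conv_window = 100) {
  stopifnot(inherits(train, "apkl_dataset"))
  if (!is.null(test)) {
    stopifnot(inherits(test, "apkl_dataset"))
    miss <- setdiff(rownames(train$exprs), rownames(test$exprs))
    if (length(miss))
      stop("validation data lacks training probes: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ...")
  }
  G <- nrow(train$exprs)
  if (N > G) {
    warning("N = ", N, " exceeds the probe count ", G, "; using N = ", G)
    N <- G
  }
  if (k_max > N - 2L) {
    warning("k_max capped at N - 2 = ", N - 2L)
    k_max <- N - 2L
  }
  stage <- function(tag, expr)
    tryCatch(expr, error = function(e)
      stop("[", tag, "] ", conditionMessage(e), call. = FALSE))

  ranked <- stage("rank", maxt_adjusted(train, B = B, seed = seed))
  top <- stage("top", select_top_n(ranked, train, N))
  kl <- stage("kl", kl_cluster_count(top, k_max = k_max))
  S <- negsq_similarity(top)
  clusters <- stage("ap", ap_with_target_k(S, kl$k_hat, lambda = lambda,
                                           max_iters = max_iters,
                                           conv_window = conv_window))
  exemplars <- rownames(top)[clusters$exemplars]
  exempl_train <- subset_dataset(train, probes = exemplars)
  exempl_test <- if (!is.null(test))
    subset_dataset(test, probes = exemplars)
  structure(list(ranked = ranked, top_matrix = top, kl = kl,
                 clusters = clusters, exemplars = exemplars,
                 exempl_train = exempl_train, exempl_test = exempl_test,
                 params = list(N = N, B = B, seed = seed, k_max = k_max,
                               lambda = lambda, max_iters = max_iters,
                               conv_window = conv_window)),
            class = "mapkl")
}

#' @export
print.mapkl <- function(x, ...) {
  cat("mapkl fit: ", nrow(x$ranked), " probes ranked over ",
      attr(x$ranked, "n_perm"),
      if (isTRUE(attr(x$ranked, "exhaustive"))) " exhaustive" else " random",
      " permutations\n", sep = "")
  cat("  top N:", x$params$N, " estimated clusters (KL): k_hat =",
      x$kl$k_hat, "\n")
  cat("  exemplars (", length(x$exemplars), "): ",
      paste(utils::head(x$exemplars, 8), collapse = ", "),
      if (length(x$exemplars) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.mapkl <- function(object, n_show = 10, ...) {
  ord <- order(object$ranked$rank)
  structure(list(fit = object,
                 top_table = utils::head(object$ranked[ord, ], n_show)),
            class = "summary.mapkl")
}

#' @export
print.summary.mapkl <- function(x, ...) {
  print(x$fit)
  cat("\nTop of the ranked list:\n")
  print(x$top_table, digits = 4, row.names = FALSE)
  sizes <- table(x$fit$clusters$assignment)
  cat("\nCluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  if (!x$fit$clusters$target_reached)
    cat("note: affinity propagation returned k =", x$fit$clusters$k,
        "instead of the KL target", x$fit$clusters$target_k, "\n")
  invisible(x)
}

#' Plot the Krzanowski-Lai profile of a fit
#' @param x a `"mapkl"` object.
#' @param ... passed to [plot.kl_profile()].
#' @export
plot.mapkl <- function(x, ...) {
  plot(x$kl, main = paste0("KL index (k_hat = ", x$kl$k_hat, ")"), ...)
  invisible(x)
}

#' Exemplar probes of a fit
#' @param fit a `"mapkl"` object.
#' @return character vector of exemplar probe ids.
#' @export
exemplars <- function(fit) {
  stopifnot(inherits(fit, "mapkl"))
  fit$exemplars
}
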