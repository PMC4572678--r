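#' Pairwise mutual information of gene profiles
#'
#' Each gene profile is discretized into equal-width bins over its own
#' range (default bin count: the square root of the sample count, rounded
#' down) and pairwise mutual information is computed from the joint
#' frequency table with the maximum-likelihood (plug-in) entropy
#' estimate, in nats. Constant genes discretize into a single bin, carry
#' zero information with every partner and are flagged. The diagonal
#' holds each gene's self-information H(X).
#'
#' @param top numeric matrix, genes in rows, at least 4 samples.
#' @param bins number of discretization bins (default `floor(sqrt(n))`).
#' @return An object of class `"mi_matrix"`: list with `mi` (symmetric
#'   matrix, nats), `bins`, `estimator` and `constant` (flag per gene).
#' @export
mutual_information <- function(top, bins = NULL) {
  stopifnot(is.matrix(top))
  n <- ncol(top)
  if (n < 4L) stop("mutual information needs at least 4 samples")
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  G <- nrow(top)
  disc <- matrix(1L, G, n)
  constant <- logical(G)
  for (g in seq_len(G)) {
    r <- range(top[g, ])
    if (r[1L] == r[2L]) { constant[g] <- TRUE; next }
    brk <- seq(r[1L], r[2L], length.out = bins + 1L)
    disc[g, ] <- pmin(pmax(findInterval(top[g, ], brk,
                                        rightmost.closed = TRUE), 1L), bins)
  }
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  H <- vapply(seq_len(G), function(g) ent(tabulate(disc[g, ], bins)),
              numeric(1))
  mi <- matrix(0, G, G, dimnames = list(rownames(top), rownames(top)))
  diag(mi) <- H
  if (G > 1L) {
    for (i in seq_len(G - 1L)) {
      if (constant[i]) next
      for (j in (i + 1L):G) {
        if (constant[j]) next
        joint <- tabulate((disc[i, ] - 1L) * bins + disc[j, ], bins * bins)
        mi[i, j] <- mi[j, i] <- max(0, H[i] + H[j] - ent(joint))
      }
    }
  }
  structure(list(mi = mi, bins = as.integer(bins),
                 estimator = "ML plug-in, equal-width bins",
                 constant = stats::setNames(constant, rownames(top))),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("mutual-information matrix:", nrow(x$mi), "genes,", x$bins,
      "equal-width bins (", x$estimator, ")\n")
  invisible(x)
}

new_weighted_network <- function(W, method) {
  diag(W) <- 0
  structure(list(genes = rownames(W), W = W, method = method),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted network (", x$method, "): ", length(x$genes), " genes, ",
      sum(x$W[upper.tri(x$W)] > 0), " positive edges\n", sep = "")
  invisible(x)
}

#' CLR network weights from a mutual-information matrix
#'
#' The context-likelihood-of-relatedness transform: every MI value is
#' z-scored against its row background (mean and sd of the row's
#' off-diagonal entries, negatives clipped at 0) and the two directional
#' z-scores combine as `w_ij = sqrt(z_ij^2 + z_ji^2)`. Rows with zero
#' off-diagonal sd contribute zero z-scores (flagged via a warning).
#'
#' @param mim a [mutual_information()] result.
#' @return a `"weighted_network"` with `method = "clr"`.
#' @export
clr_weights <- function(mim) {
  stopifnot(inherits(mim, "mi_matrix"))
  M <- mim$mi
  G <- nrow(M)
  if (G < 3L) stop("CLR needs at least 3 genes")
  off <- M
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sd <- apply(off, 1L, stats::sd, na.rm = TRUE)
  degenerate <- sd == 0
  if (any(degenerate))
    warning("zero row sd for ", sum(degenerate),
            " gene(s); their z-scores set to 0")
  z <- (M - mu) / ifelse(degenerate, Inf, sd)   # row i stats on row i
  z <- pmax(z, 0)
  W <- sqrt(z^2 + t(z)^2)
  new_weighted_network(W, "clr")
}

#' ARACNE pruning of a mutual-information matrix
#'
#' Applies the data-processing inequality to every gene triple against
#' the original MI matrix (not iteratively): edge (i, j) is dropped when
#' a third gene k satisfies `mi_ij < min(mi_ik, mi_jk) - eps` (additive
#' mode, `aracne.a`) or `mi_ij < min(mi_ik, mi_jk) * (1 - tau)`
#' (multiplicative mode, `aracne.m`). The inequality is strict, so
#' equal-MI triangles are left untouched. Surviving edges keep their MI
#' weight.
#'
#' @param mim a [mutual_information()] result.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param eps additive tolerance (default 0).
#' @param tau multiplicative tolerance in \[0, 1) (default 0.15).
#' @return a `"weighted_network"` with `method` `"aracne.a"` or
#'   `"aracne.m"`.
#' @export
aracne_prune <- function(mim, mode = c("additive", "multiplicative"),
                         eps = 0, tau = 0.15) {
  stopifnot(inherits(mim, "mi_matrix"))
  mode <- match.arg(mode)
  if (eps < 0) stop("eps must be >= 0")
  if (tau < 0 || tau >= 1) stop("tau must lie in [0, 1)")
  M <- mim$mi
  diag(M) <- 0
  G <- nrow(M)
  W <- M
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      others <- setdiff(seq_len(G), c(i, j))
      if (!length(others)) next
      floor_k <- pmin(M[i, others], M[j, others])
      thr <- if (mode == "additive") floor_k - eps else floor_k * (1 - tau)
      if (any(M[i, j] < thr)) W[i, j] <- W[j, i] <- 0
    }
  }
  new_weighted_network(W, if (mode == "additive") "aracne.a" else "aracne.m")
}

#' Local and global weighted network characteristics
#'
#' Computes, per node: the weighted degree (sum of incident weights),
#' closeness and betweenness centralities over shortest paths on the
#' distances `d = 1/w`, and the weighted local clustering coefficient
#' (transitivity, arithmetic-mean edge-weight variant). Closeness is the
#' reciprocal of the summed distance to all reachable nodes (0 for an
#' isolated node); local transitivity of nodes with fewer than two
#' neighbors is 0. Global values are the means of the local ones,
#' supplemented by the sample sd of the weighted degrees and the
#' triangle-over-triple transitivity of the binarized graph.
#'
#' @param net a `"weighted_network"`.
#' @return An object of class `"network_stats"`: list with `local` (a
#'   data.frame: gene, wdegree, closeness, betweenness, transitivity) and
#'   `global` (means, `sd_wdegree`, `transitivity_global`).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$W
  G <- nrow(W)
  if (G == 0L || all(W == 0)) {
    loc <- data.frame(gene = net$genes, wdegree = numeric(G),
                      closeness = numeric(G), betweenness = numeric(G),
                      transitivity = numeric(G), stringsAsFactors = FALSE)
    glob <- list(wdegree = 0, closeness = 0, betweenness = 0,
                 transitivity = 0, sd_wdegree = 0, transitivity_global = 0)
    return(structure(list(local = loc, global = glob, method = net$method),
                     class = "network_stats"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight
  dist_w <- 1 / wts
  wdeg <- igraph::strength(g)
  clo <- suppressWarnings(igraph::closeness(g, weights = dist_w,
                                            mode = "all"))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(g, weights = dist_w)
  trans <- igraph::transitivity(g, type = "barrat", weights = wts,
                                isolates = "zero")
  trans[!is.finite(trans)] <- 0
  tg <- igraph::transitivity(g, type = "global")
  if (!is.finite(tg)) tg <- 0
  loc <- data.frame(gene = net$genes, wdegree = unname(wdeg),
                    closeness = unname(clo), betweenness = unname(btw),
                    transitivity = unname(trans), stringsAsFactors = FALSE)
  glob <- list(wdegree = mean(loc$wdegree), closeness = mean(loc$closeness),
               betweenness = mean(loc$betweenness),
               transitivity = mean(loc$transitivity),
               sd_wdegree = if (G > 1L) stats::sd(loc$wdegree) else 0,
               transitivity_global = tg)
  structure(list(local = loc, global = glob, method = net$method),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("network statistics (", x$method, "), ", nrow(x$local),
      " nodes\n", sep = "")
  cat(sprintf("  global: wdegree %.3f (sd %.3f), closeness %.4f, betweenness %.2f,\n",
              x$global$wdegree, x$global$sd_wdegree, x$global$closeness,
              x$global$betweenness))
  cat(sprintf("          transitivity %.3f (triangle-based global %.3f)\n",
              x$global$transitivity, x$global$transitivity_global))
  cat("  hubs:", length(hub_filter(x)), "\n")
  invisible(x)
}

#' Hub genes by the two-sigma weighted-degree rule
#'
#' Returns the nodes whose local weighted degree exceeds the global mean
#' weighted degree by more than two standard deviations.
#'
#' @param stats a [network_stats()] result.
#' @return character vector of hub gene ids (possibly empty).
#' @export
hub_filter <- function(stats) {
  stopifnot(inherits(stats, "network_stats"))
  thr <- stats$global$wdegree + 2 * stats$global$sd_wdegree
  stats$local$gene[stats$local$wdegree > thr]
}

#' Export a weighted edge list
#'
#' One row per strictly positive edge of the upper triangle, the two node
#' ids in lexical order. Suitable for import into graph packages or
#' Cytoscape.
#'
#' @param net a `"weighted_network"`.
#' @param path optional path; when given, the list is written as TSV with
#'   header `Node1 Node2 weight`.
#' @return data.frame with columns `Node1`, `Node2`, `weight` (invisibly
#'   when `path` is given).
#' @export
export_edge_list <- function(net, path = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$W
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  a <- net$genes[ut[, 1L]]
  b <- net$genes[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  el <- data.frame(Node1 = a, Node2 = b, weight = W[ut],
                   stringsAsFactors = FALSE)
  el <- el[order(el$Node1, el$Node2), , drop = FALSE]
  rownames(el) <- NULL
  if (!is.null(path)) {
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(el))
  }
  el
}
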