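#' Two-sample t statistics per probe
#'
#' Computes the two-sample t statistic for every probe, with class 0 as
#' the reference: `t = (mean0 - mean1) / se`. The default is the
#' pooled-variance statistic; Welch's unequal-variance form is available
#' via `var_equal = FALSE`. Probes with (near-)zero within-class variance
#' have the pooled variance floored at `1e-12` times the probe's overall
#' variance so the statistic stays finite; such probes are flagged. Probes
#' that are constant across all samples get t = 0.
#'
#' @param data an [apkl_dataset()] with at least 2 samples per class.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) variance.
#' @return numeric vector of t statistics named by probe, with a logical
#'   attribute `"zero_variance"` flagging floored probes.
#' @export
t_statistics <- function(data, var_equal = TRUE) {
  stopifnot(inherits(data, "apkl_dataset"))
  cls <- class_codes(data)
  if (sum(cls == 0) < 2L || sum(cls == 1) < 2L)
    stop("each class needs at least 2 samples for t statistics")
  x <- data$exprs
  res <- tstat_engine(x, cls == 1L, var_equal = var_equal)
  t <- res$t
  names(t) <- rownames(x)
  attr(t, "zero_variance") <- stats::setNames(res$floored, rownames(x))
  t
}

# Core t computation for one class-1 membership vector (logical length n).
# Returns t (with variance floor applied), the class means and the flag.
tstat_engine <- function(x, memb1, var_equal = TRUE) {
  n1 <- sum(memb1); n0 <- sum(!memb1)
  m1 <- rowMeans(x[, memb1, drop = FALSE])
  m0 <- rowMeans(x[, !memb1, drop = FALSE])
  ss1 <- rowSums((x[, memb1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((x[, !memb1, drop = FALSE] - m0)^2)
  gvar <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L)
  if (var_equal) {
    sp2 <- (ss0 + ss1) / (n0 + n1 - 2L)
    floor_at <- 1e-12 * gvar
    floored <- sp2 <= floor_at
    sp2 <- pmax(sp2, floor_at)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  } else {
    v0 <- ss0 / (n0 - 1L); v1 <- ss1 / (n1 - 1L)
    floor_at <- 1e-12 * gvar
    floored <- (v0 / n0 + v1 / n1) <= floor_at
    se <- sqrt(pmax(v0 / n0 + v1 / n1, floor_at))
  }
  t <- (m0 - m1) / se
  t[gvar == 0] <- 0            # constant probe: no signal at all
  floored <- floored | gvar == 0
  list(t = t, m0 = m0, m1 = m1, floored = floored)
}

# Vectorized pooled t statistics for B membership columns at once.
# x: G x n matrix; memb: n x B 0/1 matrix of class-1 membership.
tstat_perm_matrix <- function(x, memb) {
  n <- ncol(x)
  n1 <- colSums(memb)
  n0 <- n - n1
  rs <- rowSums(x)
  rq <- rowSums(x^2)
  s1 <- x %*% memb                       # G x B group-1 sums
  q1 <- x^2 %*% memb
  m1 <- sweep(s1, 2L, n1, "/")
  m0 <- sweep(-s1 + rs, 2L, n0, "/")
  ss1 <- q1 - sweep(m1^2, 2L, n1, "*")
  ss0 <- (rq - q1) - sweep(m0^2, 2L, n0, "*")
  sp2 <- sweep(ss0 + ss1, 2L, n0 + n1 - 2L, "/")
  gvar <- (rq - rs^2 / n) / (n - 1L)
  sp2 <- pmax(sp2, 1e-12 * gvar)
  se <- sqrt(sweep(sp2, 2L, 1 / n0 + 1 / n1, "*"))
  t <- (m0 - m1) / se
  t[gvar == 0, ] <- 0
  t
}

#' Fold change per probe
#'
#' Difference of class means on the analysis scale (so a log2 difference
#' when the matrix was log2-preprocessed): `mean(class 1) - mean(class 0)`.
#'
#' @param data an [apkl_dataset()].
#' @return numeric vector named by probe.
#' @export
fold_changes <- function(data) {
  stopifnot(inherits(data, "apkl_dataset"))
  cls <- class_codes(data)
  x <- data$exprs
  rowMeans(x[, cls == 1L, drop = FALSE]) -
    rowMeans(x[, cls == 0L, drop = FALSE])
}

#' Westfall-Young maxT permutation-adjusted gene ranking
#'
#' Ranks every probe by the absolute pooled t statistic and attaches
#' permutation p-values: the raw per-probe p-value and the step-down maxT
#' family-wise-error-adjusted p-value. For each label permutation the
#' successive maxima of permuted |t| are formed from the bottom of the
#' observed ranking upward; the adjusted p-value of the j-th ranked probe
#' is the exceedance frequency of that running maximum, made monotone down
#' the ranking.
#'
#' Random permutations use the (count + 1)/(B + 1) convention so p > 0
#' always. When the number of distinct class assignments `choose(n, n1)`
#' does not exceed `B`, the procedure switches to exhaustive enumeration
#' (with a message) and p-values become exact counts over all assignments,
#' the identity included.
#'
#' @param data an [apkl_dataset()].
#' @param B number of random permutations (minimum 100; default 1000).
#' @param seed integer seed for the permutation draw.
#' @return An object of class `"ranked_genes"`: a data.frame with columns
#'   `probe`, `t`, `p_raw`, `p_adj`, `fc`, `rank` (1 = largest |t|, ties
#'   broken by probe id) and `zero_variance`, in original probe order.
#' @export
maxt_adjusted <- function(data, B = 1000, seed = 1) {
  stopifnot(inherits(data, "apkl_dataset"))
  if (B < 100) stop("B must be at least 100")
  cls <- class_codes(data)
  x <- data$exprs
  n <- length(cls)
  n1 <- sum(cls == 1L)
  if (n1 < 2L || n - n1 < 2L)
    stop("each class needs at least 2 samples")
  G <- nrow(x)
  zero_var <- attr(t_statistics(data), "zero_variance")

  n_distinct <- choose(n, n1)
  exhaustive <- is.finite(n_distinct) && n_distinct <= B
  if (exhaustive) {
    message("only ", n_distinct, " distinct class assignments; ",
            "using exhaustive enumeration instead of ", B,
            " random permutations")
    combs <- utils::combn(n, n1)
    memb <- matrix(0, n, ncol(combs))
    memb[cbind(as.vector(combs),
               rep(seq_len(ncol(combs)), each = n1))] <- 1
    n_perm <- ncol(memb)
    denom <- n_perm
    extra <- 0
  } else {
    set.seed(as.integer(seed))
    memb <- vapply(seq_len(B), function(b) {
      m <- numeric(n); m[sample.int(n, n1)] <- 1; m
    }, numeric(n))
    n_perm <- B
    denom <- B + 1
    extra <- 1
  }

  tstar_signed <- tstat_perm_matrix(x, memb)        # G x n_perm
  # observed t through the same vectorized engine (in exhaustive mode the
  # identity assignment's own column) so it counts itself exactly
  if (exhaustive) {
    id_col <- which(colSums(memb == (cls == 1L)) == n)[1L]
    t_obs <- tstar_signed[, id_col]
  } else {
    t_obs <- drop(tstat_perm_matrix(x, matrix(as.numeric(cls == 1L))))
  }
  abs_obs <- abs(t_obs)
  tstar <- abs(tstar_signed)
  # complementary assignments yield mathematically equal |t| through a
  # different float path; count such ties with a relative tolerance
  tol <- 1e-9 * (1 + abs_obs)
  p_raw <- (rowSums(tstar >= abs_obs - tol) + extra) / denom

  ord <- order(-abs_obs, rownames(x))               # step-down order
  ts_ord <- tstar[ord, , drop = FALSE]
  # running maxima from the bottom of the ranking upward, per permutation
  u <- apply(ts_ord[G:1, , drop = FALSE], 2L, cummax)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)    # G == 1 collapse
  u <- u[G:1, , drop = FALSE]
  cnt <- rowSums(u >= abs_obs[ord] - tol[ord]) + extra
  p_adj_ord <- cummax(cnt / denom)                  # enforce monotonicity
  p_adj <- numeric(G)
  p_adj[ord] <- p_adj_ord
  rank <- integer(G)
  rank[ord] <- seq_len(G)

  structure(data.frame(probe = rownames(x), t = unname(t_obs),
                       p_raw = p_raw, p_adj = p_adj,
                       fc = unname(fold_changes(data)), rank = rank,
                       zero_variance = unname(zero_var),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_genes", "data.frame"),
            exhaustive = exhaustive, n_perm = n_perm)
}

#' Top-N submatrix of a ranked gene list
#'
#' @param ranked a [maxt_adjusted()] result.
#' @param data the dataset the ranking came from.
#' @param N number of top-ranked probes to keep (at most the probe count).
#' @return expression submatrix of the N best-ranked probes, rows in rank
#'   order.
#' @export
select_top_n <- function(ranked, data, N) {
  stopifnot(inherits(ranked, "ranked_genes"), inherits(data, "apkl_dataset"))
  G <- nrow(ranked)
  if (N > G) stop("N = ", N, " exceeds the number of probes (", G, ")")
  top <- ranked$probe[order(ranked$rank)][seq_len(N)]
  data$exprs[top, , drop = FALSE]
}

#' Krzanowski-Lai estimate of the cluster count
#'
#' Gene rows of the top-N matrix are clustered hierarchically
#' (Ward linkage on Euclidean distances) and the dendrogram is cut at
#' every k up to `k_max`. With `W_k` the total within-cluster sum of
#' squares at k clusters and p the feature-space dimension (number of
#' samples),
#' `DIFF_k = (k-1)^(2/p) W_(k-1) - k^(2/p) W_k` and
#' `KL_k = |DIFF_k / DIFF_(k+1)|`; the estimated count is the k in
#' `2..k_max-1` maximizing KL (smallest k on ties).
#'
#' @param top numeric matrix of the top-ranked genes (rows) by samples.
#' @param k_max largest cluster count scanned (default 30); the row count
#'   must be at least `k_max + 2`.
#' @return An object of class `"kl_profile"`: list with `k`, `W`, `DIFF`,
#'   `KL` and the estimate `k_hat`.
#' @export
kl_cluster_count <- function(top, k_max = 30) {
  stopifnot(is.matrix(top))
  N <- nrow(top)
  if (k_max < 2L) stop("k_max must be at least 2")
  if (N < k_max + 2L)
    stop("need at least k_max + 2 = ", k_max + 2L, " genes, got ", N)
  d <- stats::dist(top)
  if (all(d == 0)) stop("all gene rows identical; cluster count undefined")
  hc <- stats::hclust(d, method = "ward.D2")
  p <- ncol(top)
  wss <- function(assign) {
    sum(vapply(split(seq_len(N), assign), function(idx) {
      sub <- top[idx, , drop = FALSE]
      sum(sweep(sub, 2L, colMeans(sub))^2)
    }, numeric(1)))
  }
  ks <- seq_len(k_max)
  W <- vapply(ks, function(k) wss(stats::cutree(hc, k)), numeric(1))
  kd <- 2:k_max
  DIFF <- (kd - 1)^(2 / p) * W[kd - 1] - kd^(2 / p) * W[kd]
  kk <- 2:(k_max - 1)
  KL <- abs(DIFF[match(kk, kd)] / DIFF[match(kk + 1, kd)])
  k_hat <- kk[which.max(KL)]
  structure(list(k = ks, W = W, DIFF = stats::setNames(DIFF, kd),
                 KL = stats::setNames(KL, kk), k_hat = k_hat),
            class = "kl_profile")
}

#' @export
print.kl_profile <- function(x, ...) {
  cat("Krzanowski-Lai profile over k = 2..", max(x$k), ": k_hat = ",
      x$k_hat, "\n", sep = "")
  invisible(x)
}

#' @export
plot.kl_profile <- function(x, ...) {
  graphics::plot(as.integer(names(x$KL)), x$KL, type = "b",
                 xlab = "number of clusters k", ylab = "KL index", ...)
  graphics::abline(v = x$k_hat, lty = 2)
  invisible(x)
}

#' Negative squared Euclidean similarity matrix of gene rows
#' @param m numeric matrix (genes x samples).
#' @return symmetric similarity matrix `s(i,k) = -||x_i - x_k||^2` with a
#'   zero diagonal (callers set the preference).
#' @export
negsq_similarity <- function(m) {
  s <- -as.matrix(stats::dist(m))^2
  diag(s) <- 0
  s
}

#' Affinity propagation clustering
#'
#' Message-passing clustering over a similarity matrix. Responsibilities
#' and availabilities are exchanged with damping `lambda` until the
#' exemplar set is stable for `conv_window` consecutive iterations or
#' `max_iters` is reached:
#' \deqn{r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}[a(i,k') + s(i,k')]}
#' \deqn{a(i,k) \leftarrow \min(0,\, r(k,k) + \sum_{i' \notin \{i,k\}}
#'   \max(0, r(i',k))), \quad i \ne k}
#' \deqn{a(k,k) \leftarrow \sum_{i' \ne k} \max(0, r(i',k))}
#' Exemplars are the points with `r(k,k) + a(k,k) > 0`; every other point
#' joins the exemplar of maximal similarity.
#'
#' @param S square similarity matrix (typically [negsq_similarity()]).
#' @param preference shared self-similarity put on the diagonal; higher
#'   values yield more clusters. Default: median off-diagonal similarity.
#' @param lambda damping factor in \[0.5, 1).
#' @param max_iters iteration cap (default 1000).
#' @param conv_window iterations of unchanged exemplar set declaring
#'   convergence (default 100).
#' @return An object of class `"ap_solution"`: list with `exemplars`
#'   (indices; names if S has dimnames), `assignment` (exemplar index per
#'   point), `k`, `preference`, `converged`, `iterations` and
#'   `net_similarity`. With no emerging exemplar, `k = 0` and an empty
#'   solution is returned (adjust the preference).
#' @export
affinity_propagation <- function(S, preference = NULL, lambda = 0.9,
                                 max_iters = 1000, conv_window = 100) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (lambda < 0.5 || lambda >= 1) stop("lambda must lie in [0.5, 1)")
  n <- nrow(S)
  offd <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(offd)
  diag(S) <- preference
  S0 <- S
  # exactly tied similarities make the messages oscillate symmetrically;
  # a deterministic perturbation of relative size 1e-12 breaks the ties
  rng <- max(S) - min(S)
  if (rng == 0) rng <- 1
  S <- S + 1e-12 * rng * matrix(seq_len(n * n), n, n) / (n * n)
  R <- A <- matrix(0, n, n)
  idx <- seq_len(n)
  ex_prev <- integer(0)
  stable <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iters) {
    iter <- iter + 1L
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    y1 <- AS[cbind(idx, i1)]
    AS[cbind(idx, i1)] <- -Inf
    y2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - y1
    Rnew[cbind(idx, i1)] <- S[cbind(idx, i1)] - y2
    R <- lambda * R + (1 - lambda) * Rnew
    P <- pmax(R, 0)
    diag(P) <- 0
    colS <- colSums(P)                    # sum_{i' != k} max(0, r(i',k))
    Anew <- pmin(matrix(diag(R) + colS, n, n, byrow = TRUE) - P, 0)
    diag(Anew) <- colS
    A <- lambda * A + (1 - lambda) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_window) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) {
    return(structure(list(exemplars = integer(0), assignment = integer(0),
                          k = 0L, preference = preference,
                          converged = FALSE, iterations = iter,
                          net_similarity = -Inf),
                     class = "ap_solution"))
  }
  ex <- unname(ex)
  assignment <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assignment <- unname(assignment)
  assignment[ex] <- ex
  net <- sum(S0[cbind(setdiff(idx, ex), assignment[setdiff(idx, ex)])]) +
    length(ex) * preference
  nm <- rownames(S)
  structure(list(exemplars = if (is.null(nm)) ex else
                   stats::setNames(ex, nm[ex]),
                 assignment = assignment, k = length(ex),
                 preference = preference, converged = converged,
                 iterations = iter, net_similarity = net),
            class = "ap_solution")
}

#' @export
print.ap_solution <- function(x, ...) {
  cat("affinity propagation:", x$k, "clusters",
      if (x$converged) "(converged)" else "(not converged)",
      "after", x$iterations, "iterations\n")
  cat("  preference:", format(x$preference, digits = 4),
      " net similarity:", format(x$net_similarity, digits = 4), "\n")
  invisible(x)
}

#' Affinity propagation forced to a target cluster count
#'
#' Bisects the shared preference until affinity propagation yields exactly
#' `k_target` clusters. The initial bracket is `[2 * min(offdiag S),
#' max(offdiag S)]`; if the target lies outside the counts achievable at
#' the bracket ends the bounds are expanded geometrically before
#' bisection. The probe budget caps the total number of affinity
#' propagation runs; if the exact count is not reached the closest
#' solution is returned with `target_reached = FALSE` (never an error).
#'
#' @param S similarity matrix as in [affinity_propagation()].
#' @param k_target desired cluster count, `1 <= k_target <= nrow(S)`.
#' @param lambda,max_iters,conv_window passed to [affinity_propagation()].
#' @param bisection_iters preference-probe budget (default 20).
#' @return an `"ap_solution"` with extra fields `target_k` and
#'   `target_reached`.
#' @export
ap_with_target_k <- function(S, k_target, lambda = 0.9, max_iters = 1000,
                             conv_window = 100, bisection_iters = 20) {
  n <- nrow(S)
  if (k_target < 1L || k_target > n)
    stop("k_target must lie in [1, ", n, "]")
  offd <- S[row(S) != col(S)]
  lo <- if (min(offd) < 0) 2 * min(offd) else -1
  hi <- max(offd)
  run <- function(pref) affinity_propagation(S, preference = pref,
                                             lambda = lambda,
                                             max_iters = max_iters,
                                             conv_window = conv_window)
  best <- NULL
  note <- function(sol) {
    if (is.null(best) ||
        abs(sol$k - k_target) < abs(best$k - k_target) ||
        (abs(sol$k - k_target) == abs(best$k - k_target) &&
         sol$converged && !best$converged))
      best <<- sol
    sol
  }
  probes <- 0L
  sol_lo <- note(run(lo)); probes <- probes + 1L
  sol_hi <- note(run(hi)); probes <- probes + 1L
  # expand the bracket if the target is not enclosed
  while (sol_hi$k < k_target && probes < bisection_iters) {
    hi <- if (hi < 0) hi / 4 else max(4 * hi, abs(lo) / 16, 1e-8)
    sol_hi <- note(run(hi)); probes <- probes + 1L
  }
  while (sol_lo$k > k_target && sol_lo$k > 0 && probes < bisection_iters) {
    lo <- 4 * lo
    sol_lo <- note(run(lo)); probes <- probes + 1L
  }
  while (probes < bisection_iters && best$k != k_target) {
    mid <- (lo + hi) / 2
    sol <- note(run(mid)); probes <- probes + 1L
    if (sol$k < k_target) lo <- mid else hi <- mid
  }
  best$target_k <- as.integer(k_target)
  best$target_reached <- best$k == k_target
  if (!best$target_reached)
    warning("target cluster count ", k_target, " not reached within the ",
            bisection_iters, "-probe budget; returning k = ", best$k)
  best
}
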