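# Shared fixtures and independent oracles used across test files.

make_dataset <- function(m, types) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  labels <- data.frame(sample_id = colnames(m), title = colnames(m),
                       type = types, stringsAsFactors = FALSE)
  apkl_dataset(m, labels)
}

random_dataset <- function(G, n0, n1, seed) {
  set.seed(seed)
  make_dataset(matrix(rnorm(G * (n0 + n1)), G, n0 + n1),
               c(rep(0L, n0), rep(1L, n1)))
}

# pooled two-sample t computed the pedestrian way (per probe, no floors)
oracle_pooled_t <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  sp2 <- ((n0 - 1) * var(x0) + (n1 - 1) * var(x1)) / (n0 + n1 - 2)
  (mean(x0) - mean(x1)) / sqrt(sp2 * (1 / n0 + 1 / n1))
}

# Exhaustive-enumeration maxT oracle: loops over every class assignment,
# recomputes t probe by probe, applies the step-down definition literally.
oracle_maxt <- function(m, types) {
  n <- ncol(m); G <- nrow(m)
  n1 <- sum(types == 1)
  combs <- utils::combn(n, n1)
  tmat <- sapply(seq_len(ncol(combs)), function(b) {
    memb <- seq_len(n) %in% combs[, b]
    vapply(seq_len(G), function(g)
      oracle_pooled_t(m[g, !memb], m[g, memb]), numeric(1))
  })
  id <- which(vapply(seq_len(ncol(combs)), function(b)
    setequal(combs[, b], which(types == 1)), logical(1)))
  t_obs <- tmat[, id]
  abs_obs <- abs(t_obs)
  ord <- order(-abs_obs, rownames(m))
  p_raw <- vapply(seq_len(G), function(g)
    mean(abs(tmat[g, ]) >= abs_obs[g]), numeric(1))
  p_adj_ord <- numeric(G)
  for (j in seq_len(G)) {
    u <- apply(abs(tmat)[ord[j:G], , drop = FALSE], 2, max)
    p_adj_ord[j] <- mean(u >= abs_obs[ord[j]])
  }
  p_adj_ord <- cummax(p_adj_ord)
  p_adj <- numeric(G)
  p_adj[ord] <- p_adj_ord
  list(t = t_obs, p_raw = p_raw, p_adj = p_adj)
}

# Net similarity of a candidate exemplar set, from first principles.
oracle_net_similarity <- function(S, ex, preference) {
  others <- setdiff(seq_len(nrow(S)), ex)
  sum(apply(S[others, ex, drop = FALSE], 1, max)) +
    length(ex) * preference
}

# All-subset optimal exemplar set (small n only).
oracle_best_exemplars <- function(S, preference) {
  n <- nrow(S)
  best <- NULL; best_val <- -Inf
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- oracle_net_similarity(S, ex, preference)
    if (val > best_val) { best_val <- val; best <- ex }
  }
  list(exemplars = best, value = best_val)
}

# Unit-weight closeness/betweenness oracle: Floyd-Warshall distances plus
# shortest-path counting by dynamic programming over increasing distance.
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(adj[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  list(closeness = clo, betweenness = btw)
}

# Literal O(n^3) data-processing-inequality scan.
oracle_aracne <- function(M, mode = "additive", eps = 0, tau = 0.15) {
  n <- nrow(M); W <- M; diag(W) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i >= j || k == i || k == j) next
    bound <- if (mode == "additive") min(M[i, k], M[j, k]) - eps
             else min(M[i, k], M[j, k]) * (1 - tau)
    if (M[i, j] < bound) W[i, j] <- W[j, i] <- 0
  }
  W
}

fig2_annotation_fixture <- function() {
  # 15 probes -> 10 distinct entrez ids -> 4 distinct pathways
  probes <- sprintf("x%02d", 1:15)
  annot <- data.frame(
    probe_id = probes,
    symbol = sprintf("SYM%d", c(1:10, 1:3, NA, NA))[1:15],
    entrez_id = c(sprintf("e%d", 1:10), sprintf("e%d", 1:3), NA, NA),
    ensembl_id = sprintf("ENSG%05d", 1:15),
    chromosome = rep(c("1", "7q21", "X"), 5),
    stringsAsFactors = FALSE)
  pathways <- data.frame(
    entrez_id = sprintf("e%d", 1:10),
    pathway_id = c(rep("P1", 3), rep("P2", 3), rep("P3", 3), "P4"),
    pathway_name = c(rep("path one", 3), rep("path two", 3),
                     rep("path three", 3), "path four"),
    stringsAsFactors = FALSE)
  list(annot = annot, pathways = pathways)
}

# Direct construction of a weighted_network object from a weight matrix.
new_weighted_network_for_test <- function(W, method) {
  diag(W) <- 0
  structure(list(genes = rownames(W), W = W, method = method),
            class = "weighted_network")
}
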