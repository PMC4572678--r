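test_that("mutual information respects self-information bounds", {
  set.seed(13)
  m <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:40)))
  m[2, ] <- m[1, ]                         # exact copy
  m[5, ] <- 3                              # constant gene
  mim <- mutual_information(m)
  mi <- mim$mi
  expect_true(isSymmetric(mi))
  expect_true(all(mi >= 0))
  # self-information dominates any partner, and a perfect copy attains it
  for (g in 1:4) expect_true(all(mi[g, g] >= mi[g, -g] - 1e-12))
  expect_equal(mi[1, 2], mi[1, 1], tolerance = 1e-12)
  # constant gene carries no information and is flagged
  expect_true(all(mi[5, ] == 0))
  expect_true(mim$constant["g5"])
})

test_that("independent profiles carry near-zero mutual information", {
  set.seed(19)
  m <- matrix(rnorm(2 * 1000), 2, 1000)
  rownames(m) <- c("a", "b")
  mim <- mutual_information(m, bins = 10)
  expect_lt(mim$mi["a", "b"], 0.05)
  # the plug-in bias shrinks as samples accumulate at fixed binning
  m_small <- m[, 1:100]
  expect_lt(mim$mi["a", "b"], mutual_information(m_small, bins = 10)$mi["a", "b"])
})

test_that("CLR highlights the standout pair and zeroes flat rows", {
  # 3-gene MI fixture with one standout pair (1,2)
  M <- rbind(c(1.0, 0.8, 0.1),
             c(0.8, 1.0, 0.1),
             c(0.1, 0.1, 1.0))
  dimnames(M) <- list(letters[1:3], letters[1:3])
  mim <- structure(list(mi = M, bins = 3L, estimator = "fixture",
                        constant = setNames(rep(FALSE, 3), letters[1:3])),
                   class = "mi_matrix")
  # row c has equal off-diagonal MI, so its z-scores degenerate (warned)
  expect_warning(net <- clr_weights(mim), "zero row sd")
  W <- net$W
  expect_true(isSymmetric(W))
  expect_true(all(diag(W) == 0))
  expect_true(W["a", "b"] > W["a", "c"] && W["a", "b"] > W["b", "c"])
  # hand z-score check: z_ab = max(0, (0.8 - 0.45) / sd(c(0.8, 0.1)))
  z_ab <- (0.8 - mean(c(0.8, 0.1))) / sd(c(0.8, 0.1))
  expect_equal(W["a", "b"], sqrt(2) * z_ab, tolerance = 1e-12)

  # uniform off-diagonal MI degenerates to the empty network
  U <- matrix(0.5, 4, 4); diag(U) <- 1
  dimnames(U) <- list(letters[1:4], letters[1:4])
  mim_u <- structure(list(mi = U, bins = 3L, estimator = "fixture",
                          constant = setNames(rep(FALSE, 4), letters[1:4])),
                     class = "mi_matrix")
  expect_warning(net_u <- clr_weights(mim_u), "zero row sd")
  expect_true(all(net_u$W == 0))
})

test_that("CLR weights do not depend on gene ordering", {
  set.seed(23)
  m <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:30)))
  W1 <- clr_weights(mutual_information(m))$W
  perm <- c(4, 2, 6, 1, 3, 5)
  W2 <- clr_weights(mutual_information(m[perm, ]))$W
  expect_equal(W2[rownames(W1), colnames(W1)], W1, tolerance = 1e-12)
})

test_that("ARACNE pruning matches the literal triple-scan oracle", {
  # chain X-Y-Z: the weakest closing edge is removed at eps = 0
  M <- rbind(c(0.0, 0.9, 0.2),
             c(0.9, 0.0, 0.8),
             c(0.2, 0.8, 0.0))
  dimnames(M) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  mk <- function(M) structure(list(mi = M, bins = 3L, estimator = "fixture",
                                   constant = setNames(rep(FALSE, nrow(M)),
                                                       rownames(M))),
                              class = "mi_matrix")
  W <- aracne_prune(mk(M), "additive", eps = 0)$W
  expect_identical(unname(W["X", "Z"]), 0)
  expect_equal(W["X", "Y"], 0.9)
  expect_equal(W["Y", "Z"], 0.8)

  # an equilateral MI triangle survives (strict inequality only)
  E <- matrix(0.5, 3, 3); diag(E) <- 0
  dimnames(E) <- dimnames(M)
  expect_true(all(aracne_prune(mk(E), "additive", eps = 0)$W[upper.tri(E)] ==
                    0.5))

  set.seed(31)
  for (mode in c("additive", "multiplicative")) {
    R <- matrix(runif(36, 0, 1), 6, 6)
    R <- (R + t(R)) / 2; diag(R) <- 0
    dimnames(R) <- list(letters[1:6], letters[1:6])
    got <- aracne_prune(mk(R), mode, eps = 0.02, tau = 0.15)$W
    want <- oracle_aracne(R, mode, eps = 0.02, tau = 0.15)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got <= R + 1e-12))    # pruning never adds weight
  }
})

test_that("weighted centralities match hand results on the path fixture", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 1
  W["B", "C"] <- W["C", "B"] <- 1
  st <- network_stats(new_weighted_network_for_test(W, "clr"))
  loc <- st$local
  expect_equal(loc$wdegree, c(1, 2, 1))
  expect_equal(loc$closeness, c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(loc$betweenness, c(0, 1, 0))
  expect_equal(loc$transitivity, c(0, 0, 0))

  # unit triangle: full transitivity, no betweenness
  Tw <- matrix(1, 3, 3); diag(Tw) <- 0
  dimnames(Tw) <- dimnames(W)
  st2 <- network_stats(new_weighted_network_for_test(Tw, "clr"))
  expect_equal(st2$local$transitivity, rep(1, 3))
  expect_equal(st2$global$transitivity_global, 1)
  expect_equal(st2$local$betweenness, rep(0, 3))

  # doubling weights doubles degree and closeness, fixes betweenness
  st3 <- network_stats(new_weighted_network_for_test(2 * W, "clr"))
  expect_equal(st3$local$wdegree, 2 * loc$wdegree)
  expect_equal(st3$local$closeness, 2 * loc$closeness)
  expect_equal(st3$local$betweenness, loc$betweenness)
})

test_that("centralities agree with the Floyd-Warshall oracle on random graphs", {
  set.seed(37)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    adj <- matrix(rbinom(n * n, 1, 0.35), n, n)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0
    dimnames(adj) <- list(sprintf("v%d", 1:n), sprintf("v%d", 1:n))
    st <- network_stats(new_weighted_network_for_test(adj + 0, "clr"))
    o <- oracle_centralities(adj)
    expect_equal(st$local$closeness, o$closeness, tolerance = 1e-10)
    expect_equal(st$local$betweenness, o$betweenness, tolerance = 1e-10)
    # leaves never lie on a shortest path between others
    leaves <- which(rowSums(adj) == 1)
    if (length(leaves))
      expect_true(all(st$local$betweenness[leaves] == 0))
  }
})

test_that("the hub rule keeps only degree outliers", {
  # 10-node star: the centre towers over the leaves
  n <- 10
  W <- matrix(0, n, n, dimnames = list(sprintf("v%d", 1:n),
                                       sprintf("v%d", 1:n)))
  W[1, 2:n] <- W[2:n, 1] <- 1
  st <- network_stats(new_weighted_network_for_test(W, "clr"))
  expect_identical(hub_filter(st), "v1")
  mu <- st$global$wdegree; sdv <- st$global$sd_wdegree
  expect_true(st$local$wdegree[1] > mu + 2 * sdv)

  # all-equal degrees: strict inequality leaves no hubs
  Tw <- matrix(1, 4, 4); diag(Tw) <- 0
  dimnames(Tw) <- list(letters[1:4], letters[1:4])
  expect_length(hub_filter(network_stats(
    new_weighted_network_for_test(Tw, "clr"))), 0)

  # invariance to node order
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 8, 10)
  stp <- network_stats(new_weighted_network_for_test(W[perm, perm], "clr"))
  expect_identical(hub_filter(stp), "v1")
})

test_that("edge lists export the positive upper triangle and round-trip", {
  W <- matrix(runif(16, 0.5, 1), 4, 4)
  W <- (W + t(W)) / 2; diag(W) <- 0
  dimnames(W) <- list(c("d", "b", "a", "c"), c("d", "b", "a", "c"))
  net <- new_weighted_network_for_test(W, "clr")
  el <- export_edge_list(net)
  expect_identical(nrow(el), 6L)                 # n(n-1)/2
  expect_true(all(el$Node1 < el$Node2))
  expect_true(all(el$weight > 0))

  f <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(net, f)
  expect_identical(readLines(f)[1], "Node1\tNode2\tweight")
  back <- utils::read.delim(f)
  rebuilt <- matrix(0, 4, 4, dimnames = dimnames(W))
  for (r in seq_len(nrow(back))) {
    rebuilt[back$Node1[r], back$Node2[r]] <- back$weight[r]
    rebuilt[back$Node2[r], back$Node1[r]] <- back$weight[r]
  }
  expect_equal(rebuilt, W, tolerance = 1e-10)

  # empty network: header only
  Z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  elz <- export_edge_list(new_weighted_network_for_test(Z, "clr"))
  expect_identical(nrow(elz), 0L)
})
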