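test_that("pooled t statistics match hand computation and guard degeneracy", {
  d <- make_dataset(rbind(p1 = c(1, 2, 3, 4, 5, 6),
                          p2 = c(5, 5, 5, 5, 5, 5),
                          p3 = c(0, 0, 0.5, 1, 1, 1.5)),
                    c(0, 0, 0, 1, 1, 1))
  t <- t_statistics(d)
  expect_equal(unname(t["p1"]), -3.674235, tolerance = 1e-6)
  expect_equal(unname(t["p1"]), oracle_pooled_t(c(1, 2, 3), c(4, 5, 6)))
  # constant probe: t = 0, flagged
  expect_identical(unname(t["p2"]), 0)
  expect_true(attr(t, "zero_variance")["p2"])
  # zero within-class variance but distinct means: finite capped |t|
  d2 <- make_dataset(rbind(p1 = c(0, 0, 0, 1, 1, 1)), c(0, 0, 0, 1, 1, 1))
  t2 <- t_statistics(d2)
  expect_true(is.finite(t2["p1"]) && abs(t2["p1"]) > 1e3)
  expect_true(attr(t2, "zero_variance")["p1"])
  # equal class means and variances -> t = 0
  d3 <- make_dataset(rbind(p1 = c(1, 2, 3, 1, 2, 3)), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(t_statistics(d3)["p1"]), 0)
  expect_error(t_statistics(make_dataset(rbind(p1 = c(1, 2, 3)),
                                         c(0, 0, 1))), "at least 2")
})

test_that("fold changes are class-mean differences and antisymmetric", {
  d <- make_dataset(rbind(p1 = c(2, 2, 2, 5, 5, 5),
                          p2 = c(1, 2, 3, 1, 2, 3)),
                    c(0, 0, 0, 1, 1, 1))
  fc <- fold_changes(d)
  expect_equal(unname(fc), c(3, 0))
  d_swap <- make_dataset(d$exprs, 1L - class_codes(d))
  expect_equal(fold_changes(d_swap), -fc)
})

test_that("maxT p-values agree exactly with exhaustive enumeration", {
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(rnorm(42), 7, 6,
                dimnames = list(sprintf("p%d", 1:7), sprintf("s%d", 1:6)))
    types <- c(0, 0, 0, 1, 1, 1)
    d <- make_dataset(m, types)
    r <- suppressMessages(maxt_adjusted(d, B = 100, seed = 1))
    expect_true(attr(r, "exhaustive"))
    expect_identical(attr(r, "n_perm"), 20L)
    o <- oracle_maxt(m, types)
    expect_equal(r$t, unname(o$t), tolerance = 1e-10)
    expect_equal(r$p_raw, o$p_raw, tolerance = 1e-12)
    expect_equal(r$p_adj, o$p_adj, tolerance = 1e-12)
  }
})

test_that("adjusted p-values dominate raw ones and are rank-monotone", {
  d <- random_dataset(G = 40, n0 = 8, n1 = 8, seed = 4)
  r <- maxt_adjusted(d, B = 200, seed = 2)
  expect_true(all(r$p_adj >= r$p_raw))
  expect_true(all(r$p_raw > 0 & r$p_raw <= 1))
  expect_true(all(diff(r$p_adj[order(r$rank)]) >= 0))
  # a single-probe family collapses to the raw p-value
  d1 <- random_dataset(G = 1, n0 = 6, n1 = 6, seed = 4)
  r1 <- maxt_adjusted(d1, B = 200, seed = 2)
  expect_identical(r1$p_adj, r1$p_raw)
  expect_error(maxt_adjusted(d, B = 50, seed = 1), "at least 100")
})

test_that("top-N selection follows |t| rank with lexical tie-breaks", {
  d <- make_dataset(rbind(b2 = c(0, 0, 0, 2, 2, 2),
                          a1 = c(0, 0, 0, 2, 2, 2),
                          c3 = c(0.1, 0, 0, 0, 0.1, 0)),
                    c(0, 0, 0, 1, 1, 1))
  r <- suppressMessages(maxt_adjusted(d, B = 100, seed = 1))
  expect_identical(r$probe[order(r$rank)], c("a1", "b2", "c3"))
  top <- select_top_n(r, d, 2)
  expect_identical(rownames(top), c("a1", "b2"))
  expect_identical(rownames(select_top_n(r, d, 1)), "a1")
  expect_identical(dim(select_top_n(r, d, 3)), dim(d$exprs))
  expect_error(select_top_n(r, d, 4), "exceeds")
})

test_that("the KL index recovers forced cluster geometry", {
  set.seed(10)
  two <- rbind(matrix(rnorm(10 * 6, 0, 0.3), 10, 6),
               matrix(rnorm(10 * 6, 20, 0.3), 10, 6))
  rownames(two) <- sprintf("g%d", 1:20)
  kl <- kl_cluster_count(two, k_max = 8)
  expect_identical(kl$k_hat, 2L)
  expect_true(all(diff(kl$W) <= 1e-8))
  expect_true(all(kl$KL >= 0))

  # W_k is non-increasing for arbitrary data too
  set.seed(11)
  rnd <- matrix(rnorm(25 * 5), 25, 5)
  klr <- kl_cluster_count(rnd, k_max = 10)
  expect_true(all(diff(klr$W) <= 1e-8))
  expect_true(klr$k_hat >= 2 && klr$k_hat <= 9)

  expect_error(kl_cluster_count(matrix(1, 30, 4), k_max = 5), "identical")
  expect_error(kl_cluster_count(rnd, k_max = 24), "k_max")
})

test_that("affinity propagation finds the brute-force optimal exemplars", {
  # 5 points in two distant tight groups
  set.seed(2)
  pts <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2),
               matrix(rnorm(4, 10, 0.1), 2, 2))
  S <- negsq_similarity(pts)
  pref <- median(S[row(S) != col(S)])
  sol <- affinity_propagation(S, preference = pref)
  expect_identical(sol$k, 2L)
  oracle <- oracle_best_exemplars(S, pref)
  # the achieved objective ties the brute-force optimum (exemplar identity
  # may tie within a group) and the grouping is the geometric one
  expect_equal(sol$net_similarity, oracle$value, tolerance = 1e-8)
  grp <- unname(split(1:5, sol$assignment))
  expect_setequal(lapply(grp, sort), list(1:3, 4:5))
  expect_length(intersect(unname(sol$exemplars), 1:3), 1)
  expect_length(intersect(unname(sol$exemplars), 4:5), 1)
  # damping strength does not change the converged answer
  sol05 <- affinity_propagation(S, preference = pref, lambda = 0.5)
  expect_setequal(unname(sol05$exemplars), unname(sol$exemplars))
})

test_that("identical points collapse to a single cluster", {
  for (pref in c(-0.5, -2, -10)) {
    sol <- affinity_propagation(matrix(0, 5, 5), preference = pref)
    expect_identical(sol$k, 1L)
    expect_true(all(sol$assignment == sol$exemplars))
  }
})

test_that("converged solutions resist single-exemplar swaps (n <= 8)", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(2 * n, sd = 2), n, 2)
    S <- negsq_similarity(pts)
    pref <- median(S[row(S) != col(S)])
    sol <- affinity_propagation(S, preference = pref)
    expect_true(sol$k > 0)
    ex <- sort(unname(sol$exemplars))
    others <- setdiff(seq_len(n), ex)
    for (e in ex) for (o in others) {
      swapped <- sort(c(setdiff(ex, e), o))
      expect_gte(sol$net_similarity + 1e-8,
                 oracle_net_similarity(S, swapped, pref))
    }
  }
})

test_that("preference bisection reaches the requested cluster count", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2),
               matrix(rnorm(4, 10, 0.1), 2, 2))
  S <- negsq_similarity(pts)
  # k = n: every point becomes its own exemplar
  sol_n <- ap_with_target_k(S, 5)
  expect_true(sol_n$target_reached)
  expect_setequal(unname(sol_n$exemplars), 1:5)
  # k = 1: the exemplar is the brute-force 1-medoid
  sol_1 <- ap_with_target_k(S, 1)
  expect_true(sol_1$target_reached)
  expect_identical(unname(sol_1$exemplars),
                   unname(which.max(colSums(S))))
  # k = 2 reproduces the median-preference partition
  sol_2 <- ap_with_target_k(S, 2)
  ref <- affinity_propagation(S, median(S[row(S) != col(S)]))
  expect_identical(unname(split(1:5, sol_2$assignment)),
                   unname(split(1:5, ref$assignment)))
  expect_error(ap_with_target_k(S, 9), "k_target")
})
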