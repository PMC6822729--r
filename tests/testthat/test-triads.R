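test_that("classification of all 64 labeled 3-node digraphs matches the isomorphism oracle", {
  for (code in 0:63) {
    a <- adj3_from_code(code)
    expect_equal(unname(classify_triad(a)), igraph_triad_class(a),
                 info = paste("code", code))
  }
})

test_that("triad class is invariant under all 6 node relabellings", {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (code in 0:63) {
    a <- adj3_from_code(code)
    ref <- classify_triad(a)
    for (p in perms)
      expect_equal(classify_triad(a[p, p]), ref)
  }
})

test_that("named triad classes match their structures", {
  expect_equal(unname(classify_triad(matrix(0, 3, 3))), 1)
  expect_equal(unname(classify_triad(rbind(c(1, 2), c(2, 3), c(3, 1)))), 10)
  expect_equal(unname(classify_triad(rbind(c(1, 2), c(1, 3)))), 4)  # out-star
  a <- matrix(1, 3, 3); diag(a) <- 0
  expect_equal(unname(classify_triad(a)), 16)
  expect_error(classify_triad(diag(3)), "self-loop")
})

test_that("triad census agrees with igraph on random digraphs and satisfies the counting identities", {
  set.seed(11)
  ec <- triad_classes()$edge_count
  for (r in 1:40) {
    n <- sample(4:7, 1)
    net <- random_network(n, runif(1, 0.1, 0.7))
    cen <- triad_census(net)
    expect_equal(as.integer(cen), as.integer(igraph::triad_census(as_igraph(net))))
    expect_equal(sum(cen), choose(n, 3))
    expect_equal(sum(ec * as.integer(cen)), n_edges(net) * (n - 2))
  }
})

test_that("census of the empty graph is concentrated in class 003", {
  cen <- triad_census(inhibition_network(matrix(0, 5, 5)))
  expect_equal(as.integer(cen), c(10, rep(0, 15)))
})

test_that("goodness-of-fit statistic follows the Pearson formula", {
  expect_equal(gof_chisq(c(10, 0), c(5, 5)), 10)
  expect_equal(gof_chisq(1:16, 1:16), 0)
  expect_error(gof_chisq(c(1, 2), c(0, 3)), "zero")
  # zero-zero categories are dropped, not NaN
  expect_equal(gof_chisq(c(3, 0), c(3, 0)), 0)
})

test_that("gof statistic grows as a single observed count moves away from expectation", {
  E <- c(5, 5, 5)
  base <- gof_chisq(c(5, 5, 5), E)
  worse <- gof_chisq(c(8, 5, 5), E)
  worst <- gof_chisq(c(11, 5, 5), E)
  expect_true(base < worse && worse < worst)
})

test_that("Monte-Carlo gof p-value is bounded and agrees with exact enumeration in a 2-category case", {
  set.seed(3)
  res <- monte_carlo_gof_p(c(15, 5), c(10, 10), n_sim = 4000)
  expect_gte(res$p, 1 / 4001)
  expect_lte(res$p, 1)
  # exact oracle: enumerate binomial(20, 1/2) outcomes
  k <- 0:20
  stat_k <- (k - 10)^2 / 10 + ((20 - k) - 10)^2 / 10
  exact <- sum(dbinom(k, 20, 0.5)[stat_k >= res$statistic])
  expect_equal(res$p, exact, tolerance = 0.05)
  # observation at expectation: p near 1
  res2 <- monte_carlo_gof_p(c(10, 10), c(10, 10), n_sim = 500)
  expect_gt(res2$p, 0.9)
})

test_that("cross-network chi-squared matches hand computations", {
  set.seed(4)
  tabs <- rbind(c(10, rep(0, 15)), c(0, 10, rep(0, 14)))
  expect_warning(res <- cross_network_chisq(tabs, n_sim = 200),
                 "all-zero")
  expect_equal(res$statistic, 20)
  same <- rbind(c(5, 3, rep(1, 14)), c(5, 3, rep(1, 14)))
  expect_equal(cross_network_chisq(same, n_sim = 100)$statistic, 0)
})

test_that("per-triad cross-network tests match the direct formula and skip absent triads", {
  cen <- rbind(A = c(10, rep(2, 15)), B = c(2, rep(2, 15)))
  cen[, 16] <- 0
  suppressMessages(res <- per_triad_cross_network_tests(cen, n_sim = 200))
  expect_false(res$tested[16])
  # direct 2x2 Pearson for triad 1
  two <- rbind(c(10, 2), c(sum(cen[1, ]) - 10, sum(cen[2, ]) - 2))
  E <- outer(rowSums(two), colSums(two)) / sum(two)
  expect_equal(res$statistic[1], sum((two - E)^2 / E))
  # equal counts with equal totals: statistic 0
  eq <- rbind(c(4, rep(2, 15)), c(4, rep(2, 15)))
  suppressMessages(res_eq <- per_triad_cross_network_tests(eq, n_sim = 100))
  expect_equal(res_eq$statistic[1], 0)
})

test_that("motif tests flag nothing when the census equals the null means, and BH matches the step-up procedure", {
  set.seed(5)
  net <- random_network(8, 0.4)
  ens <- degree_ensemble(net, n_reps = 50, seed = 1)
  fake <- ens
  fake$triads$mean <- as.numeric(triad_census(net))
  res <- motif_tests(triad_census(net), fake)
  expect_true(all(res$z[fake$triads$sd > 0] == 0))
  expect_false(any(res$motif))
  expect_true(all(res$p_fdr >= res$p))
  # BH step-up on a known p-vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.9)
  m <- length(p)
  stepup <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(stats::p.adjust(p, "BH"), pmin(stepup, 1))
})
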