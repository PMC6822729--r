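test_that("simulated communities hit the target density exactly per draw", {
  set.seed(61)
  prof <- community_profile(18, "bimodal", target_density = 0.258)
  for (r in 1:10) {
    net <- simulate_community(prof)
    expect_equal(n_edges(net), round(0.258 * 18 * 17))
    expect_true(all(diag(as.matrix(net)) == 0))
  }
  empty <- simulate_community(community_profile(10, target_density = 0))
  expect_equal(n_edges(empty), 0)
})

test_that("bimodal and unimodal profiles are separable by their out-degree distributions", {
  set.seed(62)
  draws <- function(prof, k = 60) {
    unlist(lapply(1:k, function(i)
      rowSums(as.matrix(simulate_community(prof)))))
  }
  bi <- draws(community_profile(18, "bimodal", target_density = 0.29))
  un <- draws(community_profile(18, "unimodal", target_density = 0.29,
                                mean = 5, sd = 2))
  ks <- suppressWarnings(stats::ks.test(bi, un))
  expect_lt(ks$p.value, 0.01)
  # bimodal draws occupy both modes
  expect_gt(mean(bi >= 12), 0.1)
  expect_gt(mean(bi <= 3), 0.4)
})

test_that("mutual_excess raises reciprocity", {
  set.seed(63)
  recip <- function(me, k = 40) {
    mean(sapply(1:k, function(i) {
      net <- simulate_community(community_profile(12, "even",
                                                  target_density = 0.3,
                                                  mutual_excess = me))
      dyad_census(net)[["mutual"]]
    }))
  }
  expect_gt(recip(8), recip(0) * 1.3)
})

test_that("degree-exact simulation realises requested sequences or errors with a reason", {
  net <- simulate_from_degrees(c(2, 0, 0), c(0, 1, 1), randomize = 0)
  expect_identical(unname(as.matrix(net)),
                   rbind(c(0L, 1L, 1L), c(0L, 0L, 0L), c(0L, 0L, 0L)))
  set.seed(64)
  for (r in 1:10) {
    src <- random_digraph(8, 0.4)
    net2 <- simulate_from_degrees(rowSums(src), colSums(src))
    expect_equal(unname(rowSums(as.matrix(net2))), unname(rowSums(src)))
    expect_equal(unname(colSums(as.matrix(net2))), unname(colSums(src)))
  }
  expect_error(simulate_from_degrees(c(1, 1, 1), c(3, 0, 0)),
               "not realizable")
  expect_error(simulate_from_degrees(c(3, 0, 0), c(1, 1, 1)),
               "exceeds n - 1")
  # repeated draws of a non-forced sequence vary
  set.seed(65)
  draws <- replicate(20, paste(as.matrix(
    simulate_from_degrees(c(1, 1, 0, 0), c(0, 0, 1, 1))), collapse = ""))
  expect_gt(length(unique(draws)), 1)
})

test_that("planted triads appear in the census with untouched surroundings", {
  set.seed(66)
  base <- inhibition_network(matrix(0, 9, 9))
  g <- plant_triads(base, 10, 2)
  expect_equal(unname(as.integer(triad_census(g))[10]), 2L)
  expect_equal(n_edges(g), 6)  # 3 arcs per 3-cycle
  g16 <- plant_triads(base, 16, 1)
  expect_equal(n_edges(g16), 6)  # complete mutual triad
  expect_error(plant_triads(base, 10, 4), "disjoint")
})

test_that("zone simulation round-trips through binarize", {
  set.seed(67)
  net <- sample_er(6, 12)
  exact <- simulate_zone_table(net, edge_zone_mean = 8, noise_sd = 0)
  expect_identical(as.matrix(binarize(exact)$all), as.matrix(net))
  # with noise well clear of the threshold recovery stays exact
  ok <- vapply(1:20, function(i) {
    m <- sample_er(6, 12)
    z <- simulate_zone_table(m, edge_zone_mean = 8, noise_sd = 1)
    identical(as.matrix(binarize(z)$all), as.matrix(m))
  }, logical(1))
  expect_equal(mean(ok), 1)
  z <- simulate_zone_table(net, edge_zone_mean = 8, noise_sd = 3)
  expect_true(all(z$zone_a_mm >= 0 & z$zone_b_mm >= 0))
  expect_equal(nrow(z), 6 * 5 * 3)
})

test_that("generators are seed-reproducible", {
  prof <- community_profile(10, "bimodal", target_density = 0.3)
  set.seed(68); a <- as.matrix(simulate_community(prof))
  set.seed(68); b <- as.matrix(simulate_community(prof))
  expect_identical(a, b)
  set.seed(68); z1 <- simulate_zone_table(sample_er(5, 8))
  set.seed(68); z2 <- simulate_zone_table(sample_er(5, 8))
  expect_identical(z1, z2)
})
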