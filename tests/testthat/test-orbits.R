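test_that("the orbit table enumerates the 30 positions with the right multiplicities", {
  tab <- orbit_table()
  expect_equal(nrow(tab), 30)
  expect_false(anyDuplicated(tab$orbit_id) > 0)
  per_class <- table(factor(tab$triad, levels = 4:16))
  expect_equal(unname(c(per_class)), c(2, 2, 3, 3, 3, 3, 1, 2, 2, 2, 3, 3, 1))
  # orbit sizes within each class account for all 3 nodes
  expect_true(all(tapply(tab$multiplicity, tab$triad, sum) == 3))
  # the 3-cycle has the single symmetric (1,1) position
  t10 <- tab[tab$triad == 10, ]
  expect_equal(nrow(t10), 1)
  expect_equal(c(t10$out_degree, t10$in_degree), c(1, 1))
})

test_that("the (out, in) key matches brute-force automorphism orbits in every connected class", {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  tab <- orbit_table()
  for (cls in 4:16) {
    arcs <- antagonet:::.triad_representatives()[[cls]]
    a <- antagonet:::.arcs_to_adj3(arcs)
    # automorphism oracle: nodes u, v equivalent iff some permutation fixes
    # the graph and maps u to v
    autos <- Filter(function(p) identical(a[p, p], a), perms)
    orbit_of <- sapply(1:3, function(u) min(sapply(autos, function(p) p[u])))
    expect_equal(length(unique(orbit_of)), sum(tab$triad == cls),
                 info = paste("class", cls))
    # nodes in the same automorphism orbit share (out, in); different orbits differ
    key <- paste(rowSums(a), colSums(a))
    expect_equal(length(unique(key)), length(unique(orbit_of)),
                 info = paste("class", cls))
  }
})

test_that("orbit counts of small named graphs are as expected", {
  star <- inhibition_network(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
  oc <- node_orbit_census(star)
  expect_equal(unname(oc[1, "t4.2.0"]), 1L)
  expect_equal(unname(oc[2, "t4.0.1"]), 1L)
  expect_equal(unname(oc[3, "t4.0.1"]), 1L)
  expect_equal(sum(oc), 3L)
  k3 <- inhibition_network(matrix(1, 3, 3) - diag(3))
  ock <- node_orbit_census(k3)
  expect_equal(unname(ock[, "t16.2.2"]), rep(1L, 3))
})

test_that("orbit census is consistent with the triad census on random digraphs", {
  set.seed(51)
  tab <- orbit_table()
  for (r in 1:20) {
    n <- sample(5:7, 1)
    net <- random_network(n, runif(1, 0.15, 0.7))
    cen <- as.integer(triad_census(net))
    oc <- node_orbit_census(net)
    for (cls in 4:16) {
      cols <- tab$triad == cls
      expect_equal(sum(oc[, cols]), 3 * cen[cls])
      # per-orbit totals are multiplicity x class count
      expect_equal(unname(colSums(oc[, cols, drop = FALSE])),
                   tab$multiplicity[cols] * cen[cls])
    }
  }
})

test_that("signature rows are unit vectors after the square-root transform", {
  counts <- rbind(one = c(7, rep(0, 29)),
                  two = c(1, 3, rep(0, 28)),
                  none = rep(0, 30))
  sig <- signature_matrix(counts)
  expect_equal(unname(sig["one", 1]), 1)
  expect_equal(unname(sig["two", 1:2]), sqrt(c(0.25, 0.75)))
  expect_equal(unname(rowSums(sig^2)[1:2]), c(1, 1))
  expect_equal(attr(sig, "zero_participation"), "none")
  raw <- signature_matrix(counts, transform = "raw")
  expect_equal(unname(raw["two", 2]), 0.75)
})

test_that("Shannon diversity of participation matches closed forms and bounds", {
  expect_equal(unname(node_shannon(c(5, rep(0, 29)))), 0)
  expect_equal(unname(node_shannon(c(4, 4, 4, 4, rep(0, 26)))), log(4))
  expect_equal(unname(node_shannon(rep(1, 30))), log(30))
  expect_equal(unname(node_shannon(c(1, 3, rep(0, 28)), base = 2)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  set.seed(52)
  h <- node_shannon(matrix(rpois(300, 2), 10, 30))
  expect_true(all(h >= 0 & h <= log(30)))
  expect_equal(unname(node_shannon(rep(0, 30))), 0)  # flagged, not NaN
})

test_that("signature clustering merges identical vectors first and recovers planted groups", {
  patt <- list(c(rep(8, 5), rep(0, 25)),
               c(rep(0, 12), rep(8, 5), rep(0, 13)),
               c(rep(0, 25), rep(8, 5)))
  set.seed(53)
  counts <- do.call(rbind, lapply(1:3, function(g) {
    t(sapply(1:6, function(i) patt[[g]] + rpois(30, 0.3)))
  }))
  rownames(counts) <- sprintf("n%02d", 1:18)
  truth <- rep(1:3, each = 6)
  cl <- cluster_signatures(counts, k = 3)
  expect_gt(rand_index(cl$clusters[rownames(counts)], truth), 0.9)
  # identical vectors are at distance 0 and merge first
  dup <- rbind(a = patt[[1]], b = patt[[1]], c = patt[[2]], d = patt[[3]])
  cl2 <- cluster_signatures(dup)
  expect_equal(cl2$tree$height[1], 0)
  expect_equal(sort(cl2$tree$merge[1, ]), c(-2, -1))
  # input-order invariance
  perm <- sample(nrow(counts))
  cl3 <- cluster_signatures(counts[perm, ], k = 3)
  expect_gt(rand_index(cl3$clusters[rownames(counts)],
                       cl$clusters[rownames(counts)]), 0.999)
})

test_that("dendrograms export as parseable Newick with all leaves", {
  counts <- rbind(a = c(5, 1, rep(0, 28)), b = c(0, 5, 1, rep(0, 27)),
                  c = c(1, 0, 5, rep(0, 27)))
  cl <- cluster_signatures(counts)
  tf <- tempfile(fileext = ".nwk")
  write_dendrogram(cl, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("zero and constant signatures are excluded from clustering with a warning", {
  counts <- rbind(a = c(5, rep(0, 29)), b = c(0, 5, rep(0, 28)),
                  c = c(1, 2, rep(0, 28)), z = rep(0, 30))
  expect_warning(cl <- cluster_signatures(counts), "zero or constant")
  expect_equal(cl$excluded, "z")
  expect_setequal(cl$used, c("a", "b", "c"))
})

test_that("the community ANOVA reproduces a hand-computed F and detects equal means", {
  # toy: groups (1, 2, 3) and (4, 5, 6): SSB = 13.5, SSW = 4, F = 13.5/1
  h <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("x", "y"), each = 3)
  res <- community_anova(h, g)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, 1 - pf(13.5, 1, 4))
  eq <- community_anova(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(eq$F, 0)
  expect_error(community_anova(c(1, 2, 3), c("x", "x", "y")), "at least 2")
})
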