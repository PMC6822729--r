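write_zone_file <- function(df, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  utils::write.csv(df, tf, row.names = FALSE)
  tf
}

full_zone_df <- function(labels, zones, replicates = 3) {
  # zones: named vector "src>tgt" -> mean zone; unnamed pairs get 0
  rows <- expand.grid(source = labels, target = labels,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  key <- paste0(rows$source, ">", rows$target)
  mu <- ifelse(key %in% names(zones), zones[key], 0)
  data.frame(rows, zone_a_mm = unname(mu), zone_b_mm = unname(mu))
}

test_that("well-formed zone tables read completely; deficient pairs warn", {
  df <- full_zone_df(c("a", "b", "c"), c(`a>b` = 5))
  z <- read_zone_table(write_zone_file(df))
  expect_s3_class(z, "zone_table")
  expect_equal(nrow(z), 9 * 3)   # 9 ordered pairs (self rows permitted) x 3
  df2 <- df[-1, ]                # drop one replicate of one pair
  expect_warning(read_zone_table(write_zone_file(df2)), "fewer than 3")
})

test_that("malformed and negative measurements are rejected with location info", {
  df <- full_zone_df(c("a", "b"), c(`a>b` = 5), replicates = 1)
  df$zone_a_mm[2] <- -1.0
  expect_error(read_zone_table(write_zone_file(df)), "negative")
  df$zone_a_mm[2] <- "oops"
  expect_error(read_zone_table(write_zone_file(df)), "malformed")
})

test_that("binarize applies the strict > threshold rule to the replicate-mean zone", {
  z <- data.frame(source = c("a", "a"), target = c("b", "c"),
                  replicate = c(1, 1),
                  zone_a_mm = c(3.5, 2.0), zone_b_mm = c(3.5, 2.0))
  net <- binarize(z)$all
  expect_equal(as.matrix(net)["a", "b"], 1L)   # 3.5 mm -> edge
  expect_equal(as.matrix(net)["a", "c"], 0L)   # exactly 2.0 mm -> no edge
})

test_that("binarize recovers a hand-specified 3-isolate toy", {
  zones <- c(`A>B` = 4, `B>A` = 0, `A>C` = 2, `C>A` = 5, `B>C` = 0, `C>B` = 0)
  z <- full_zone_df(c("A", "B", "C"), zones)
  adj <- as.matrix(binarize(z)$all)
  expected <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"),
                                               c("A", "B", "C")))
  expected["A", "B"] <- 1L; expected["C", "A"] <- 1L
  expect_identical(adj, expected)
})

test_that("binarize averages perpendicular measurements before thresholding", {
  z <- data.frame(source = "a", target = "b", replicate = 1:2,
                  zone_a_mm = c(0, 0), zone_b_mm = c(10, 0))
  # replicate means 5 and 0 -> grand mean 2.5 > 2
  expect_equal(as.matrix(binarize(z)$all)["a", "b"], 1L)
})

test_that("binarize is monotone in the threshold", {
  set.seed(31)
  net <- random_network(6, 0.4)
  z <- simulate_zone_table(net, edge_zone_mean = 6, noise_sd = 2)
  thresholds <- c(0, 1, 2, 4, 6, 9)
  counts <- vapply(thresholds,
                   function(th) n_edges(binarize(z, threshold = th)$all),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("binarize splits by community and uses only sympatric pairs", {
  zones <- c(`a1>a2` = 6, `a2>a1` = 6, `b1>b2` = 6, `a1>b1` = 9)
  z <- full_zone_df(c("a1", "a2", "b1", "b2"), zones)
  comm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  nets <- binarize(z, communities = comm)
  expect_named(nets, c("A", "B"))
  expect_equal(n_edges(nets$A), 2)
  expect_equal(n_edges(nets$B), 1)  # cross-community a1>b1 excluded
  expect_error(binarize(z, communities = comm[-1]), "without community")
})

test_that("matrix write/read round-trips and self-pairs never become edges", {
  set.seed(32)
  net <- random_network(5, 0.5)
  tf <- tempfile(fileext = ".csv")
  write_inhibition_matrix(net, tf)
  back <- read_inhibition_matrix(tf)
  expect_identical(as.matrix(back), as.matrix(net))
  # diagonal-only matrix reads as an edgeless network
  tf2 <- tempfile(fileext = ".tsv")
  m <- diag(4)
  dimnames(m) <- list(letters[1:4], letters[1:4])
  utils::write.table(m, tf2, sep = "\t", col.names = NA, quote = FALSE)
  expect_equal(n_edges(read_inhibition_matrix(tf2)), 0)
  # malformed matrices are rejected
  tf3 <- tempfile(fileext = ".csv")
  writeLines(c("x,a,b", "a,0,2", "b,1,0"), tf3)
  expect_error(read_inhibition_matrix(tf3), "0 or 1")
})

test_that("edge-list export has one source-target row per edge", {
  net <- inhibition_network(rbind(c(0, 1, 1), c(0, 0, 0), c(1, 0, 0)))
  tf <- tempfile(fileext = ".tsv")
  write_edge_list(net, tf)
  el <- utils::read.delim(tf)
  expect_equal(nrow(el), 3)
  expect_named(el, c("source", "target"))
})
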