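# shared helpers: random digraphs, tiny oracles, cluster agreement

# random simple digraph adjacency with edge probability p
random_digraph <- function(n, p = 0.35) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

random_network <- function(n, p = 0.35) {
  suppressWarnings(inhibition_network(random_digraph(n, p)))
}

# 3x3 adjacency from a 6-bit code, same arc order as the package encoding
adj3_from_code <- function(code) {
  bits <- as.integer(intToBits(code)[1:6])
  a <- matrix(0L, 3, 3)
  a[1, 2] <- bits[1]; a[2, 1] <- bits[2]
  a[1, 3] <- bits[3]; a[3, 1] <- bits[4]
  a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
  a
}

# independent classification of a 3-node digraph via igraph's triad census
igraph_triad_class <- function(a3) {
  g <- igraph::graph_from_adjacency_matrix(a3, mode = "directed")
  which(igraph::triad_census(g) == 1)
}

# Rand index between two flat clusterings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

fixture_path <- function(id) {
  system.file("extdata", sprintf("synthetic-community-%s.csv", id),
              package = "antagonet", mustWork = TRUE)
}

fixture_networks <- function() {
  ids <- c("A", "B", "C")
  setNames(lapply(ids, function(id)
    read_inhibition_matrix(fixture_path(id), community_id = id)), ids)
}
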