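# Synthetic-community generator: seedable simulation of inhibition networks
# with the degree structure seen in sympatric Streptomyces communities
# (a few high out-degree "super-killers" among many weak inhibitors), plus
# degree-exact samplers, planted triads and raw zone-table simulation.

#' Define a synthetic community profile
#'
#' Describes the statistical structure of a community to simulate.  The
#' defaults emulate the assayed prairie-soil communities: 17-18 isolates,
#' directed edge density around 0.26-0.33, and a bimodal out-degree
#' distribution in which a small fraction of "super-killer" isolates
#' inhibit most of the community while the rest inhibit few.
#'
#' @param n_isolates Community size (default 18).
#' @param model Out-degree model: `"bimodal"` (super-killers plus weak
#'   inhibitors), `"even"` (uniform over `range`), or `"unimodal"`
#'   (normal with `mean` and `sd`, rounded and truncated).
#' @param target_density Desired directed edge density, or `NULL` to use
#'   the raw degree draws unscaled.  When given, drawn out-degrees are
#'   rescaled (largest-remainder allocation, capped at `n - 1`) so every
#'   realisation has exactly `round(target_density * n * (n-1))` edges.
#' @param p_super,high_range,low_range Bimodal parameters: fraction of
#'   super-killers and the inclusive out-degree ranges for the two modes.
#' @param range `even` model range.
#' @param mean,sd `unimodal` model parameters.
#' @param mutual_excess Propensity (>= 0) for reciprocated edges: when
#'   assigning targets of an isolate, targets already inhibiting it get
#'   weight `1 + mutual_excess`.  Default 0 (independent placement).
#' @return An object of class `community_profile`.
#' @examples
#' community_profile(18, "bimodal", target_density = 0.26)
#' @export
community_profile <- function(n_isolates = 18,
                              model = c("bimodal", "even", "unimodal"),
                              target_density = 0.29,
                              p_super = 0.2,
                              high_range = c(14, 17),
                              low_range = c(0, 3),
                              range = c(0, 10),
                              mean = 5, sd = 2,
                              mutual_excess = 0) {
  model <- match.arg(model)
  stopifnot(n_isolates >= 3, mutual_excess >= 0,
            is.null(target_density) ||
              (target_density >= 0 && target_density <= 1),
            p_super >= 0, p_super <= 1)
  structure(list(n_isolates = n_isolates, model = model,
                 target_density = target_density, p_super = p_super,
                 high_range = high_range, low_range = low_range,
                 range = range, mean = mean, sd = sd,
                 mutual_excess = mutual_excess),
            class = "community_profile")
}

# integer allocation of m edges proportional to non-negative weights,
# capped at n-1 per node (largest-remainder method)
.allocate_degrees <- function(w, m, cap) {
  n <- length(w)
  if (m == 0) return(integer(n))
  if (sum(w) == 0) w <- rep(1, n)
  x <- w / sum(w) * m
  d <- pmin(floor(x), cap)
  frac <- x - floor(x)
  ord <- order(frac, decreasing = TRUE)
  i <- 1
  while (sum(d) < m) {
    j <- ord[(i - 1) %% n + 1]
    if (d[j] < cap) d[j] <- d[j] + 1L
    i <- i + 1
    if (i > 100 * n) stop("cannot allocate ", m, " edges under the cap")
  }
  as.integer(d)
}

#' Simulate a synthetic inhibition community
#'
#' Draws per-isolate out-degrees from the profile's model, rescales them to
#' the target density when one is set, and assigns each isolate's targets
#' at random (optionally biased towards reciprocation).  The result is a
#' simple directed network.
#'
#' @param profile A [community_profile()].
#' @param labels Optional isolate labels.
#' @return An [inhibition_network()].
#' @examples
#' set.seed(42)
#' net <- simulate_community(community_profile(18))
#' network_metrics(net)
#' @export
simulate_community <- function(profile, labels = NULL) {
  stopifnot(inherits(profile, "community_profile"))
  n <- profile$n_isolates
  cap <- n - 1L
  draw <- switch(profile$model,
    bimodal = {
      super <- stats::runif(n) < profile$p_super
      lo <- profile$low_range; hi <- profile$high_range
      ifelse(super,
             sample(hi[1]:hi[2], n, replace = TRUE),
             sample(lo[1]:lo[2], n, replace = TRUE))
    },
    even = sample(profile$range[1]:profile$range[2], n, replace = TRUE),
    unimodal = pmax(0, round(stats::rnorm(n, profile$mean, profile$sd)))
  )
  draw <- pmin(draw, cap)
  if (!is.null(profile$target_density)) {
    m <- round(profile$target_density * n * (n - 1))
    out_deg <- .allocate_degrees(draw, m, cap)
  } else {
    out_deg <- as.integer(draw)
  }
  A <- matrix(0L, n, n)
  for (i in sample.int(n)) {
    if (out_deg[i] == 0) next
    cand <- setdiff(seq_len(n), i)
    w <- 1 + profile$mutual_excess * A[cand, i]
    tgt <- sample(cand, out_deg[i], prob = w)
    A[i, tgt] <- 1L
  }
  if (is.null(labels)) labels <- sprintf("iso%02d", seq_len(n))
  dimnames(A) <- list(labels, labels)
  inhibition_network(A, community_id = "synthetic")
}

#' Simulate a digraph with exact in- and out-degree sequences
#'
#' Builds a simple digraph realising the given degree sequences with a
#' directed Havel-Hakimi-type greedy construction (each source is wired to
#' the targets with the largest residual in-degree demand), then optionally
#' randomised by degree-preserving edge swaps so repeated draws vary.
#'
#' @param out_seq,in_seq Non-negative integer vectors of equal length with
#'   equal sums.
#' @param randomize Number of post-construction swap attempts (default
#'   `10 * sum(out_seq)`; set 0 for the deterministic greedy graph).
#' @return An [inhibition_network()] whose degree sequences equal the
#'   request exactly; an error names the violated condition when the
#'   sequences are not realizable as a simple digraph.
#' @examples
#' net <- simulate_from_degrees(c(2, 0, 0), c(0, 1, 1), randomize = 0)
#' as.matrix(net)  # the out-star, forced
#' @export
simulate_from_degrees <- function(out_seq, in_seq,
                                  randomize = 10 * sum(out_seq)) {
  out_seq <- as.integer(out_seq); in_seq <- as.integer(in_seq)
  n <- length(out_seq)
  if (length(in_seq) != n) stop("degree sequences must have equal length")
  if (any(out_seq < 0) || any(in_seq < 0)) stop("degrees must be non-negative")
  if (sum(out_seq) != sum(in_seq))
    stop("sum(out_seq) must equal sum(in_seq)")
  if (any(out_seq > n - 1) || any(in_seq > n - 1))
    stop("a degree exceeds n - 1: not realizable as a simple digraph")
  A <- matrix(0L, n, n)
  res_out <- out_seq
  res_in <- in_seq
  # Kleitman-Wang: satisfy one node's in-degree at a time (node choice is
  # arbitrary) from the sources with lexicographically largest residual
  # (out-degree, in-degree); the secondary key matters for correctness.
  # Remaining ties are broken at random so draws vary.
  for (j in sample.int(n)) {
    k <- in_seq[j]
    res_in[j] <- 0L
    if (k == 0) next
    cand <- setdiff(seq_len(n), j)
    cand <- cand[res_out[cand] > 0]
    if (length(cand) < k)
      stop("sequences not realizable: node ", j, " needs ", k,
           " in-edges but only ", length(cand), " have residual out-degree")
    cand <- cand[order(res_out[cand], res_in[cand],
                       stats::runif(length(cand)), decreasing = TRUE)]
    src <- cand[seq_len(k)]
    A[src, j] <- 1L
    res_out[src] <- res_out[src] - 1L
  }
  if (randomize > 0) A <- .rewire_adj(A, randomize)$adj
  inhibition_network(A, community_id = "synthetic")
}

#' Plant triad instances into a network
#'
#' Overwrites the internal edges of randomly chosen disjoint node triples
#' so that each realises the requested triad class exactly (the three class
#' representative labels are assigned to the triple in random order).
#' Edges outside the chosen triples are untouched.
#'
#' @param net An [inhibition_network()].
#' @param triad_class Class index 1..16 (see [triad_classes()]).
#' @param count Number of disjoint instances to plant (`3 * count` must not
#'   exceed the node count).
#' @return The modified [inhibition_network()], with the planted triples
#'   (a 3 x count matrix of node indices) in attribute `"planted"`.
#' @examples
#' set.seed(7)
#' g <- plant_triads(inhibition_network(matrix(0, 9, 9)), 10, 2)
#' triad_census(g)[10]
#' @export
plant_triads <- function(net, triad_class, count) {
  stopifnot(inherits(net, "inhibition_network"),
            triad_class %in% 1:16, count >= 1)
  A <- as.matrix(net)
  n <- nrow(A)
  if (3 * count > n)
    stop("cannot plant ", count, " disjoint triads in ", n, " nodes")
  nodes <- sample.int(n, 3 * count)
  triples <- matrix(nodes, nrow = 3)
  rep_adj <- .arcs_to_adj3(.triad_representatives()[[triad_class]])
  for (j in seq_len(count)) {
    tri <- triples[sample.int(3), j]
    A[tri, tri] <- rep_adj
  }
  out <- inhibition_network(A, community_id = net$community_id)
  attr(out, "planted") <- triples
  out
}

# normal truncated at zero (exact inverse-cdf truncation; sd = 0 degenerates
# to the mean)
.rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(pmax(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate a raw inhibition-zone table from a known network
#'
#' Generates replicated assay measurements whose binarization should
#' recover the network: ordered pairs with a true edge draw zone sizes from
#' a normal distribution with mean `edge_zone_mean`, non-edges from a
#' normal centred at 0, both truncated at 0 mm; each pair gets two
#' perpendicular measurements per replicate.  With
#' `edge_zone_mean > threshold + ~3 * noise_sd` the round trip through
#' [binarize()] is essentially exact.
#'
#' @param net The true [inhibition_network()].
#' @param edge_zone_mean Mean zone (mm) for inhibitory pairs (default 8).
#' @param noise_sd Measurement noise sd in mm (default 1).
#' @param n_replicates Replicates per ordered pair (default 3).
#' @return A `zone_table` data frame (columns `source`, `target`,
#'   `replicate`, `zone_a_mm`, `zone_b_mm`) covering every ordered pair of
#'   distinct isolates.
#' @examples
#' set.seed(1)
#' net <- sample_er(5, 8)
#' z <- simulate_zone_table(net)
#' identical(as.matrix(binarize(z)$all), as.matrix(net))
#' @export
simulate_zone_table <- function(net, edge_zone_mean = 8, noise_sd = 1,
                                n_replicates = 3) {
  stopifnot(inherits(net, "inhibition_network"),
            edge_zone_mean >= 0, noise_sd >= 0, n_replicates >= 1)
  A <- as.matrix(net)
  lab <- rownames(A)
  n <- nrow(A)
  pairs <- which(diag(n) == 0, arr.ind = FALSE)
  src <- ((pairs - 1) %% n) + 1
  tgt <- ((pairs - 1) %/% n) + 1
  k <- length(pairs)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    mu <- ifelse(A[pairs] == 1L, edge_zone_mean, 0)
    rows[[r]] <- data.frame(
      source = lab[src], target = lab[tgt], replicate = r,
      zone_a_mm = .rtrunc0(k, mu, noise_sd),
      zone_b_mm = .rtrunc0(k, mu, noise_sd),
      stringsAsFactors = FALSE)
  }
  z <- do.call(rbind, rows)
  z <- z[order(z$source, z$target, z$replicate), ]
  rownames(z) <- NULL
  class(z) <- c("zone_table", "data.frame")
  z
}
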