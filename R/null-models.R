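# The three null-model ensembles (Erdos-Renyi, dyad-conditioned,
# degree-preserving rewiring) and z-tests of observed statistics against
# ensemble distributions.

.off_diagonal <- function(n) which(diag(n) == 0)

.sample_er_adj <- function(n, m) {
  A <- matrix(0L, n, n)
  A[sample(.off_diagonal(n), m)] <- 1L
  A
}

#' Sample an Erdos-Renyi directed graph with fixed edge count
#'
#' Draws a simple digraph with exactly `m` edges placed uniformly at random
#' (without replacement) among the `n (n - 1)` ordered node pairs; no
#' self-loops.
#'
#' @param n Number of nodes.
#' @param m Number of directed edges, `0 <= m <= n (n - 1)`.
#' @param labels Optional node labels.
#' @return An [inhibition_network()].
#' @examples
#' set.seed(1)
#' sample_er(18, 79)
#' @export
sample_er <- function(n, m, labels = NULL) {
  if (m < 0 || m > n * (n - 1))
    stop("'m' must be between 0 and n(n-1) = ", n * (n - 1))
  A <- .sample_er_adj(n, m)
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  inhibition_network(A, community_id = "er")
}

#' Dyad census of a directed network
#'
#' Counts the unordered node pairs that are mutually connected (`mutual`),
#' connected in one direction only (`asym`), or unconnected (`null`).
#'
#' @param net An [inhibition_network()].
#' @return A named integer vector `c(mutual, asym, null)` summing to
#'   `n (n - 1) / 2`.
#' @export
dyad_census <- function(net) {
  A <- as.matrix(net)
  n <- nrow(A)
  mut <- sum(A * t(A)) / 2
  asym <- sum(A) - 2 * mut
  c(mutual = as.integer(mut), asym = as.integer(asym),
    null = as.integer(n * (n - 1) / 2 - mut - asym))
}

#' Recover the dyad census from a triad census
#'
#' Every unordered node pair lies in exactly `n - 2` triads, so the dyad
#' census is a fixed linear function of the 16-class triad census.  This
#' makes the dyad-conditioned null model runnable from a published triad
#' census alone, without the underlying network.
#'
#' @param census A 16-vector of triad class counts (standard order).
#' @param n Number of nodes of the network the census came from.
#' @return A named integer vector as in [dyad_census()].
#' @examples
#' net <- sample_er(10, 30)
#' identical(dyad_census_from_triads(triad_census(net), 10), dyad_census(net))
#' @export
dyad_census_from_triads <- function(census, n) {
  census <- as.numeric(census)
  stopifnot(length(census) == 16, n >= 3)
  cls <- triad_classes()
  M <- sum(cls$mutual * census) / (n - 2)
  A <- sum(cls$asym * census) / (n - 2)
  N <- sum(cls$null * census) / (n - 2)
  out <- c(mutual = M, asym = A, null = N)
  if (max(abs(out - round(out))) > 1e-8)
    stop("census is not consistent with any dyad census at n = ", n)
  stats::setNames(as.integer(round(out)), names(out))
}

.sample_dyad_adj <- function(mutual, asym, null, n) {
  if (mutual + asym + null != n * (n - 1) / 2)
    stop("dyad census inconsistent with n = ", n,
         " (pairs must total n(n-1)/2)")
  pairs <- utils::combn(n, 2)
  type <- sample(rep.int(1:3, c(mutual, asym, null)))
  A <- matrix(0L, n, n)
  mu <- pairs[, type == 1L, drop = FALSE]
  A[cbind(mu[1, ], mu[2, ])] <- 1L
  A[cbind(mu[2, ], mu[1, ])] <- 1L
  as <- pairs[, type == 2L, drop = FALSE]
  if (ncol(as)) {
    flip <- stats::runif(ncol(as)) < 0.5
    from <- ifelse(flip, as[2, ], as[1, ])
    to <- ifelse(flip, as[1, ], as[2, ])
    A[cbind(from, to)] <- 1L
  }
  A
}

#' Sample a dyad-conditioned random digraph
#'
#' Draws a simple digraph whose dyad census (mutual / asymmetric / null
#' pair counts) equals the given one: dyad types are assigned uniformly at
#' random to the `n (n - 1) / 2` unordered pairs and each asymmetric dyad is
#' oriented by a fair coin.
#'
#' @param dyads A named vector as from [dyad_census()] (names `mutual`,
#'   `asym`, `null`), or an [inhibition_network()] whose census is used.
#' @param n Number of nodes (taken from the network when one is given).
#' @return An [inhibition_network()].
#' @export
sample_dyad_conditioned <- function(dyads, n = NULL) {
  if (inherits(dyads, "inhibition_network")) {
    n <- n_nodes(dyads)
    dyads <- dyad_census(dyads)
  }
  stopifnot(!is.null(n), all(c("mutual", "asym", "null") %in% names(dyads)))
  A <- .sample_dyad_adj(dyads[["mutual"]], dyads[["asym"]], dyads[["null"]], n)
  inhibition_network(A, community_id = "dyad")
}

.rewire_adj <- function(A, n_swaps) {
  el <- which(A == 1L, arr.ind = TRUE)
  m <- nrow(el)
  if (m < 2) return(list(adj = A, attempted = 0L, accepted = 0L))
  accepted <- 0L
  for (s in seq_len(n_swaps)) {
    pick <- sample.int(m, 2L)
    a <- el[pick[1L], 1L]; b <- el[pick[1L], 2L]
    cc <- el[pick[2L], 1L]; d <- el[pick[2L], 2L]
    # propose a->d, c->b; reject self-loops and duplicate edges
    if (a == d || cc == b) next
    if (A[a, d] == 1L || A[cc, b] == 1L) next
    A[a, b] <- 0L; A[cc, d] <- 0L
    A[a, d] <- 1L; A[cc, b] <- 1L
    el[pick[1L], 2L] <- d
    el[pick[2L], 2L] <- b
    accepted <- accepted + 1L
  }
  list(adj = A, attempted = as.integer(n_swaps), accepted = accepted)
}

#' Degree-preserving edge rewiring
#'
#' Randomizes a network while preserving every node's in- and out-degree
#' exactly: `n_swaps` times, two distinct edges `a -> b`, `c -> d` are drawn
#' uniformly and the swap to `a -> d`, `c -> b` is applied iff it creates no
#' self-loop and no duplicate edge (rejected proposals still count as
#' attempts).  Attempt and acceptance counts are attached as attributes
#' `"attempted"` and `"accepted"`.
#'
#' @param net An [inhibition_network()] with at least 2 edges.
#' @param n_swaps Number of attempted swaps (default 1000).
#' @return A rewired [inhibition_network()].
#' @examples
#' set.seed(1)
#' net <- sample_er(10, 25)
#' rw <- rewire_degree_preserving(net)
#' identical(rowSums(as.matrix(rw)), rowSums(as.matrix(net)))
#' @export
rewire_degree_preserving <- function(net, n_swaps = 1000) {
  stopifnot(inherits(net, "inhibition_network"), n_swaps >= 0)
  res <- .rewire_adj(as.matrix(net), n_swaps)
  out <- inhibition_network(res$adj, community_id = net$community_id)
  attr(out, "attempted") <- res$attempted
  attr(out, "accepted") <- res$accepted
  out
}

.summarise_stat <- function(x) {
  ok <- !is.na(x)
  list(mean = mean(x[ok]), sd = stats::sd(x[ok]),
       n_effective = sum(ok), n_excluded = sum(!ok))
}

#' Summarise a null-model ensemble
#'
#' `ensemble_summary()` is the workhorse: it draws `n_reps` networks from a
#' sampler function and records the mean and sample standard deviation of
#' the mean shortest path `L`, the directed clustering coefficient `C`, and
#' the 16 triad-class frequencies.  Samples on which a statistic is
#' undefined (e.g. a graph with no directed 2-path) are excluded for that
#' statistic and the exclusion count reported.  The convenience wrappers
#' build the sampler for each of the three null models:
#' * `er_ensemble(n, m, ...)` - uniform digraphs with fixed edge count;
#' * `dyad_ensemble(dyads, n, ...)` - fixed dyad census;
#' * `degree_ensemble(net, ...)` - degree-preserving rewirings of `net`
#'   (each replicate restarts from the observed network).
#'
#' @param sampler A function of no arguments returning an adjacency matrix.
#' @param n_reps Number of ensemble replicates (>= 2; 10000 in a full
#'   analysis, fewer for exploration).
#' @param seed Optional integer seed for reproducibility.
#' @param model Model label stored in the result.
#' @return An object of class `null_ensemble`: a list with `model`,
#'   `n_reps`, `seed`, per-statistic summaries `L` and `C` (mean, sd,
#'   exclusion counts, plus the raw replicate values `values`), and `triads`
#'   (16-vector `mean` and `sd`).
#' @examples
#' es <- er_ensemble(18, 79, n_reps = 200, seed = 1)
#' es$C$mean
#' @export
ensemble_summary <- function(sampler, n_reps = 10000, seed = NULL,
                             model = "custom") {
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  Ls <- Cs <- numeric(n_reps)
  census <- matrix(0, n_reps, 16,
                   dimnames = list(NULL, .TRIAD_NAMES))
  for (r in seq_len(n_reps)) {
    A <- sampler()
    Ls[r] <- .mean_path_adj(A)
    Cs[r] <- .clustering_adj(A)
    census[r, ] <- .triad_census_adj(A)
  }
  structure(list(
    model = model, n_reps = n_reps, seed = seed,
    L = c(.summarise_stat(Ls), list(values = Ls)),
    C = c(.summarise_stat(Cs), list(values = Cs)),
    triads = list(mean = colMeans(census),
                  sd = apply(census, 2, stats::sd))
  ), class = "null_ensemble")
}

#' @rdname ensemble_summary
#' @inheritParams sample_er
#' @export
er_ensemble <- function(n, m, n_reps = 10000, seed = NULL) {
  ensemble_summary(function() .sample_er_adj(n, m), n_reps, seed, "er")
}

#' @rdname ensemble_summary
#' @inheritParams sample_dyad_conditioned
#' @export
dyad_ensemble <- function(dyads, n = NULL, n_reps = 10000, seed = NULL) {
  if (inherits(dyads, "inhibition_network")) {
    n <- n_nodes(dyads)
    dyads <- dyad_census(dyads)
  }
  M <- dyads[["mutual"]]; As <- dyads[["asym"]]; N <- dyads[["null"]]
  ensemble_summary(function() .sample_dyad_adj(M, As, N, n),
                   n_reps, seed, "dyad")
}

#' @rdname ensemble_summary
#' @param net An [inhibition_network()] to rewire.
#' @param n_swaps Attempted swaps per replicate (see
#'   [rewire_degree_preserving()]).
#' @export
degree_ensemble <- function(net, n_reps = 10000, n_swaps = 1000,
                            seed = NULL) {
  A0 <- as.matrix(net)
  ensemble_summary(function() .rewire_adj(A0, n_swaps)$adj,
                   n_reps, seed, "degree")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> model '%s', %d replicates%s\n", x$model,
              x$n_reps,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  cat(sprintf("  L: mean %.3f sd %.3f (%d excluded)\n",
              x$L$mean, x$L$sd, x$L$n_excluded))
  cat(sprintf("  C: mean %.3f sd %.3f (%d excluded)\n",
              x$C$mean, x$C$sd, x$C$n_excluded))
  invisible(x)
}

#' z-test of an observed statistic against a null ensemble
#'
#' Standard normal z-test: `z = (observed - null_mean) / null_sd`, two-sided
#' p-value from the standard normal distribution.  A degenerate ensemble
#' (`null_sd == 0`) gives `p = 1` when the observation equals the null mean
#' and `p = 0` otherwise (structurally forced statistics).
#'
#' @param observed Observed value.
#' @param null_mean,null_sd Ensemble mean and standard deviation.
#' @return A list with `observed`, `null_mean`, `null_sd`, `z` and `p`.
#' @examples
#' z_test(1.48, 1.78, 0.2)
#' @export
z_test <- function(observed, null_mean, null_sd) {
  stopifnot(null_sd >= 0)
  if (null_sd == 0) {
    z <- if (observed == null_mean) 0 else sign(observed - null_mean) * Inf
    p <- if (observed == null_mean) 1 else 0
  } else {
    z <- (observed - null_mean) / null_sd
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(observed = observed, null_mean = null_mean, null_sd = null_sd,
       z = z, p = p)
}
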