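# Whole-network statistics: density, degrees, mean directed shortest path,
# directed transitivity and small-world indices.

# all-pairs directed hop distances by repeated boolean matrix products;
# Inf marks unreachable ordered pairs (diagonal set to Inf so it is never
# counted).  Fast for the community-sized graphs used here.
.distances_adj <- function(A) {
  n <- nrow(A)
  reach <- A > 0
  D <- ifelse(reach, 1, Inf)
  frontier <- reach
  k <- 1
  while (any(frontier) && k < n) {
    k <- k + 1
    nxt <- (frontier %*% A) > 0
    new <- nxt & !reach
    diag(new) <- FALSE
    if (!any(new)) break
    D[new] <- k
    reach <- reach | new
    frontier <- new
  }
  diag(D) <- Inf
  D
}

# mean over reachable ordered pairs; NA when no pair is reachable
.mean_path_adj <- function(A) {
  d <- .distances_adj(A)
  f <- d[is.finite(d)]
  if (!length(f)) NA_real_ else mean(f)
}

# directed transitivity: closed directed 2-paths / directed 2-paths.
# A 2-path u->v->w (u != w) is closed when the shortcut u->w exists.
.clustering_adj <- function(A) {
  A2 <- A %*% A
  paths <- sum(A2) - sum(diag(A2))
  if (paths == 0) return(NA_real_)
  sum(A2 * A) / paths
}

#' Mean directed shortest path length
#'
#' Average number of hops over all ordered pairs `(u, v)`, `u != v`, for
#' which `v` is reachable from `u` along directed edges.  Unreachable pairs
#' are excluded from both numerator and denominator (so nodes without
#' out-edges simply contribute no source pairs); if no ordered pair is
#' reachable the value is `NA` with a warning.
#'
#' @param net An [inhibition_network()].
#' @return A single numeric value (>= 1 when any edge exists).
#' @examples
#' chain <- inhibition_network(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' mean_shortest_path(chain)  # (1 + 1 + 2) / 3
#' @export
mean_shortest_path <- function(net) {
  L <- .mean_path_adj(as.matrix(net))
  if (is.na(L)) warning("no reachable ordered pair: mean path is undefined")
  L
}

#' Directed clustering coefficient (transitivity)
#'
#' The fraction of directed 2-paths `u -> v -> w` (three distinct nodes)
#' closed by the shortcut edge `u -> w`.  On Erdos-Renyi directed graphs its
#' ensemble mean approaches the directed density.
#'
#' @param net An [inhibition_network()].
#' @return A value in `[0, 1]`, or `NA` (with a warning) when the graph has
#'   no directed 2-path.
#' @export
clustering_coefficient <- function(net) {
  C <- .clustering_adj(as.matrix(net))
  if (is.na(C)) warning("no directed 2-path: clustering is undefined")
  C
}

#' Degree summary of an inhibition network
#'
#' @param net An [inhibition_network()].
#' @return A list with per-isolate `in_degree` and `out_degree` vectors and
#'   their means and sample (n-1) standard deviations.  Mean in- and
#'   out-degree are identical by construction (`n_edges / n_nodes`).
#' @export
degree_summary <- function(net) {
  adj <- as.matrix(net)
  out_deg <- rowSums(adj)
  in_deg <- colSums(adj)
  list(in_degree = in_deg, out_degree = out_deg,
       mean_in_degree = mean(in_deg), sd_in_degree = stats::sd(in_deg),
       mean_out_degree = mean(out_deg), sd_out_degree = stats::sd(out_deg))
}

#' Standard metrics of an inhibition network
#'
#' Computes the node/edge counts, directed density, degree summaries, mean
#' directed shortest path length `L` and directed clustering coefficient `C`.
#'
#' @param net An [inhibition_network()].
#' @return An object of class `network_metrics` (a list; printable).
#' @examples
#' net <- sample_er(18, 79)
#' network_metrics(net)
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "inhibition_network"))
  adj <- as.matrix(net)
  n <- nrow(adj)
  m <- sum(adj)
  deg <- degree_summary(net)
  out <- c(list(community_id = net$community_id, n_nodes = n, n_edges = m,
                density = m / (n * (n - 1))),
           deg,
           list(L = .mean_path_adj(adj), C = .clustering_adj(adj)))
  structure(out, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Network metrics (community %s)\n", x$community_id))
  cat(sprintf("  nodes: %d   edges: %d   density: %.3f\n",
              x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  mean degree: %.2f   sd in: %.2f   sd out: %.2f\n",
              x$mean_in_degree, x$sd_in_degree, x$sd_out_degree))
  cat(sprintf("  mean shortest path L: %.3f   clustering C: %.3f\n",
              x$L, x$C))
  invisible(x)
}

#' Small-world indices
#'
#' `gamma` is the ratio of the observed clustering coefficient to its mean
#' over an Erdos-Renyi ensemble with the same node and edge counts; `lambda`
#' is the analogous ratio for the mean shortest path; small-worldness is
#' `S = gamma / lambda` (values well above 1 indicate small-world structure:
#' much more clustering than a random graph at comparable path lengths).
#'
#' Supply either the raw quantities (`C`, `L`, `C_null`, `L_null`) or the
#' precomputed ratios `gamma`/`lambda` directly (useful when a lambda from
#' another source is to be combined with a computed gamma).
#'
#' @param C,L Observed clustering coefficient and mean shortest path.
#' @param C_null,L_null Null-ensemble means (e.g. from [er_ensemble()]).
#' @param gamma,lambda Optional precomputed ratios overriding the above.
#' @return A list with `gamma`, `lambda` and `smallworldness`.
#' @examples
#' small_world_indices(gamma = 3.12, lambda = 0.95)
#' @export
small_world_indices <- function(C = NULL, L = NULL, C_null = NULL,
                                L_null = NULL, gamma = NULL, lambda = NULL) {
  if (is.null(gamma)) {
    if (is.null(C) || is.null(C_null)) stop("supply C and C_null, or gamma")
    if (C_null == 0) stop("null mean clustering is zero: gamma undefined")
    gamma <- C / C_null
  }
  if (is.null(lambda)) {
    if (is.null(L) || is.null(L_null)) stop("supply L and L_null, or lambda")
    if (L_null == 0) stop("null mean path length is zero: lambda undefined")
    lambda <- L / L_null
  }
  list(gamma = gamma, lambda = lambda, smallworldness = gamma / lambda)
}
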