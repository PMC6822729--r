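# Node participation (orbit) analysis: the 30 automorphism positions within
# connected triads, per-node signature vectors, correlation-based
# hierarchical clustering, Shannon diversity and the among-community ANOVA.

#' The 30 node positions (orbits) of connected directed triads
#'
#' Each of the 13 connected triad classes (indices 4-16) contributes one to
#' three automorphism-equivalence classes of node positions.  A position is
#' identified by the triad class together with the node's within-triad out-
#' and in-degree; for directed triads this key separates all 30 orbits
#' (verified at build time against the class representatives).  Orbit ids
#' follow the `t{triad}.{out}.{in}` convention, e.g. `t4.2.0` is the centre
#' of the out-star triad.
#'
#' @return A data frame with 30 rows: `orbit_id`, `triad` (class index),
#'   `name` (class label), `out_degree`, `in_degree`, and `multiplicity`
#'   (number of nodes holding the position in one triad instance).
#' @examples
#' nrow(orbit_table())  # 30
#' @export
orbit_table <- function() {
  tb <- .antagonet_cache$orbit_table
  if (!is.null(tb)) return(tb)
  reps <- .triad_representatives()
  rows <- list()
  for (cls in 4:16) {
    a <- .arcs_to_adj3(reps[[cls]])
    key <- paste(rowSums(a), colSums(a))
    for (k in unique(key)) {
      d <- as.integer(strsplit(k, " ")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        triad = cls, name = .TRIAD_NAMES[cls],
        out_degree = d[1], in_degree = d[2],
        multiplicity = sum(key == k), stringsAsFactors = FALSE)
    }
  }
  tb <- do.call(rbind, rows)
  tb <- tb[order(tb$triad, -tb$out_degree, -tb$in_degree), ]
  tb <- data.frame(orbit_id = sprintf("t%d.%d.%d", tb$triad, tb$out_degree,
                                      tb$in_degree),
                   tb, stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  stopifnot(nrow(tb) == 30, !anyDuplicated(tb$orbit_id),
            all(tapply(tb$multiplicity, tb$triad, sum) == 3))
  .antagonet_cache$orbit_table <- tb
  tb
}

.node_orbit_census_adj <- function(A) {
  n <- nrow(A)
  codes <- .triple_codes(A)
  ol <- .orbit_lookup()
  tri <- .triple_index(n)$triples
  counts <- matrix(0L, n, 30)
  for (p in 1:3) {
    orb <- ol[codes + 1L, p]
    keep <- orb > 0L
    if (!any(keep)) next
    idx <- (orb[keep] - 1L) * n + tri[p, keep]
    tl <- tabulate(idx, nbins = n * 30L)
    counts <- counts + matrix(tl, n, 30)
  }
  dimnames(counts) <- list(rownames(A), orbit_table()$orbit_id)
  counts
}

#' Orbit participation counts for every node
#'
#' For every node and every connected triple containing it, increments the
#' orbit matching the node's within-triad out- and in-degrees.  Triples
#' inducing a non-connected triad (classes 1-3) contribute nothing.  The
#' row of counts is the node's raw participation signature.
#'
#' @param net An [inhibition_network()] with at least 3 nodes.
#' @return An integer matrix, nodes x 30 orbits (columns ordered and named
#'   as in [orbit_table()]).
#' @examples
#' star <- inhibition_network(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
#' node_orbit_census(star)  # centre in t4.2.0, leaves in t4.0.1
#' @export
node_orbit_census <- function(net) {
  stopifnot(inherits(net, "inhibition_network"))
  A <- as.matrix(net)
  if (nrow(A) < 3) stop("orbit census requires at least 3 nodes")
  .node_orbit_census_adj(A)
}

#' Signature matrix of square-root-transformed orbit proportions
#'
#' Converts raw orbit counts into each node's signature vector: counts are
#' normalised to proportions (per node) and square-root transformed, so the
#' squares of a participating node's row sum to 1.  Nodes that take part in
#' no connected triad yield all-zero rows, flagged in the
#' `"zero_participation"` attribute.
#'
#' @param counts A node x 30 count matrix from [node_orbit_census()].
#' @param transform `"sqrt"` (default) or `"raw"` (plain proportions).
#' @return A numeric matrix of the same shape.
#' @export
signature_matrix <- function(counts, transform = c("sqrt", "raw")) {
  transform <- match.arg(transform)
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  props <- counts / ifelse(tot == 0, 1, tot)
  out <- if (transform == "sqrt") sqrt(props) else props
  attr(out, "zero_participation") <- rownames(counts)[tot == 0]
  out
}

#' Hierarchical clustering of node signatures
#'
#' Clusters nodes by the similarity of their orbit signature vectors:
#' distance is one minus the Pearson correlation between (by default
#' square-root-transformed) signature rows, with average-linkage
#' agglomeration.  Nodes with zero participation, or with constant
#' signature rows (undefined correlation), are excluded with a warning.
#'
#' @param counts A node x 30 count matrix from [node_orbit_census()], or a
#'   matrix combining several communities' counts (rbind them; keep row
#'   names unique).
#' @param k Optional number of flat clusters to cut the tree into.
#' @param transform Passed to [signature_matrix()].
#' @param method Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list with the `hclust` object (`tree`), the distance matrix
#'   (`dist`), the rows used (`used`), excluded node labels (`excluded`)
#'   and, when `k` is given, a named `clusters` vector.
#' @export
cluster_signatures <- function(counts, k = NULL,
                               transform = c("sqrt", "raw"),
                               method = "average") {
  sig <- signature_matrix(counts, transform = match.arg(transform))
  keep <- apply(sig, 1, function(r) stats::sd(r) > 0)
  if (any(!keep))
    warning("excluding node(s) with zero or constant signatures: ",
            paste(rownames(sig)[!keep], collapse = ", "))
  sig <- sig[keep, , drop = FALSE]
  sig <- sig[order(rownames(sig)), , drop = FALSE]  # order-invariant input
  if (nrow(sig) < 2) stop("need at least 2 nodes with non-constant signatures")
  d <- stats::as.dist(1 - stats::cor(t(sig)))
  tree <- stats::hclust(d, method = method)
  out <- list(tree = tree, dist = d, used = rownames(sig),
              excluded = rownames(counts)[!keep])
  if (!is.null(k)) out$clusters <- stats::cutree(tree, k = k)
  out
}

#' Export a signature dendrogram in Newick format
#'
#' @param clustering A result of [cluster_signatures()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  stopifnot(!is.null(clustering$tree))
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Shannon diversity of node participation
#'
#' Shannon entropy `H' = -sum(p_i log p_i)` of a node's orbit proportions
#' (zero-count orbits contribute nothing).  Nodes participating in no
#' connected triad are reported as `H' = 0` (named in the
#' `"zero_participation"` attribute).  Bounded above by `log(30)`.
#'
#' @param counts A node x 30 count matrix (or a single node's 30-vector).
#' @param base Logarithm base (default natural log).
#' @return A named numeric vector of per-node diversity values.
#' @examples
#' node_shannon(rbind(a = c(4, 4, 4, 4, rep(0, 26))))  # log(4)
#' @export
node_shannon <- function(counts, base = exp(1)) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  h <- apply(counts, 1, function(x) {
    tot <- sum(x)
    if (tot == 0) return(0)
    p <- x[x > 0] / tot
    -sum(p * log(p, base = base))
  })
  attr(h, "zero_participation") <- rownames(counts)[rowSums(counts) == 0]
  h
}

#' One-way ANOVA of diversity among communities
#'
#' Classic fixed-effects one-way analysis of variance of per-isolate
#' Shannon diversities grouped by community, treating isolates as
#' independent replicates within each community.
#'
#' @param h Numeric vector of per-node H' values.
#' @param community Factor (or coercible) of community memberships, same
#'   length as `h`; at least 2 groups with 2 or more values each.
#' @return A list with `F`, `p`, degrees of freedom `df`, and per-community
#'   `means` and `sds`.
#' @export
community_anova <- function(h, community) {
  community <- factor(community)
  stopifnot(length(h) == length(community), nlevels(community) >= 2)
  if (any(table(community) < 2))
    stop("every community needs at least 2 values")
  fit <- stats::oneway.test(h ~ community, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter),
       means = tapply(h, community, mean),
       sds = tapply(h, community, stats::sd))
}
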