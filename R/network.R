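#' Directed inhibition network
#'
#' Constructs the central data structure of the package: a simple directed
#' graph over the isolates of one community, stored as a labeled binary
#' adjacency matrix.  An arc `u -> v` means isolate `u` inhibits isolate `v`
#' (inhibition zone beyond the assay threshold).  The diagonal is ignored:
#' self-inhibition is never represented, and isolated nodes are retained so
#' that degree distributions refer to the full community.
#'
#' @param x A square binary (0/1) matrix, optionally with row/column names
#'   giving isolate labels (row names win on conflict), or a data frame
#'   coercible to one.  Any non-zero diagonal is dropped with a warning.
#' @param community_id Optional community label attached to the network.
#' @return An object of class `inhibition_network`: a list with elements
#'   `adj` (integer adjacency with isolate dimnames) and `community_id`.
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' m["a", "b"] <- 1; m["c", "a"] <- 1
#' net <- inhibition_network(m, community_id = "demo")
#' net
#' @seealso [network_metrics()], [triad_census()], [antagonism()]
#' @export
inhibition_network <- function(x, community_id = NA_character_) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("'x' must be a square matrix")
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  labels <- rownames(x)
  if (is.null(labels)) labels <- colnames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  if (anyDuplicated(labels)) stop("duplicated isolate labels")
  adj <- matrix(as.integer(x), nrow(x), ncol(x),
                dimnames = list(labels, labels))
  if (any(diag(adj) != 0)) {
    warning("non-zero diagonal entries dropped (self-inhibition is ignored)")
    diag(adj) <- 0L
  }
  structure(list(adj = adj, community_id = as.character(community_id)),
            class = "inhibition_network")
}

#' @export
as.matrix.inhibition_network <- function(x, ...) x$adj

#' Number of nodes and edges of an inhibition network
#'
#' @param net An [inhibition_network()].
#' @return An integer count.
#' @export
n_nodes <- function(net) nrow(as.matrix(net))

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(as.matrix(net))

#' Isolate labels of an inhibition network
#' @param net An [inhibition_network()].
#' @return Character vector of labels.
#' @export
isolates <- function(net) rownames(as.matrix(net))

#' @export
print.inhibition_network <- function(x, ...) {
  cat(sprintf("<inhibition_network> community %s: %d isolates, %d directed edges (density %.3f)\n",
              x$community_id, n_nodes(x), n_edges(x),
              n_edges(x) / (n_nodes(x) * (n_nodes(x) - 1))))
  invisible(x)
}

#' Convert an inhibition network to an igraph object
#'
#' @param net An [inhibition_network()].
#' @return A directed `igraph` graph with isolate names as vertex names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "inhibition_network"))
  igraph::graph_from_adjacency_matrix(as.matrix(net), mode = "directed")
}

#' @export
plot.inhibition_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, edge.arrow.size = 0.4,
                      main = paste("Community", x$community_id), ...)
  invisible(x)
}

#' Edge list of an inhibition network
#'
#' @param net An [inhibition_network()].
#' @return A two-column character matrix (`source`, `target`), one directed
#'   edge per row.
#' @export
edge_list <- function(net) {
  adj <- as.matrix(net)
  idx <- which(adj == 1L, arr.ind = TRUE)
  cbind(source = rownames(adj)[idx[, 1]], target = colnames(adj)[idx[, 2]])
}
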