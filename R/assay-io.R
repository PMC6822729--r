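# Reading/writing of raw inhibition-zone tables and binary interaction
# matrices, and the binarization rule that turns assay measurements into
# directed networks.

.delim_for <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a raw inhibition-zone table
#'
#' Reads a table of replicated agar-overlay measurements.  Each row records
#' one replicate for one ordered isolate pair: the source (killed, antibiotic
#' producing) isolate, the target (overlaid test) isolate, the replicate
#' number, and the two perpendicular inhibition-zone measurements in mm.
#'
#' @param path Path to a CSV/TSV file with columns `source`, `target`,
#'   `replicate`, `zone_a_mm`, `zone_b_mm` (extra columns are ignored).
#' @param sep Field delimiter; default is inferred from the file extension
#'   (tab for `.tsv`/`.txt`, comma otherwise).
#' @return A data frame of class `zone_table` with the five canonical
#'   columns.  Ordered pairs present with fewer replicates than the modal
#'   replicate count are reported with a warning.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(source = "a", target = "b", replicate = 1:3,
#'                      zone_a_mm = 5, zone_b_mm = 6), tf, row.names = FALSE)
#' read_zone_table(tf)
#' @export
read_zone_table <- function(path, sep = NULL) {
  sep <- .delim_for(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source", "target", "replicate", "zone_a_mm", "zone_b_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("zone table is missing column(s): ", paste(miss, collapse = ", "))
  z <- raw[need]
  z$source <- as.character(z$source)
  z$target <- as.character(z$target)
  for (col in c("replicate", "zone_a_mm", "zone_b_mm")) {
    v <- suppressWarnings(as.numeric(z[[col]]))
    bad <- which(is.na(v) & !is.na(z[[col]]))
    if (anyNA(v)) {
      at <- which(is.na(v))[1]
      stop(sprintf("malformed value in column '%s' at data row %d", col, at))
    }
    z[[col]] <- v
  }
  if (any(!is.finite(z$zone_a_mm)) || !all(z$zone_a_mm >= 0) ||
      any(!is.finite(z$zone_b_mm)) || !all(z$zone_b_mm >= 0)) {
    at <- which(z$zone_a_mm < 0 | z$zone_b_mm < 0 |
                  !is.finite(z$zone_a_mm) | !is.finite(z$zone_b_mm))[1]
    stop(sprintf("negative or non-finite zone measurement at data row %d", at))
  }
  n_rep <- table(paste(z$source, z$target, sep = "\r"))
  modal <- as.integer(names(sort(table(n_rep), decreasing = TRUE))[1])
  low <- names(n_rep)[n_rep < modal]
  if (length(low)) {
    warning("pair(s) with fewer than ", modal, " replicates: ",
            paste(gsub("\r", " -> ", low), collapse = ", "))
  }
  class(z) <- c("zone_table", "data.frame")
  z
}

#' Binarize zone measurements into inhibition networks
#'
#' Applies the edge rule used throughout the package: for each ordered
#' isolate pair the two perpendicular zone measurements are averaged within
#' each replicate, replicate means are averaged, and a directed edge is
#' placed iff that grand mean is strictly greater than `threshold` mm.
#' Exact ties at the threshold give no edge.  Only within-community
#' (sympatric) pairs are considered, and self-pairs are always excluded.
#'
#' @param zones A zone table as returned by [read_zone_table()] (or any data
#'   frame with the same columns).
#' @param communities Either a named character vector mapping isolate label
#'   to community id, or `NULL`, in which case all isolates form a single
#'   community `"all"`.
#' @param threshold Edge threshold in mm (default 2, the assay convention).
#' @return A named list of [inhibition_network()] objects, one per community.
#' @examples
#' z <- data.frame(source = c("a", "b"), target = c("b", "a"),
#'                 replicate = 1, zone_a_mm = c(5, 0), zone_b_mm = c(5, 1))
#' binarize(z)
#' @export
binarize <- function(zones, communities = NULL, threshold = 2) {
  stopifnot(threshold >= 0)
  labels <- sort(unique(c(zones$source, zones$target)))
  if (is.null(communities)) {
    communities <- stats::setNames(rep("all", length(labels)), labels)
  }
  unassigned <- setdiff(labels, names(communities))
  if (length(unassigned))
    stop("isolate(s) without community assignment: ",
         paste(unassigned, collapse = ", "))
  # perpendicular measurements first, then replicates (equal to grand mean)
  rep_mean <- (zones$zone_a_mm + zones$zone_b_mm) / 2
  key <- paste(zones$source, zones$target, sep = "\r")
  pair_mean <- tapply(rep_mean, key, mean)
  comm <- communities[labels]
  out <- list()
  for (cid in unique(comm)) {
    members <- labels[comm == cid]
    n <- length(members)
    adj <- matrix(0L, n, n, dimnames = list(members, members))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      m <- pair_mean[paste(members[i], members[j], sep = "\r")]
      if (!is.na(m) && m > threshold) adj[i, j] <- 1L
    }
    out[[cid]] <- inhibition_network(adj, community_id = cid)
  }
  out
}

#' Read and write binary interaction matrices
#'
#' `read_inhibition_matrix()` reads a square, header-labeled 0/1 table
#' (rows inhibit columns); `write_inhibition_matrix()` writes one, so the
#' two functions round-trip.  `write_edge_list()` exports the directed edge
#' list as two-column TSV.
#'
#' @param path File path (CSV or TSV; delimiter inferred from the extension
#'   unless `sep` is given).
#' @param sep Field delimiter override.
#' @param community_id Community label to attach on read.
#' @return `read_inhibition_matrix()` returns an [inhibition_network()];
#'   the writers return `path` invisibly.
#' @examples
#' net <- sample_er(5, 8)
#' tf <- tempfile(fileext = ".csv")
#' write_inhibition_matrix(net, tf)
#' identical(as.matrix(read_inhibition_matrix(tf)), as.matrix(net))
#' @export
read_inhibition_matrix <- function(path, sep = NULL,
                                   community_id = NA_character_) {
  sep <- .delim_for(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop("interaction matrix must be square (got ",
         nrow(m), " x ", ncol(m), ")")
  if (!all(m %in% c(0, 1))) stop("interaction matrix cells must be 0 or 1")
  suppressWarnings(inhibition_network(m, community_id = community_id))
}

#' @rdname read_inhibition_matrix
#' @param net An [inhibition_network()].
#' @export
write_inhibition_matrix <- function(net, path, sep = NULL) {
  stopifnot(inherits(net, "inhibition_network"))
  sep <- .delim_for(path, sep)
  adj <- as.matrix(net)
  utils::write.table(adj, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname read_inhibition_matrix
#' @export
write_edge_list <- function(net, path) {
  el <- edge_list(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
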