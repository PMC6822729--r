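# Internal machinery for classifying directed triads and node orbits.
#
# A triad state over three labeled nodes is encoded as a 6-bit integer using
# the fixed arc order (1,2),(2,1),(1,3),(3,1),(2,3),(3,2).  All 64 states fall
# into 16 isomorphism classes, indexed 1..16 in the standard census order
# 003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D, 120U,
# 120C, 210, 300.  Class membership is resolved at load time by matching each
# state's permutation-invariant signature (mutual/asymmetric dyad counts plus
# sorted out- and in-degree multisets) against reference representatives --
# this signature separates all 16 classes for 3-node digraphs.

.antagonet_cache <- new.env(parent = emptyenv())

.TRIAD_NAMES <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                  "111U", "030T", "030C", "201", "120D", "120U", "120C",
                  "210", "300")

# arc lists of one representative per class (rows are from,to)
.triad_representatives <- function() {
  e <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    "003"  = matrix(integer(0), ncol = 2),
    "012"  = e(1, 2),
    "102"  = e(1, 2, 2, 1),
    "021D" = e(2, 1, 2, 3),
    "021U" = e(1, 2, 3, 2),
    "021C" = e(1, 2, 2, 3),
    "111D" = e(1, 2, 2, 1, 3, 2),
    "111U" = e(1, 2, 2, 1, 2, 3),
    "030T" = e(1, 2, 3, 2, 1, 3),
    "030C" = e(1, 2, 2, 3, 3, 1),
    "201"  = e(1, 2, 2, 1, 2, 3, 3, 2),
    "120D" = e(2, 1, 2, 3, 1, 3, 3, 1),
    "120U" = e(1, 2, 3, 2, 1, 3, 3, 1),
    "120C" = e(1, 2, 2, 3, 1, 3, 3, 1),
    "210"  = e(1, 2, 2, 3, 3, 2, 1, 3, 3, 1),
    "300"  = e(1, 2, 2, 1, 1, 3, 3, 1, 2, 3, 3, 2)
  )
}

.arcs_to_adj3 <- function(arcs) {
  a <- matrix(0L, 3, 3)
  if (nrow(arcs)) a[arcs] <- 1L
  a
}

# decode a 0..63 code to a 3x3 adjacency
.code_to_adj3 <- function(code) {
  bits <- as.integer(intToBits(code)[1:6])
  a <- matrix(0L, 3, 3)
  a[1, 2] <- bits[1]; a[2, 1] <- bits[2]
  a[1, 3] <- bits[3]; a[3, 1] <- bits[4]
  a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
  a
}

.adj3_signature <- function(a) {
  m <- a * t(a)                       # mutual arcs
  n_mut <- sum(m) / 2
  n_asym <- sum(a) - 2 * n_mut
  paste(n_mut, n_asym,
        paste(sort(rowSums(a)), collapse = ""),
        paste(sort(colSums(a)), collapse = ""), sep = "|")
}

# 64-vector: class index (1..16) of each triad code + 1
.triad_lookup <- function() {
  lk <- .antagonet_cache$triad_lookup
  if (!is.null(lk)) return(lk)
  ref <- vapply(.triad_representatives(),
                function(arcs) .adj3_signature(.arcs_to_adj3(arcs)),
                character(1))
  stopifnot(!anyDuplicated(ref))
  lk <- integer(64)
  for (code in 0:63) {
    sig <- .adj3_signature(.code_to_adj3(code))
    cls <- match(sig, ref)
    if (is.na(cls)) stop("internal error: unmatched triad signature")
    lk[code + 1L] <- cls
  }
  .antagonet_cache$triad_lookup <- lk
  lk
}

# 64 x 3 matrix: orbit index (row of orbit_table()) of node position p under
# triad code, or 0 for positions in non-connected classes (1..3).
.orbit_lookup <- function() {
  ol <- .antagonet_cache$orbit_lookup
  if (!is.null(ol)) return(ol)
  tab <- orbit_table()
  key <- paste(tab$triad, tab$out_degree, tab$in_degree)
  lk <- .triad_lookup()
  ol <- matrix(0L, 64, 3)
  for (code in 0:63) {
    cls <- lk[code + 1L]
    if (cls < 4L) next
    a <- .code_to_adj3(code)
    for (p in 1:3) {
      idx <- match(paste(cls, sum(a[p, ]), sum(a[, p])), key)
      if (is.na(idx)) stop("internal error: orbit not found")
      ol[code + 1L, p] <- idx
    }
  }
  .antagonet_cache$orbit_lookup <- ol
  ol
}

# per-n cache of triple indices used by the vectorised census: the linear
# indices into an n x n adjacency of the 6 arcs of every node triple
.triple_index <- function(n) {
  key <- as.character(n)
  ti <- .antagonet_cache$triples[[key]]
  if (!is.null(ti)) return(ti)
  tr <- utils::combn(n, 3)
  i <- tr[1, ]; j <- tr[2, ]; k <- tr[3, ]
  ti <- list(
    triples = tr,
    idx = cbind((j - 1L) * n + i,   # i -> j
                (i - 1L) * n + j,   # j -> i
                (k - 1L) * n + i,   # i -> k
                (i - 1L) * n + k,   # k -> i
                (k - 1L) * n + j,   # j -> k
                (j - 1L) * n + k)   # k -> j
  )
  if (is.null(.antagonet_cache$triples)) .antagonet_cache$triples <- list()
  .antagonet_cache$triples[[key]] <- ti
  ti
}

# codes (0..63) of every node triple of adjacency A
.triple_codes <- function(A) {
  n <- nrow(A)
  ti <- .triple_index(n)
  b <- ti$idx
  A[b[, 1]] + 2L * A[b[, 2]] + 4L * A[b[, 3]] +
    8L * A[b[, 4]] + 16L * A[b[, 5]] + 32L * A[b[, 6]]
}

.triad_census_adj <- function(A) {
  cls <- .triad_lookup()[.triple_codes(A) + 1L]
  tabulate(cls, nbins = 16L)
}

#' The sixteen directed triad isomorphism classes
#'
#' Enumerates the isomorphism classes of a directed graph on three nodes in
#' the standard census order (003, 012, 102, 021D, 021U, 021C, 111D, 111U,
#' 030T, 030C, 201, 120D, 120U, 120C, 210, 300).  Class 4 (021D) is the
#' out-star, class 10 (030C) the cyclic "rock-paper-scissors" triad, class 16
#' (300) the complete mutual triad.  Classes 1-3 are the only classes whose
#' induced subgraph is not weakly connected.
#'
#' @return A data frame with one row per class: `index` (1..16), `name`
#'   (standard label), `edge_count` (number of arcs, 0..6), `mutual`, `asym`,
#'   `null` (dyad composition) and `is_connected`.
#' @examples
#' triad_classes()
#' @export
triad_classes <- function() {
  reps <- .triad_representatives()
  out <- data.frame(
    index = seq_along(reps),
    name = names(reps),
    edge_count = vapply(reps, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  dy <- t(vapply(reps, function(arcs) {
    a <- .arcs_to_adj3(arcs)
    m <- sum(a * t(a)) / 2
    c(mutual = m, asym = sum(a) - 2 * m)
  }, numeric(2)))
  out$mutual <- as.integer(dy[, 1])
  out$asym <- as.integer(dy[, 2])
  out$null <- 3L - out$mutual - out$asym
  out$is_connected <- out$index >= 4L
  rownames(out) <- NULL
  out
}

#' Classify a three-node directed graph into its triad class
#'
#' @param x Either a 3x3 binary adjacency matrix with zero diagonal, or a
#'   two-column matrix/data frame of arcs with entries in `{1,2,3}`.
#' @return The class index, an integer in 1..16, with the standard class name
#'   as the `names` attribute.  The result is invariant under relabelling of
#'   the three nodes.
#' @examples
#' classify_triad(rbind(c(1, 2), c(2, 3), c(3, 1)))  # 3-cycle -> 10 (030C)
#' classify_triad(matrix(0, 3, 3))                   # empty   -> 1 (003)
#' @export
classify_triad <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x) && ncol(x) == 2) {
    storage.mode(x) <- "integer"
    if (nrow(x) && (any(x < 1L) || any(x > 3L)))
      stop("arc endpoints must be in 1..3")
    x <- .arcs_to_adj3(x)
  }
  if (!is.matrix(x) || !all(dim(x) == c(3, 3)))
    stop("'x' must be a 3x3 adjacency matrix or a 2-column arc list")
  if (any(diag(x) != 0)) stop("self-loops are not allowed in a triad")
  if (!all(x %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  a <- matrix(as.integer(x), 3, 3)
  code <- a[1, 2] + 2L * a[2, 1] + 4L * a[1, 3] + 8L * a[3, 1] +
    16L * a[2, 3] + 32L * a[3, 2]
  cls <- .triad_lookup()[code + 1L]
  names(cls) <- .TRIAD_NAMES[cls]
  cls
}
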