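# Reference values for three sympatric prairie-soil Streptomyces
# communities (A, B, C), used in examples and validation: their triad
# censuses, summary network metrics, and degree-conditioned ensemble mean
# triad frequencies.

#' Reference statistics for three prairie-soil Streptomyces communities
#'
#' Summary data for the inhibition networks of three sympatric
#' *Streptomyces* communities (labelled A, B and C) isolated from
#' different prairie soil cores and assayed pairwise by agar overlay.
#' `streptomyces_censuses()` returns their empirical triad censuses;
#' `streptomyces_conditioned_means()` the mean triad frequencies of the
#' matching degree-conditioned null ensembles; `streptomyces_metrics()` the
#' reported whole-network metrics.  These values allow much of the analysis
#' to be exercised and cross-checked without the underlying interaction
#' matrices: dyad censuses (and hence the dyad-conditioned null model) are
#' exactly recoverable from the triad censuses via
#' [dyad_census_from_triads()], and the Erdos-Renyi ensembles need only the
#' node and edge counts.
#'
#' @return `streptomyces_censuses()` and
#'   `streptomyces_conditioned_means()`: a 3 x 16 matrix (rows `A`, `B`,
#'   `C`; columns the triad classes in standard order).
#'   `streptomyces_metrics()`: a data frame with one row per community and
#'   columns `community`, `n_nodes`, `n_edges`, `density`, `L`, `C`,
#'   `L_er`, `C_er`, `lambda`, `gamma`, `smallworldness`.
#' @examples
#' rowSums(streptomyces_censuses())  # choose(18,3), choose(17,3), choose(17,3)
#' @export
streptomyces_censuses <- function() {
  m <- rbind(
    A = c(318, 22, 22, 289, 0, 0, 2, 58, 4, 0, 1, 7, 79, 0, 4, 10),
    B = c(113, 106, 18, 208, 34, 10, 3, 34, 55, 0, 9, 14, 57, 4, 13, 2),
    C = c(100, 196, 5, 103, 56, 41, 10, 43, 75, 2, 5, 4, 22, 12, 4, 2))
  colnames(m) <- .TRIAD_NAMES
  m
}

#' @rdname streptomyces_censuses
#' @export
streptomyces_conditioned_means <- function() {
  m <- rbind(
    A = c(302, 53.097, 2.9142, 288.03, 1.0325, 2.0192, 0.277, 54.343,
          13.476, 0.0695, 0.6293, 1.015, 76.948, 2.7317, 11.361, 6.051),
    B = c(108.22, 113.79, 8.5286, 202.24, 16.284, 18.654, 4.9684, 30.991,
          96.145, 0.4075, 2.8139, 11.678, 47.704, 5.4739, 11.083, 1.0295),
    C = c(103.47, 193.18, 13.538, 96.844, 57.907, 37.478, 9.0169, 44.989,
          68.395, 1.7265, 5.0763, 4.1212, 27.213, 8.7982, 7.3634, 0.8747))
  colnames(m) <- .TRIAD_NAMES
  m
}

#' @rdname streptomyces_censuses
#' @export
streptomyces_metrics <- function() {
  data.frame(
    community = c("A", "B", "C"),
    n_nodes = c(18L, 17L, 17L),
    n_edges = c(79L, 89L, 80L),
    density = c(0.258, 0.327, 0.294),
    L = c(1.48, 1.56, 2.23),
    C = c(0.79, 0.75, 0.54),
    L_er = c(2.00, 1.79, 1.89),
    C_er = c(0.25, 0.32, 0.29),
    lambda = c(0.95, 1.07, 1.48),
    gamma = c(3.12, 2.31, 1.88),
    smallworldness = c(3.29, 2.15, 1.27),
    stringsAsFactors = FALSE)
}
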