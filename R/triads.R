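# Triad census, motif significance tests, and chi-squared comparisons of
# censuses within and across communities.

#' Census of the sixteen directed triad classes
#'
#' Classifies all `choose(n, 3)` node triples of a network into the 16
#' directed triad isomorphism classes (standard order; see
#' [triad_classes()]).
#'
#' @param net An [inhibition_network()] with at least 3 nodes.
#' @return An object of class `triad_census`: a named integer 16-vector
#'   with attributes `n_nodes` and `n_edges`.  Counts sum to
#'   `choose(n, 3)`, and weighting each class by its edge count sums to
#'   `n_edges * (n - 2)`.
#' @examples
#' set.seed(1)
#' triad_census(sample_er(10, 25))
#' @export
triad_census <- function(net) {
  stopifnot(inherits(net, "inhibition_network"))
  A <- as.matrix(net)
  if (nrow(A) < 3) stop("triad census requires at least 3 nodes")
  counts <- .triad_census_adj(A)
  structure(stats::setNames(counts, .TRIAD_NAMES),
            n_nodes = nrow(A), n_edges = sum(A), class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat(sprintf("Triad census (%d nodes, %d edges, %d triples)\n",
              attr(x, "n_nodes"), attr(x, "n_edges"), sum(x)))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Motif tests of a triad census against a null ensemble
#'
#' Compares each observed triad frequency to the ensemble mean and standard
#' deviation with a two-sided z-test, then applies a Benjamini-Hochberg
#' false-discovery-rate correction across the 16 triads of this
#' network-by-model comparison.  A triad is flagged as a motif (over- or
#' under-represented) when its adjusted p-value falls below `alpha`.
#'
#' @param census A [triad_census()] (or plain 16-vector of counts).
#' @param ensemble A `null_ensemble` with per-triad means and sds (see
#'   [ensemble_summary()]).
#' @param alpha Motif significance level after FDR adjustment (default
#'   0.05).
#' @return A data frame with one row per triad: `triad`, `name`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p`, `p_fdr`, `motif`.
#' @export
motif_tests <- function(census, ensemble, alpha = 0.05) {
  obs <- as.numeric(census)
  stopifnot(length(obs) == 16, inherits(ensemble, "null_ensemble"))
  zs <- ps <- numeric(16)
  for (t in 1:16) {
    zt <- z_test(obs[t], ensemble$triads$mean[t], ensemble$triads$sd[t])
    zs[t] <- zt$z; ps[t] <- zt$p
  }
  p_fdr <- stats::p.adjust(ps, method = "BH")
  data.frame(triad = 1:16, name = .TRIAD_NAMES, observed = obs,
             null_mean = unname(ensemble$triads$mean),
             null_sd = unname(ensemble$triads$sd),
             z = zs, p = ps, p_fdr = p_fdr,
             motif = p_fdr < alpha,
             model = ensemble$model,
             stringsAsFactors = FALSE)
}

#' Chi-squared goodness of fit of a census to expected frequencies
#'
#' Pearson statistic `sum((O - E)^2 / E)` over the 16 triad categories,
#' with the null-ensemble mean frequencies as the expectation.  No pooling
#' of small expected counts is performed.  Categories where both observed
#' and expected are zero are dropped; a zero expectation with a non-zero
#' observation is an error.
#'
#' @param observed,expected Numeric vectors of equal length (usually 16).
#' @return The chi-squared statistic (single numeric).
#' @examples
#' gof_chisq(c(10, 0), c(5, 5))  # 10
#' @export
gof_chisq <- function(observed, expected) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  stopifnot(length(observed) == length(expected))
  bad <- which(expected == 0 & observed > 0)
  if (length(bad))
    stop("expected frequency is zero for non-empty category ",
         paste(bad, collapse = ", "))
  keep <- expected > 0
  sum((observed[keep] - expected[keep])^2 / expected[keep])
}

#' Monte-Carlo p-value for the goodness-of-fit statistic
#'
#' Simulates `n_sim` censuses from the multinomial distribution with
#' `sum(observed)` draws and cell probabilities proportional to `expected`,
#' and returns the add-one tail estimate
#' `(1 + #\{simulated statistic >= observed statistic\}) / (n_sim + 1)`
#' (never exactly zero), appropriate when small expected counts invalidate
#' the asymptotic chi-squared distribution.
#'
#' @inheritParams gof_chisq
#' @param n_sim Number of simulations (default 2000).
#' @return A list with `statistic`, `p`, and `n_sim`.
#' @export
monte_carlo_gof_p <- function(observed, expected, n_sim = 2000) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  stopifnot(sum(observed) > 0)
  stat <- gof_chisq(observed, expected)
  size <- sum(observed)
  prob <- expected / sum(expected)
  sims <- stats::rmultinom(n_sim, size, prob)
  E <- prob * size
  keep <- E > 0
  sim_stat <- colSums((sims[keep, , drop = FALSE] - E[keep])^2 / E[keep])
  list(statistic = stat,
       p = (1 + sum(sim_stat >= stat)) / (n_sim + 1),
       n_sim = n_sim)
}

.as_census_matrix <- function(censuses) {
  if (is.list(censuses) && !is.data.frame(censuses))
    censuses <- do.call(rbind, lapply(censuses, as.numeric))
  censuses <- as.matrix(censuses)
  if (ncol(censuses) != 16) stop("censuses must have 16 triad columns")
  colnames(censuses) <- .TRIAD_NAMES
  censuses
}

#' Compare triad censuses across communities
#'
#' `cross_network_chisq()` computes Pearson's chi-squared statistic on the
#' communities-by-16 contingency table of triad counts, with a Monte-Carlo
#' p-value obtained by resampling tables under independence with both
#' margins fixed ([stats::r2dtable()]).  All-zero triad columns are dropped
#' with a warning.  `per_triad_cross_network_tests()` tests each triad
#' separately: its per-community counts against the rest of each
#' community's census (a 2-by-k table), again with Monte-Carlo p-values.
#'
#' @param censuses A matrix (communities x 16) of triad counts, or a list
#'   of [triad_census()] objects.
#' @param n_sim Number of Monte-Carlo resamples (default 2000).
#' @return `cross_network_chisq()`: a list with `statistic`, `df`, `p`,
#'   `n_sim` and the `table` used.  `per_triad_cross_network_tests()`: a
#'   data frame with per-triad `statistic`, `p` and a `tested` flag (triads
#'   absent from every community are skipped).
#' @export
cross_network_chisq <- function(censuses, n_sim = 2000) {
  tab <- .as_census_matrix(censuses)
  if (nrow(tab) < 2) stop("need censuses from at least 2 communities")
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("dropping all-zero triad column(s): ",
            paste(colnames(tab)[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  stat <- .pearson_stat(tab)
  sims <- stats::r2dtable(n_sim, rowSums(tab), colSums(tab))
  sim_stat <- vapply(sims, .pearson_stat, numeric(1))
  list(statistic = stat,
       df = (nrow(tab) - 1) * (ncol(tab) - 1),
       p = (1 + sum(sim_stat >= stat)) / (n_sim + 1),
       n_sim = n_sim, table = tab)
}

.pearson_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' @rdname cross_network_chisq
#' @export
per_triad_cross_network_tests <- function(censuses, n_sim = 2000) {
  tab <- .as_census_matrix(censuses)
  totals <- rowSums(tab)
  out <- data.frame(triad = 1:16, name = .TRIAD_NAMES,
                    statistic = NA_real_, p = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (t in 1:16) {
    cnt <- tab[, t]
    if (sum(cnt) == 0) next
    two <- rbind(cnt, totals - cnt)
    out$statistic[t] <- .pearson_stat(two)
    sims <- stats::r2dtable(n_sim, rowSums(two), colSums(two))
    sim_stat <- vapply(sims, .pearson_stat, numeric(1))
    out$p[t] <- (1 + sum(sim_stat >= out$statistic[t])) / (n_sim + 1)
    out$tested[t] <- TRUE
  }
  if (any(!out$tested))
    message("triad(s) absent from every community skipped: ",
            paste(out$name[!out$tested], collapse = ", "))
  out
}
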