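#' Fit null models to an observed inhibition network
#'
#' The central analysis of the package.  Given an observed directed
#' inhibition network, `antagonism()` computes its metrics (density,
#' degrees, mean shortest path `L`, directed clustering `C`), its triad and
#' dyad censuses, then fits the requested null-model ensembles
#' (Erdos-Renyi, dyad-conditioned, degree-preserving rewiring) and
#' compares observation to expectation: z-tests for `L` and `C`, per-triad
#' motif tests with FDR control, a chi-squared goodness-of-fit of the full
#' census with a Monte-Carlo p-value, and small-world indices against the
#' ER ensemble.
#'
#' @param net An [inhibition_network()].
#' @param models Character subset of `c("er", "dyad", "degree")`.
#' @param n_reps Ensemble replicates per model (10000 for a full analysis).
#' @param n_swaps Swap attempts per degree-conditioned replicate.
#' @param mc_sims Monte-Carlo simulations for goodness-of-fit p-values.
#' @param alpha Motif significance level after FDR adjustment.
#' @param seed Optional master seed; per-model streams are derived from it
#'   so results are reproducible and independent of model order.
#' @return An object of class `antagonism` with components `network`,
#'   `metrics`, `census`, `dyads`, `ensembles` (named list of
#'   `null_ensemble`), `tests` (per model: `L`, `C` z-tests, `motifs` data
#'   frame, `gof` list), `small_world`, and `call`.  Methods: `print`,
#'   `summary`, `coef` (observed metrics), `predict` (expected census under
#'   a null), `residuals` (observed minus expected census), `simulate`
#'   (null-network draws) and `plot`.
#' @examples
#' set.seed(1)
#' net <- simulate_community(community_profile(12, target_density = 0.3))
#' fit <- antagonism(net, n_reps = 200, seed = 1)
#' fit
#' head(residuals(fit))
#' @export
antagonism <- function(net, models = c("er", "dyad", "degree"),
                       n_reps = 1000, n_swaps = 1000, mc_sims = 2000,
                       alpha = 0.05, seed = NULL) {
  stopifnot(inherits(net, "inhibition_network"))
  models <- match.arg(models, several.ok = TRUE)
  metrics <- network_metrics(net)
  census <- triad_census(net)
  dyads <- dyad_census(net)
  model_seed <- function(i) if (is.null(seed)) NULL else seed + 1000L * i
  ensembles <- list()
  tests <- list()
  for (mod in models) {
    ens <- switch(mod,
      er = er_ensemble(metrics$n_nodes, metrics$n_edges, n_reps,
                       seed = model_seed(1L)),
      dyad = dyad_ensemble(dyads, metrics$n_nodes, n_reps,
                           seed = model_seed(2L)),
      degree = degree_ensemble(net, n_reps, n_swaps,
                               seed = model_seed(3L)))
    ensembles[[mod]] <- ens
    if (!is.null(seed)) set.seed(seed + 1000L * 4L + match(mod, models))
    tests[[mod]] <- list(
      L = z_test(metrics$L, ens$L$mean, ens$L$sd),
      C = z_test(metrics$C, ens$C$mean, ens$C$sd),
      motifs = motif_tests(census, ens, alpha = alpha),
      gof = monte_carlo_gof_p(census, ens$triads$mean, n_sim = mc_sims))
  }
  sw <- if ("er" %in% models)
    small_world_indices(C = metrics$C, L = metrics$L,
                        C_null = ensembles$er$C$mean,
                        L_null = ensembles$er$L$mean)
  structure(list(network = net, metrics = metrics, census = census,
                 dyads = dyads, ensembles = ensembles, tests = tests,
                 small_world = sw, alpha = alpha, n_reps = n_reps,
                 n_swaps = n_swaps, seed = seed, call = match.call()),
            class = "antagonism")
}

#' @export
print.antagonism <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Antagonism network analysis (community %s)\n",
              m$community_id))
  cat(sprintf("  %d isolates, %d inhibitory edges (density %.3f); L = %.2f, C = %.2f\n",
              m$n_nodes, m$n_edges, m$density, m$L, m$C))
  if (!is.null(x$small_world))
    cat(sprintf("  small-world: gamma %.2f, lambda %.2f, S = %.2f\n",
                x$small_world$gamma, x$small_world$lambda,
                x$small_world$smallworldness))
  for (mod in names(x$tests)) {
    mt <- x$tests[[mod]]$motifs
    sig <- mt$triad[mt$motif]
    cat(sprintf("  vs %s nulls (%d reps): GOF chi-sq %.1f (MC p %.4g); motifs: %s\n",
                mod, x$n_reps, x$tests[[mod]]$gof$statistic,
                x$tests[[mod]]$gof$p,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' @export
summary.antagonism <- function(object, ...) {
  structure(object, class = c("summary.antagonism", "antagonism"))
}

#' @export
print.summary.antagonism <- function(x, ...) {
  print.antagonism(x)
  cat("\nTriad census and motif tests:\n")
  for (mod in names(x$tests)) {
    cat(sprintf("-- model %s --\n", mod))
    print(x$tests[[mod]]$motifs[, c("triad", "name", "observed",
                                    "null_mean", "z", "p_fdr", "motif")],
          digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.antagonism <- function(object, ...) {
  m <- object$metrics
  out <- c(n_nodes = m$n_nodes, n_edges = m$n_edges, density = m$density,
           mean_degree = m$mean_in_degree, L = m$L, C = m$C)
  if (!is.null(object$small_world))
    out <- c(out, gamma = object$small_world$gamma,
             lambda = object$small_world$lambda,
             smallworldness = object$small_world$smallworldness)
  out
}

#' Expected triad frequencies under a fitted null model
#'
#' @param object An [antagonism()] fit.
#' @param model One of the fitted null models (default: first fitted).
#' @param ... Unused.
#' @return `predict()`: the 16-vector of ensemble mean triad frequencies;
#'   `residuals()`: observed minus expected frequencies.
#' @export
predict.antagonism <- function(object, model = names(object$ensembles)[1],
                               ...) {
  model <- match.arg(model, names(object$ensembles))
  object$ensembles[[model]]$triads$mean
}

#' @rdname predict.antagonism
#' @export
residuals.antagonism <- function(object,
                                 model = names(object$ensembles)[1], ...) {
  as.numeric(object$census) - predict.antagonism(object, model)
}

#' Draw networks from a fitted null model
#'
#' @param object An [antagonism()] fit.
#' @param nsim Number of networks to draw.
#' @param seed Optional seed.
#' @param model Null model to draw from.
#' @param ... Unused.
#' @return A list of [inhibition_network()] objects.
#' @export
simulate.antagonism <- function(object, nsim = 1, seed = NULL,
                                model = names(object$ensembles)[1], ...) {
  model <- match.arg(model, names(object$ensembles))
  if (!is.null(seed)) set.seed(seed)
  m <- object$metrics
  replicate(nsim, switch(model,
    er = sample_er(m$n_nodes, m$n_edges),
    dyad = sample_dyad_conditioned(object$dyads, m$n_nodes),
    degree = rewire_degree_preserving(object$network, object$n_swaps)),
    simplify = FALSE)
}

#' @export
plot.antagonism <- function(x, model = names(x$ensembles)[1], ...) {
  model <- match.arg(model, names(x$ensembles))
  obs <- as.numeric(x$census)
  exp <- x$ensembles[[model]]$triads$mean
  h <- rbind(observed = obs, expected = exp)
  graphics::barplot(h, beside = TRUE, names.arg = 1:16,
                    legend.text = TRUE, xlab = "triad class",
                    ylab = "frequency",
                    main = sprintf("Triad census vs %s null (community %s)",
                                   model, x$metrics$community_id), ...)
  invisible(x)
}
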