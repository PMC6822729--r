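# One-command orchestration: from raw zone tables or interaction matrices to
# a full report bundle (metrics, censuses, motif tests, orbit signatures,
# diversity ANOVA), driven by a YAML/JSON config or an equivalent list.

.default_config <- function() {
  list(threshold = 2, n_reps = 10000, n_swaps = 1000, mc_sims = 2000,
       alpha = 0.05, seed = 1L, models = c("er", "dyad", "degree"),
       output_dir = "antagonet-report")
}

#' Read and validate an analysis configuration
#'
#' A configuration names the inputs (either `matrices`, a named map of
#' community id to interaction-matrix file, or `zone_table` plus
#' `communities`, a two-column CSV `isolate,community`) and the analysis
#' parameters: `threshold` (mm, default 2), `n_reps` (default 10000),
#' `n_swaps` (default 1000), `mc_sims` (default 2000), `alpha` (default
#' 0.05), `models`, `seed`, and `output_dir`.
#'
#' @param config Path to a YAML (or JSON) file, or a list with the same
#'   fields.
#' @return A validated configuration list with defaults filled in.
#' @export
read_analysis_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config(), config)
  stopifnot(cfg$threshold >= 0, cfg$n_reps >= 2, cfg$n_swaps >= 0,
            cfg$mc_sims >= 1, cfg$alpha > 0, cfg$alpha < 1)
  cfg$models <- match.arg(unlist(cfg$models), c("er", "dyad", "degree"),
                          several.ok = TRUE)
  if (is.null(cfg$matrices) && is.null(cfg$zone_table))
    stop("config must name either 'matrices' or 'zone_table' inputs")
  cfg
}

.load_networks <- function(cfg) {
  if (!is.null(cfg$matrices)) {
    paths <- unlist(cfg$matrices)
    ids <- names(paths)
    if (is.null(ids)) ids <- sprintf("community%d", seq_along(paths))
    nets <- mapply(function(p, id) read_inhibition_matrix(p, community_id = id),
                   paths, ids, SIMPLIFY = FALSE)
    stats::setNames(nets, ids)
  } else {
    zones <- read_zone_table(cfg$zone_table)
    comm <- NULL
    if (!is.null(cfg$communities)) {
      cm <- utils::read.csv(cfg$communities, stringsAsFactors = FALSE)
      comm <- stats::setNames(as.character(cm[[2]]), as.character(cm[[1]]))
    }
    binarize(zones, communities = comm, threshold = cfg$threshold)
  }
}

#' Run the full antagonism-network analysis
#'
#' Loads one network per community, fits the configured null models with
#' [antagonism()], runs the orbit-signature and diversity analyses and the
#' cross-community census comparison, and writes a report bundle to the
#' output directory: `metrics.tsv`, `census.tsv`, `motif_tests.tsv`,
#' `orbits.tsv`, `diversity.tsv`, `analysis.json` (all parameters, seeds
#' and key results) and a `MANIFEST` noting completeness.  All randomness
#' derives from the single master seed in the config.
#'
#' @param config A configuration list or YAML path (see
#'   [read_analysis_config()]).
#' @return Invisibly, a list with the per-community [antagonism()] fits,
#'   the orbit/diversity results, the cross-community test, and the output
#'   paths.
#' @export
run_full_analysis <- function(config) {
  cfg <- read_analysis_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "analysis.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  cat("", file = logf)
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)

  nets <- .load_networks(cfg)
  logmsg("loaded %d communities: %s", length(nets),
         paste(names(nets), collapse = ", "))

  fits <- list()
  for (i in seq_along(nets)) {
    id <- names(nets)[i]
    fits[[id]] <- antagonism(nets[[i]], models = cfg$models,
                             n_reps = cfg$n_reps, n_swaps = cfg$n_swaps,
                             mc_sims = cfg$mc_sims, alpha = cfg$alpha,
                             seed = cfg$seed + 100000L * i)
    logmsg("fitted community %s", id)
  }

  tsv <- function(d, f) {
    p <- file.path(cfg$output_dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    p
  }

  met <- do.call(rbind, lapply(fits, function(f) {
    cf <- coef(f)
    data.frame(community = f$metrics$community_id, t(cf))
  }))
  tsv(met, "metrics.tsv")

  cen <- do.call(rbind, lapply(fits, function(f) {
    data.frame(community = f$metrics$community_id,
               t(as.integer(f$census)))
  }))
  names(cen)[-1] <- .TRIAD_NAMES
  tsv(cen, "census.tsv")

  mot <- do.call(rbind, lapply(fits, function(f) {
    do.call(rbind, lapply(f$tests, function(tt) {
      cbind(community = f$metrics$community_id, tt$motifs)
    }))
  }))
  tsv(mot, "motif_tests.tsv")

  orb <- do.call(rbind, lapply(names(nets), function(id) {
    oc <- node_orbit_census(nets[[id]])
    data.frame(community = id, isolate = rownames(oc), oc,
               check.names = FALSE)
  }))
  tsv(orb, "orbits.tsv")

  h <- node_shannon(as.matrix(orb[, -(1:2)]))
  div <- data.frame(community = orb$community, isolate = orb$isolate,
                    shannon = as.numeric(h))
  anova_res <- if (length(nets) >= 2 && all(table(div$community) >= 2))
    community_anova(div$shannon, div$community)
  tsv(div, "diversity.tsv")

  cross <- if (length(nets) >= 2) {
    set.seed(cfg$seed)
    cross_network_chisq(lapply(fits, function(f) f$census),
                        n_sim = cfg$mc_sims)
  }

  payload <- list(
    parameters = cfg[c("threshold", "n_reps", "n_swaps", "mc_sims",
                       "alpha", "seed", "models")],
    communities = lapply(fits, function(f) list(
      metrics = as.list(coef(f)),
      dyads = as.list(f$dyads),
      census = as.integer(f$census),
      gof = lapply(f$tests, function(tt) tt$gof[c("statistic", "p")]),
      motifs = lapply(f$tests, function(tt)
        tt$motifs$triad[tt$motifs$motif]))),
    cross_network = if (!is.null(cross))
      cross[c("statistic", "df", "p", "n_sim")],
    diversity = if (!is.null(anova_res))
      list(F = anova_res$F, p = anova_res$p,
           means = as.list(anova_res$means), sds = as.list(anova_res$sds)),
    package_version = as.character(utils::packageVersion("antagonet")))
  jp <- file.path(cfg$output_dir, "analysis.json")
  jsonlite::write_json(payload, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note("analysis.json")

  writeLines(c("complete", manifest),
             file.path(cfg$output_dir, "MANIFEST"))
  logmsg("analysis complete")
  invisible(list(fits = fits, orbits = orb, diversity = div,
                 anova = anova_res, cross_network = cross,
                 output_dir = cfg$output_dir))
}
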