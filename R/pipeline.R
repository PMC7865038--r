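# End-to-end pipeline: simulate (or load) -> clean -> crowds -> decompose ->
# fit -> report, with one master seed fanned out into named substreams and a
# manifest of stage checksums for reproducibility audits.

#' Pipeline run configuration
#'
#' Either `simulation` (a [simulation_config()]) or `input` (path to a trial
#' table in the standard format) must be supplied, never neither.
#'
#' @param simulation a [simulation_config()], or NULL when reading real data.
#' @param input path to a trial table, or NULL when simulating.
#' @param crowd_size outer-crowd size (default 10).
#' @param mcmc an [mcmc_config()]; its seed is overridden by a substream of
#'   `master_seed`.
#' @param prior a [half_normal_prior()].
#' @param likelihood observation model passed to [fit_crowd_model()].
#' @param output_dir directory for stage outputs and the manifest.
#' @param master_seed integer seed fanned out to the simulation, crowd
#'   assembly and MCMC substreams.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, input = NULL, crowd_size = 10L,
                       mcmc = mcmc_config(), prior = half_normal_prior(),
                       likelihood = "gaussian",
                       output_dir = tempfile("crowdwise_run_"),
                       master_seed = 1L) {
  if (is.null(simulation) && is.null(input)) {
    stop("either `simulation` or `input` must be set")
  }
  if (!is.null(simulation) && !inherits(simulation, "simulation_config")) {
    stop("`simulation` must be a simulation_config")
  }
  structure(list(simulation = simulation, input = input,
                 crowd_size = as.integer(crowd_size), mcmc = mcmc,
                 prior = prior, likelihood = likelihood,
                 output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `simulation`,
#' `mcmc` and `prior` are nested maps of the corresponding constructor
#' arguments (`prior` takes a `scale` key).
#'
#' @param path YAML file path.
#' @param output_dir,master_seed optional overrides of the file's values.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, output_dir = NULL, master_seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  mcmc <- if (!is.null(y$mcmc)) do.call(mcmc_config, y$mcmc) else mcmc_config()
  prior <- if (!is.null(y$prior)) do.call(half_normal_prior, y$prior)
           else half_normal_prior()
  run_config(simulation = sim, input = y$input,
             crowd_size = if (!is.null(y$crowd_size)) y$crowd_size else 10L,
             mcmc = mcmc, prior = prior,
             likelihood = if (!is.null(y$likelihood)) y$likelihood else "gaussian",
             output_dir = if (!is.null(output_dir)) output_dir
                          else if (!is.null(y$output_dir)) y$output_dir
                          else tempfile("crowdwise_run_"),
             master_seed = if (!is.null(master_seed)) master_seed
                           else if (!is.null(y$master_seed)) y$master_seed else 1L)
}

write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full crowd-wisdom pipeline
#'
#' Simulates (or loads) trial data, removes order-of-magnitude outliers,
#' builds inner and outer crowds, computes aggregation curves and per-crowd
#' decompositions on the proportional-error scale, fits the parabolic model
#' separately to each crowd type, and writes every stage as tab-delimited
#' text under `config$output_dir` together with a `manifest.yaml` recording
#' seeds, package version, row counts and MD5 checksums of the deterministic
#' stage files.
#'
#' @param config a [run_config()].
#' @param fit logical; set FALSE to stop after the deterministic stages
#'   (no MCMC), e.g. for quick data audits.
#' @return an object of class `pipeline_report`: a list with the cleaned
#'   data, removal counts, crowd series, curve observations, decompositions,
#'   fits (`fit_inner`, `fit_outer`), summary table and the manifest.
#' @export
run_pipeline <- function(config, fit = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[crowdwise] %s (%.1fs)", name,
                                          as.numeric(Sys.time() - t0, units = "secs")))

  stage("simulate/load")
  trials <- if (!is.null(config$input)) {
    read_trials(config$input)
  } else {
    sim <- config$simulation
    sim$seed <- substream_seed(config$master_seed, "simulation")
    simulate_experiment(sim)
  }

  stage("clean")
  filtered <- filter_magnitude_outliers(trials)

  stage("crowds")
  inner <- build_inner_crowds(filtered$kept)
  outer <- build_outer_crowds(filtered$kept, crowd_size = config$crowd_size,
                              seed = substream_seed(config$master_seed, "crowds"))
  series <- rbind(inner[, c("unit_id", "crowd_type", "set_size", "position", "estimate")],
                  outer[, c("unit_id", "crowd_type", "set_size", "position", "estimate")])
  observations <- curve_observations(series)

  stage("decompose")
  series$prop_error <- proportional_error(series$estimate, series$set_size)
  decomp <- decompose_table(cbind(series, truth0 = 0),
                            estimate_col = "prop_error", truth_col = "truth0",
                            by = c("crowd_type", "unit_id", "set_size"))

  files <- c(trials = write_stage(trials, config$output_dir, "trials.tsv"),
             kept = write_stage(filtered$kept, config$output_dir, "kept.tsv"),
             removed = write_stage(filtered$removed, config$output_dir, "removed.tsv"),
             curves = write_stage(observations, config$output_dir, "curves.tsv"),
             decompositions = write_stage(decomp, config$output_dir,
                                          "decompositions.tsv"))

  fits <- list(inner = NULL, outer = NULL)
  summary_tab <- NULL
  if (fit) {
    for (type in c("inner", "outer")) {
      stage(paste0("fit ", type))
      mc <- config$mcmc
      mc$seed <- substream_seed(config$master_seed, paste0("mcmc:", type))
      fits[[type]] <- fit_crowd_model(
        observations[observations$crowd_type == type, , drop = FALSE],
        prior = config$prior, mcmc = mc, likelihood = config$likelihood,
        retries = 3L)
    }
    summary_tab <- rbind(summarize_fit(fits$inner), summarize_fit(fits$outer))
    files <- c(files, summary = write_stage(summary_tab, config$output_dir,
                                            "fit_summary.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("crowdwise")),
    master_seed = config$master_seed,
    substreams = list(simulation = substream_seed(config$master_seed, "simulation"),
                      crowds = substream_seed(config$master_seed, "crowds"),
                      mcmc_inner = substream_seed(config$master_seed, "mcmc:inner"),
                      mcmc_outer = substream_seed(config$master_seed, "mcmc:outer")),
    counts = list(trials = nrow(trials), kept = nrow(filtered$kept),
                  removed = filtered$n_removed,
                  inner_series = length(unique(paste(inner$unit_id, inner$set_size))),
                  outer_crowds = length(unique(outer$unit_id))),
    checksums = as.list(tools::md5sum(files[c("trials", "kept", "removed",
                                              "curves", "decompositions")])),
    elapsed_seconds = as.numeric(Sys.time() - t0, units = "secs"))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  stage("done")

  structure(list(trials = trials, kept = filtered$kept,
                 removed = filtered$removed, n_removed = filtered$n_removed,
                 inner_series = inner, outer_series = outer,
                 observations = observations, decompositions = decomp,
                 fit_inner = fits$inner, fit_outer = fits$outer,
                 summary = summary_tab, manifest = manifest,
                 output_dir = config$output_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("crowdwise pipeline report\n")
  cat(sprintf("  trials %d (removed %d), inner series %d, outer crowds %d\n",
              x$manifest$counts$trials, x$manifest$counts$removed,
              x$manifest$counts$inner_series, x$manifest$counts$outer_crowds))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot-ready aggregation-curve table
#'
#' For each aggregate size `t`: the observed mean msep across units and set
#' sizes (the dots of an aggregation-curve figure), the fitted population
#' curve `a_mean/t + b_mean` (the solid line) and the asymptote `b_mean`
#' (the dashed line).
#'
#' @param observations curve observations for one crowd type.
#' @param fit the matching [fit_crowd_model()] result.
#' @return a data.frame with columns `t`, `observed_msep`, `fitted_msep`,
#'   `asymptote`.
#' @export
render_curve_export <- function(observations, fit) {
  stopifnot(inherits(fit, "crowd_fit"),
            all(c("t", "msep") %in% names(observations)))
  agg <- stats::aggregate(msep ~ t, data = observations, FUN = mean)
  agg <- agg[order(agg$t), ]
  data.frame(t = agg$t,
             observed_msep = agg$msep,
             fitted_msep = parabolic_mean(agg$t, fit$a_mean, fit$b_mean),
             asymptote = fit$b_mean)
}
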