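# Synthetic numerosity-estimation experiments.
#
# The generator emulates the structure of a star-counting task: each
# participant completes trials_per_set_size trials at each of six set sizes
# (50-100 stars by default, 60 critical trials in all), in an individually
# randomised order. Responses follow a multiplicative lognormal model,
#   estimate = round(set_size * beta_i * exp(eps)),  floored at 1,
# where beta_i = exp(N(bias_location, bias_spread^2)) is a stable
# person-level multiplicative bias (predominantly underestimation when
# bias_location < 0) and eps ~ N(0, noise_sd^2) is trial-level noise.
# Training is modelled as its effect: the trained defaults shrink both the
# bias magnitude and the within-person noise.

#' Simulation configuration for a numerosity-estimation experiment
#'
#' Bundles the design (participants, set sizes, trials per set size) and the
#' response-model parameters of the synthetic generator. The novice defaults
#' are calibrated so that the expected first-guess mean squared proportional
#' error (MSE_P) of the lognormal response model,
#' \eqn{E[(\beta e^\epsilon - 1)^2]}, is about 0.14; the trained defaults
#' give about 0.025, roughly five times smaller, with zero within-person
#' noise: a trained participant repeats the same (rounded) answer on every
#' trial of a set size, so the inner crowd has no diversity to aggregate
#' while people still differ from one another.
#'
#' @param n_participants number of simulated participants (>= 1).
#' @param set_sizes true star counts used on critical trials.
#' @param trials_per_set_size trials per set size per participant.
#' @param bias_location mean of the person-level log-bias log(beta_i).
#' @param bias_spread between-person SD of the log-bias (>= 0).
#' @param noise_sd within-person SD of trial-level log-scale noise (>= 0).
#' @param trained logical; selects the trained-regime defaults for the three
#'   response parameters when they are not supplied explicitly, and labels
#'   records with condition "trained".
#' @param typo_rate probability in [0, 1] that a record is corrupted by an
#'   order-of-magnitude typo (see [inject_typos()]); 0 by default.
#' @param seed master integer seed; per-participant substreams are derived
#'   from it, so increasing `n_participants` leaves earlier participants'
#'   data unchanged.
#' @return an object of class `simulation_config`.
#' @seealso [simulate_experiment()]
#' @export
#' @examples
#' cfg <- simulation_config(n_participants = 5, seed = 1)
#' trials <- simulate_experiment(cfg)
#' head(trials)
simulation_config <- function(n_participants,
                              set_sizes = seq(50L, 100L, by = 10L),
                              trials_per_set_size = 10L,
                              bias_location = NULL,
                              bias_spread = NULL,
                              noise_sd = NULL,
                              trained = FALSE,
                              typo_rate = 0,
                              seed = 1L) {
  defaults <- if (trained) {
    list(bias_location = -0.13, bias_spread = 0.12, noise_sd = 0)
  } else {
    list(bias_location = -0.38, bias_spread = 0.15, noise_sd = 0.30)
  }
  if (is.null(bias_location)) bias_location <- defaults$bias_location
  if (is.null(bias_spread)) bias_spread <- defaults$bias_spread
  if (is.null(noise_sd)) noise_sd <- defaults$noise_sd

  cfg <- list(n_participants = as.integer(n_participants),
              set_sizes = as.integer(set_sizes),
              trials_per_set_size = as.integer(trials_per_set_size),
              bias_location = bias_location,
              bias_spread = bias_spread,
              noise_sd = noise_sd,
              trained = isTRUE(trained),
              typo_rate = typo_rate,
              seed = as.integer(seed))
  vals <- c(cfg$bias_location, cfg$bias_spread, cfg$noise_sd, cfg$typo_rate)
  if (any(!is.finite(vals))) stop("non-finite configuration values")
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (length(cfg$set_sizes) < 1L || any(cfg$set_sizes < 1L)) {
    stop("set_sizes must all be >= 1")
  }
  if (cfg$trials_per_set_size < 1L) stop("trials_per_set_size must be >= 1")
  if (cfg$bias_spread < 0 || cfg$noise_sd < 0) {
    stop("bias_spread and noise_sd must be >= 0")
  }
  if (cfg$typo_rate < 0 || cfg$typo_rate > 1) stop("typo_rate must be in [0, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$n_participants, "participants,",
      length(x$set_sizes), "set sizes x", x$trials_per_set_size, "trials\n")
  cat(sprintf("  regime: %s (bias_location %.3g, bias_spread %.3g, noise_sd %.3g)\n",
              if (x$trained) "trained" else "novice",
              x$bias_location, x$bias_spread, x$noise_sd))
  cat(sprintf("  expected first-guess MSE_P: %.4f\n", expected_first_guess_msep(x)))
  invisible(x)
}

#' Closed-form expected first-guess squared proportional error
#'
#' For the lognormal response model (ignoring integer rounding of the typed
#' response), the proportional estimate \eqn{X = \beta e^\epsilon} is
#' lognormal with log-mean `bias_location` and log-variance
#' `bias_spread^2 + noise_sd^2`, so
#' \deqn{E[(X-1)^2] = e^{2\mu + 2\sigma^2} - 2 e^{\mu + \sigma^2/2} + 1.}
#' Used to calibrate the default regimes and as the analytic oracle for the
#' simulator's first-guess accuracy.
#'
#' @param config a [simulation_config()].
#' @return expected squared proportional error of a single estimate.
#' @export
expected_first_guess_msep <- function(config) {
  mu <- config$bias_location
  s2 <- config$bias_spread^2 + config$noise_sd^2
  exp(2 * mu + 2 * s2) - 2 * exp(mu + s2 / 2) + 1
}

#' Simulate a full numerosity-estimation experiment
#'
#' Generates one row per estimate. Each participant receives an independent,
#' seeded shuffle of the full trial list (every set size repeated
#' `trials_per_set_size` times), a person-level multiplicative bias
#' `beta_i`, and independent trial-level lognormal noise. Estimates are
#' rounded to the nearest whole star and floored at 1, since participants
#' type whole numbers. If `config$typo_rate > 0`, order-of-magnitude typos
#' are injected afterwards via [inject_typos()].
#'
#' @param config a [simulation_config()].
#' @return a data.frame with columns `participant_id`, `trial_index`,
#'   `set_size`, `estimate`, `condition`, sorted by participant and trial
#'   index; `n_participants * length(set_sizes) * trials_per_set_size` rows.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  condition <- if (config$trained) "trained" else "novice"
  n_trials <- length(config$set_sizes) * config$trials_per_set_size
  design <- rep(config$set_sizes, each = config$trials_per_set_size)

  per_participant <- lapply(seq_len(config$n_participants), function(i) {
    sub <- substream_seed(config$seed, paste0("participant:", i))
    with_seed(sub, {
      beta <- exp(stats::rnorm(1L, config$bias_location, config$bias_spread))
      order <- sample.int(n_trials)
      eps <- stats::rnorm(n_trials, 0, config$noise_sd)
      sizes <- design[order]
      est <- pmax(1L, as.integer(round(sizes * beta * exp(eps))))
      data.frame(participant_id = sprintf("P%03d", i),
                 trial_index = seq_len(n_trials),
                 set_size = sizes,
                 estimate = est,
                 condition = condition,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, per_participant)
  rownames(out) <- NULL
  if (config$typo_rate > 0) {
    out <- inject_typos(out, config$typo_rate,
                        seed = substream_seed(config$seed, "typos"))
  }
  out
}

#' Inject order-of-magnitude typos into a trial table
#'
#' Each record is independently replaced, with probability `typo_rate`, by a
#' magnitude-corrupted copy: the estimate is multiplied or divided by 10
#' (fair coin), rounded, and floored at 1. This emulates the slipped-digit
#' responses that the magnitude outlier filter is designed to remove.
#'
#' @param records a trial table (see [simulate_experiment()]).
#' @param typo_rate corruption probability in [0, 1].
#' @param seed integer seed for the corruption draws.
#' @return the trial table with corrupted estimates; the number of corrupted
#'   records is attached as attribute `"n_corrupted"` and their row indices
#'   as attribute `"corrupted_rows"`.
#' @export
inject_typos <- function(records, typo_rate, seed = 1L) {
  check_trials(records)
  stopifnot(is.numeric(typo_rate), length(typo_rate) == 1L, is.finite(typo_rate))
  if (typo_rate < 0 || typo_rate > 1) stop("typo_rate must be in [0, 1]")
  out <- records
  hit <- logical(nrow(records))
  if (typo_rate > 0 && nrow(records) > 0) {
    with_seed(seed, {
      hit <- stats::runif(nrow(records)) < typo_rate
      if (any(hit)) {
        up <- stats::runif(sum(hit)) < 0.5
        factor <- ifelse(up, 10, 0.1)
        out$estimate[hit] <- pmax(1L, as.integer(round(records$estimate[hit] * factor)))
      }
    })
  }
  attr(out, "n_corrupted") <- sum(hit)
  attr(out, "corrupted_rows") <- which(hit)
  out
}

#' Worked two-crowd decomposition fixture
#'
#' The textbook example of two three-member crowds estimating a true value of
#' 0: crowd A's errors (12, -14, 3) are diverse, crowd B's (0, -2, 1) are
#' not, so the two crowds have the same bias but very different variance and
#' hence very different crowd wisdom.
#'
#' @return a list with elements `crowd_a`, `crowd_b` (numeric error vectors)
#'   and `truth` (0).
#' @seealso [decompose_crowd()]
#' @export
two_crowds_fixture <- function() {
  list(crowd_a = c(12, -14, 3),
       crowd_b = c(0, -2, 1),
       truth = 0)
}

#' Read and write trial tables
#'
#' Trial tables are tab-delimited text with a header line and columns
#' `participant_id`, `trial_index`, `set_size`, `estimate`, `condition`.
#'
#' @param records a trial table.
#' @param path file path.
#' @return `read_trials` returns the trial table; `write_trials` returns
#'   `path` invisibly.
#' @export
write_trials <- function(records, path) {
  check_trials(records)
  cols <- c("participant_id", "trial_index", "set_size", "estimate", "condition")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_trials(out)
  out
}
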