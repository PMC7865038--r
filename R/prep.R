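# Cleaning and error coding.
#
# Accuracy is measured on a proportional scale so that errors are comparable
# across set sizes: an estimate of 55 for 50 stars is +0.10, 45 is -0.10,
# and both contribute 0.01 to the mean squared proportional error (MSE_P).
# Responses are deliberately not log-transformed. Estimates at least one
# order of magnitude off (ratio to the true count <= 0.1 or >= 10) are
# treated as typos and quarantined rather than analysed.

#' Proportional error of an estimate
#'
#' `proportional_error()` returns `(estimate - set_size) / set_size`, the
#' signed error as a proportion of the true value;
#' `squared_proportional_error()` returns its square, the per-trial
#' contribution to MSE_P.
#'
#' @param estimate the response (positive).
#' @param set_size the true number of items (>= 1). Both arguments are
#'   vectorised and recycled.
#' @return numeric vector of (squared) proportional errors.
#' @export
#' @examples
#' proportional_error(c(55, 45), 50)        # 0.10 -0.10
#' squared_proportional_error(c(55, 45), 50) # 0.01 0.01
proportional_error <- function(estimate, set_size) {
  stopifnot(is.numeric(estimate), is.numeric(set_size))
  if (any(set_size < 1)) stop("set_size must be >= 1")
  (estimate - set_size) / set_size
}

#' @rdname proportional_error
#' @export
squared_proportional_error <- function(estimate, set_size) {
  proportional_error(estimate, set_size)^2
}

#' Remove order-of-magnitude outliers from a trial table
#'
#' A record is removed iff its estimate is at least one order of magnitude
#' greater or smaller than the true count: `estimate / set_size >= 10` or
#' `<= 0.1`, boundaries inclusive (an estimate of 500 for 50 stars sits
#' exactly on the 10x boundary and is removed). Such responses are more
#' plausibly typos than sincere estimates. The decision depends only on the
#' estimate/set-size ratio. Removed records are returned alongside the kept
#' ones so that nothing is silently dropped.
#'
#' @param records a trial table (see [simulate_experiment()]).
#' @return a list with components `kept` and `removed` (both trial tables;
#'   their union is the input) and `n_removed`.
#' @export
#' @examples
#' trials <- simulate_experiment(simulation_config(5, typo_rate = 0.05, seed = 2))
#' filtered <- filter_magnitude_outliers(trials)
#' filtered$n_removed
filter_magnitude_outliers <- function(records) {
  check_trials(records)
  if (any(records$estimate <= 0) || any(records$set_size <= 0)) {
    stop("estimates and set sizes must be positive")
  }
  ratio <- records$estimate / records$set_size
  out <- ratio >= 10 | ratio <= 0.1
  kept <- records[!out, , drop = FALSE]
  removed <- records[out, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, n_removed = sum(out))
}
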