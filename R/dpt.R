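# Bias / MSE / variance decomposition of a crowd.
#
# For estimates x_1..x_n of a true value v, with errors e_i = x_i - v:
#   bias     = (mean e)^2          error of the crowd's aggregate
#   MSE      = mean(e^2)           error of an average individual estimate
#   variance = mean((e - mean e)^2)  diversity of the estimates (divide by n)
# The diversity prediction theorem is the algebraic identity
#   variance = MSE - bias,
# so crowd wisdom (MSE - bias, how much the aggregate beats an average
# individual) equals the diversity of the crowd's estimates. The population
# (divide-by-n) variance convention is required for the identity to hold
# exactly.

#' Decompose a crowd's error into bias, MSE and variance
#'
#' @param estimates nonempty numeric vector of estimates (any scale:
#'   raw counts or proportional errors — the identity is scale-invariant).
#' @param truth the true value being estimated.
#' @return an object of class `wisdom_decomposition`: a list with fields
#'   `bias`, `mse`, `variance`, `wisdom` (= mse - bias), `n`, `truth`.
#' @export
#' @examples
#' fx <- two_crowds_fixture()
#' decompose_crowd(fx$crowd_a, fx$truth) # bias 0.11, MSE 116.33, variance 116.22
#' decompose_crowd(fx$crowd_b, fx$truth) # bias 0.11, MSE 1.67,   variance 1.56
decompose_crowd <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("empty estimate list")
  stopifnot(is.numeric(estimates), all(is.finite(estimates)),
            is.numeric(truth), length(truth) == 1L, is.finite(truth))
  e <- estimates - truth
  m <- mean(e)
  out <- list(bias = m^2,
              mse = mean(e^2),
              variance = mean((e - m)^2),
              wisdom = mean(e^2) - m^2,
              n = length(estimates),
              truth = truth)
  class(out) <- "wisdom_decomposition"
  out
}

#' @export
print.wisdom_decomposition <- function(x, ...) {
  cat(sprintf("Crowd of %d estimates (truth %g):\n", x$n, x$truth))
  cat(sprintf("  bias %.4g  MSE %.4g  variance %.4g  (wisdom = MSE - bias = %.4g)\n",
              x$bias, x$mse, x$variance, x$wisdom))
  invisible(x)
}

#' Residual of the diversity-prediction-theorem identity
#'
#' Returns `|variance - (MSE - bias)|` for a decomposition; an exact
#' algebraic zero up to floating point, so the residual must not exceed
#' `1e-9 * max(1, MSE)`.
#'
#' @param d a [decompose_crowd()] result.
#' @return the nonnegative residual.
#' @export
verify_dpt <- function(d) {
  stopifnot(inherits(d, "wisdom_decomposition"))
  abs(d$variance - (d$mse - d$bias))
}

#' Grouped decomposition of a long table of estimates
#'
#' Applies [decompose_crowd()] within groups of a long table, e.g. per
#' (crowd, set size), returning one row per group.
#'
#' @param data a data.frame.
#' @param estimate_col name of the estimate column.
#' @param truth_col name of the column holding the true value (constant
#'   within each group).
#' @param by character vector of grouping column names.
#' @return a data.frame with the grouping columns plus `n`, `bias`, `mse`,
#'   `variance`, `wisdom`, and the DPT residual `dpt_residual`.
#' @export
decompose_table <- function(data, estimate_col = "estimate",
                            truth_col = "set_size",
                            by = c("unit_id", "set_size")) {
  stopifnot(is.data.frame(data),
            all(c(estimate_col, truth_col, by) %in% names(data)))
  groups <- split(data, data[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(groups, function(g) {
    truth <- unique(g[[truth_col]])
    if (length(truth) != 1L) stop("truth column not constant within a group")
    d <- decompose_crowd(g[[estimate_col]], truth)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = d$n, bias = d$bias, mse = d$mse,
                     variance = d$variance, wisdom = d$wisdom,
                     dpt_residual = verify_dpt(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
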