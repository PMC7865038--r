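# Inner- and outer-crowd construction and aggregation curves.
#
# An inner crowd is one person's repeated estimates of the same set size,
# aggregated in chronological order; an outer crowd is a group of people
# whose first estimates of each set size are aggregated in a random (but
# fixed within crowd, shared across set sizes) member order. Aggregation is
# the running arithmetic mean; the accuracy of the t-estimate aggregate is
# its squared proportional error, giving the (t, MSE_P) points the parabolic
# crowd-wisdom model is fit to.
#
# Crowd series are stored long: one row per (unit, set size, position), with
# crowd_type "inner" or "outer".

#' Running means (or medians) of an estimate sequence
#'
#' Element `t` of the result is the arithmetic mean (respectively median) of
#' the first `t` inputs: the value of a crowd aggregate as estimates
#' accumulate. The mean is the default aggregation statistic throughout the
#' package; the median is offered for robustness analyses.
#'
#' @param estimates nonempty numeric vector, in aggregation order.
#' @return numeric vector of running aggregates, same length as the input.
#' @export
#' @examples
#' cumulative_means(c(10, 20, 30))   # 10 15 20
#' cumulative_medians(c(10, 20, 90)) # 10 15 20
cumulative_means <- function(estimates) {
  if (length(estimates) == 0L) stop("empty estimate list")
  stopifnot(is.numeric(estimates), all(is.finite(estimates)))
  cumsum(estimates) / seq_along(estimates)
}

#' @rdname cumulative_means
#' @export
cumulative_medians <- function(estimates) {
  if (length(estimates) == 0L) stop("empty estimate list")
  stopifnot(is.numeric(estimates), all(is.finite(estimates)))
  vapply(seq_along(estimates),
         function(t) stats::median(estimates[seq_len(t)]), numeric(1))
}

#' Build inner-crowd series from a trial table
#'
#' One series per (participant, set size): that participant's estimates of
#' that set size in chronological (trial-index) order. If cleaning removed a
#' trial the series is simply shorter; nothing is imputed.
#'
#' @param records a cleaned trial table.
#' @return a crowd-series data.frame with columns `unit_id`, `crowd_type`
#'   (`"inner"`), `set_size`, `position` (1-based aggregation order) and
#'   `estimate`.
#' @export
build_inner_crowds <- function(records) {
  check_trials(records)
  ord <- order(records$participant_id, records$set_size, records$trial_index)
  r <- records[ord, , drop = FALSE]
  key <- interaction(r$participant_id, r$set_size, drop = TRUE, lex.order = TRUE)
  position <- stats::ave(seq_along(key), key, FUN = seq_along)
  out <- data.frame(unit_id = r$participant_id,
                    crowd_type = "inner",
                    set_size = r$set_size,
                    position = position,
                    estimate = as.numeric(r$estimate),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build outer-crowd series from a trial table
#'
#' Every participant anchors exactly one crowd: they contribute the first
#' estimate, and `crowd_size - 1` companions are drawn without replacement
#' from the remaining participants, in a random order that is identical
#' across set sizes within a crowd (with n crowds of size `crowd_size`
#' assembled from n people, participants necessarily belong to several
#' crowds). Only each member's chronologically first estimate of each set
#' size enters the crowd. If cleaning removed a member's first estimate of
#' a set size, their earliest surviving estimate is used; a member with no
#' surviving estimate of a set size is skipped for that set size.
#'
#' @param records a cleaned trial table.
#' @param crowd_size members per crowd (default 10); at most the number of
#'   participants.
#' @param seed integer master seed; each crowd's companions are drawn from a
#'   substream named by its anchor.
#' @return a crowd-series data.frame (see [build_inner_crowds()]) with
#'   `crowd_type = "outer"` and `unit_id` equal to the anchor's id prefixed
#'   with `"crowd:"`.
#' @export
build_outer_crowds <- function(records, crowd_size = 10L, seed = 1L) {
  check_trials(records)
  participants <- sort(unique(records$participant_id))
  n <- length(participants)
  if (crowd_size > n) stop("crowd_size exceeds the number of participants")
  if (crowd_size < 1L) stop("crowd_size must be >= 1")

  # first estimate per (participant, set_size)
  ord <- order(records$participant_id, records$set_size, records$trial_index)
  r <- records[ord, , drop = FALSE]
  first <- r[!duplicated(r[, c("participant_id", "set_size")]), , drop = FALSE]
  set_sizes <- sort(unique(records$set_size))
  est <- matrix(NA_real_, nrow = n, ncol = length(set_sizes),
                dimnames = list(participants, as.character(set_sizes)))
  est[cbind(match(first$participant_id, participants),
            match(first$set_size, set_sizes))] <- first$estimate

  crowds <- lapply(participants, function(anchor) {
    sub <- substream_seed(seed, paste0("crowd:", anchor))
    others <- setdiff(participants, anchor)
    members <- with_seed(sub, c(anchor, sample(others, crowd_size - 1L)))
    blocks <- lapply(seq_along(set_sizes), function(si) {
      e <- est[members, si]
      keep <- !is.na(e)
      if (!any(keep)) return(NULL)
      data.frame(unit_id = paste0("crowd:", anchor),
                 crowd_type = "outer",
                 set_size = set_sizes[si],
                 position = seq_len(sum(keep)),
                 estimate = as.numeric(e[keep]),
                 member_id = members[keep],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
  out <- do.call(rbind, crowds)
  rownames(out) <- NULL
  out
}

#' Aggregation-curve observations from crowd series
#'
#' For each series and each aggregate size `t`, computes the squared
#' proportional error of the mean of the first `t` estimates:
#' \deqn{MSE_P(t) = ((\bar x_{1:t} - s) / s)^2} with `s` the set size. These
#' (t, msep) points are the observations the `a/t + b` model is fit to. For
#' a fixed set size, averaging raw estimates and then taking the
#' proportional error is identical to averaging proportional errors.
#'
#' @param series a crowd-series data.frame from [build_inner_crowds()] or
#'   [build_outer_crowds()].
#' @param statistic aggregation statistic: `"mean"` (default, the standard
#'   crowd aggregate) or `"median"`.
#' @return a data.frame with columns `unit_id`, `crowd_type`, `set_size`,
#'   `t`, `msep`.
#' @export
curve_observations <- function(series, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  needed <- c("unit_id", "crowd_type", "set_size", "position", "estimate")
  if (!is.data.frame(series) || !all(needed %in% names(series))) {
    stop("`series` must be a crowd-series data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  agg <- switch(statistic, mean = cumulative_means, median = cumulative_medians)
  ord <- order(series$unit_id, series$set_size, series$position)
  s <- series[ord, , drop = FALSE]
  key <- interaction(s$unit_id, s$set_size, drop = TRUE, lex.order = TRUE)
  running <- stats::ave(s$estimate, key, FUN = agg)
  t_idx <- stats::ave(seq_along(key), key, FUN = seq_along)
  out <- data.frame(unit_id = s$unit_id,
                    crowd_type = s$crowd_type,
                    set_size = s$set_size,
                    t = t_idx,
                    msep = ((running - s$set_size) / s$set_size)^2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
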