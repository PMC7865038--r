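# Internal helpers shared across modules.

#' Derive a deterministic substream seed from a master seed and a label
#'
#' Fans one master seed out into named, reproducible substreams (one per
#' participant, per crowd, per pipeline stage) so that adding units or
#' rerunning a single stage never reshuffles the randomness used elsewhere.
#' The derived seed is a 31-bit integer, computed by a multiplicative string
#' hash; it is stable across platforms and R versions.
#'
#' @param master_seed integer master seed.
#' @param label character label naming the substream.
#' @return a single integer in [0, 2^31 - 2], usable with [set.seed()].
#' @keywords internal
substream_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed), is.character(label), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master_seed %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run an expression under a local, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_with <- function(class, message, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

# Validate a trial table: the long-format data.frame every module consumes.
check_trials <- function(records) {
  needed <- c("participant_id", "trial_index", "set_size", "estimate", "condition")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("`records` must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (anyDuplicated(records[, c("participant_id", "trial_index")])) {
    stop("duplicate (participant_id, trial_index) pairs in trial table")
  }
  invisible(records)
}
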