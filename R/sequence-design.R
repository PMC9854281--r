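#' Create a probabilistic sequence specification
#'
#' Draws a uniformly random cyclic successor permutation over `n_items`
#' items.  The cycle defines, for every item, its unique "regular"
#' successor; during trial generation a transition follows the cycle with
#' probability `p_regular` and is otherwise re-routed to a non-successor
#' item (see [next_item()]).
#'
#' @param n_items Number of distinct items (7 for the stimulus stream,
#'   6 for the response stream in the default design).  Must be at least 3:
#'   with fewer items there is no way to offer both a no-repetition
#'   alternative and a non-successor alternative on every trial.
#' @param p_regular Probability that a transition follows the successor
#'   cycle.  Default 0.5.
#' @param enabled If `FALSE` the stream carries no sequential structure:
#'   items are drawn uniformly subject only to the no-repetition
#'   constraint, and the regularity flag merely records chance
#'   coincidence with the successor.
#'
#' @return An object of class `sequence_spec`: a list with elements
#'   `n_items`, `successor` (integer vector, `successor[i]` is the regular
#'   follower of item `i`), `p_regular` and `enabled`.
#' @examples
#' set.seed(1)
#' spec <- make_sequence_spec(7)
#' spec$successor
#' @export
make_sequence_spec <- function(n_items, p_regular = 0.5, enabled = TRUE) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 3) {
    stop("`n_items` must be a single number >= 3 (no-repetition plus a ",
         "non-regular alternative requires at least 3 items)")
  }
  n_items <- as.integer(n_items)
  if (!is.numeric(p_regular) || p_regular < 0 || p_regular > 1) {
    stop("`p_regular` must lie in [0, 1]")
  }
  # a uniformly random single n-cycle: visit the items in a random order
  # and let each point to the next
  ord <- sample.int(n_items)
  successor <- integer(n_items)
  successor[ord] <- ord[c(2:n_items, 1L)]
  structure(
    list(n_items = n_items, successor = successor,
         p_regular = p_regular, enabled = isTRUE(enabled)),
    class = "sequence_spec"
  )
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> %d items, p_regular = %.2f%s\n",
              x$n_items, x$p_regular,
              if (x$enabled) "" else " (disabled)"))
  cat("  successor cycle:", paste(x$successor, collapse = " "), "\n")
  invisible(x)
}

#' Draw the next item of a probabilistic stream
#'
#' With probability `p_regular` the successor of `prev_item` is returned
#' and the transition is flagged regular.  Otherwise an item is drawn
#' uniformly from the items that are neither `prev_item` (no direct
#' repetitions) nor the successor, so a non-regular flag is exact, never a
#' chance coincidence.  For a disabled stream the draw is uniform over
#' all items except `prev_item`, and the flag records whether the draw
#' happens to coincide with the successor.
#'
#' @param spec A [make_sequence_spec()] object.
#' @param prev_item The item presented on the previous trial.
#' @return A list with `item` (integer) and `regular` (logical).
#' @export
next_item <- function(spec, prev_item) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (prev_item < 1L || prev_item > spec$n_items) {
    stop("`prev_item` is not a valid item of this spec")
  }
  succ <- spec$successor[prev_item]
  if (!spec$enabled) {
    pool <- seq_len(spec$n_items)[-prev_item]
    item <- pool[sample.int(length(pool), 1L)]
    return(list(item = item, regular = item == succ))
  }
  if (stats::runif(1L) < spec$p_regular) {
    list(item = succ, regular = TRUE)
  } else {
    pool <- setdiff(seq_len(spec$n_items), c(prev_item, succ))
    list(item = pool[sample.int(length(pool), 1L)], regular = FALSE)
  }
}

# Vectorised stream generation used by generate_trial_plan(); draws the
# whole stream sequentially (the process is Markov, so the loop is
# unavoidable, but all randomness comes from pre-drawn uniforms).
.generate_stream <- function(spec, n_trials) {
  items <- integer(n_trials)
  regular <- rep(NA, n_trials)
  items[1L] <- sample.int(spec$n_items, 1L)
  if (n_trials == 1L) return(list(items = items, regular = regular))
  u <- stats::runif(n_trials - 1L)
  pick <- stats::runif(n_trials - 1L) # uniform index into the alternative pool
  succ <- spec$successor
  n <- spec$n_items
  if (spec$enabled) {
    for (t in 2:n_trials) {
      prev <- items[t - 1L]
      s <- succ[prev]
      if (u[t - 1L] < spec$p_regular) {
        items[t] <- s
        regular[t] <- TRUE
      } else {
        # uniform among items excluding prev and its successor: index the
        # 1..n scale skipping the two excluded values
        k <- 1L + as.integer(pick[t - 1L] * (n - 2L))
        lo <- min(prev, s); hi <- max(prev, s)
        if (k >= lo) k <- k + 1L
        if (k >= hi) k <- k + 1L
        items[t] <- k
        regular[t] <- FALSE
      }
    }
  } else {
    for (t in 2:n_trials) {
      prev <- items[t - 1L]
      k <- 1L + as.integer(pick[t - 1L] * (n - 1L))
      if (k >= prev) k <- k + 1L
      items[t] <- k
      regular[t] <- (k == succ[prev])
    }
  }
  list(items = items, regular = regular)
}

#' Generate the full trial plan of one session
#'
#' Applies [next_item()] independently to the stimulus stream and the
#' response stream for `n_blocks * trials_per_block` trials.  Both streams
#' run continuously across block boundaries.  The first trial's items are
#' uniform draws and its regularity flags are `NA` (its trial type is
#' `"undefined"` and it is excluded from analysis).
#'
#' @param stimulus_spec,response_spec [make_sequence_spec()] objects for
#'   the two streams.
#' @param n_blocks,trials_per_block Session dimensions (defaults 6 and
#'   180, i.e. 1,080 trials).
#' @return A `data.frame` with columns `trial`, `block`, `stimulus`,
#'   `required_response`, `stimulus_regular`, `response_regular`,
#'   `trial_type`.
#' @examples
#' set.seed(1)
#' plan <- generate_trial_plan(make_sequence_spec(7), make_sequence_spec(6))
#' nrow(plan)             # 1080
#' table(plan$trial_type)
#' @export
generate_trial_plan <- function(stimulus_spec, response_spec,
                                n_blocks = 6L, trials_per_block = 180L) {
  stopifnot(inherits(stimulus_spec, "sequence_spec"),
            inherits(response_spec, "sequence_spec"),
            n_blocks >= 1L, trials_per_block >= 1L)
  n <- as.integer(n_blocks) * as.integer(trials_per_block)
  stim <- .generate_stream(stimulus_spec, n)
  resp <- .generate_stream(response_spec, n)
  plan <- data.frame(
    trial = seq_len(n),
    block = rep(seq_len(n_blocks), each = trials_per_block),
    stimulus = stim$items,
    required_response = resp$items,
    stimulus_regular = stim$regular,
    response_regular = resp$regular
  )
  plan$trial_type <- classify_trial(plan$stimulus_regular,
                                    plan$response_regular)
  plan
}

#' Classify a trial by the regularity of its two streams
#'
#' Maps the pair of regularity flags to the four trial-type labels used in
#' the analysis: `both_regular`, `stimulus_only`, `response_only`,
#' `neither`.  A missing flag (the first trial of a session) yields
#' `"undefined"`.
#'
#' @param stimulus_regular,response_regular Logical vectors (recycled to
#'   common length).
#' @return A character vector of labels.
#' @export
classify_trial <- function(stimulus_regular, response_regular) {
  n <- max(length(stimulus_regular), length(response_regular))
  s <- rep_len(stimulus_regular, n)
  r <- rep_len(response_regular, n)
  out <- rep("undefined", n)
  ok <- !is.na(s) & !is.na(r)
  out[ok & s & r] <- "both_regular"
  out[ok & s & !r] <- "stimulus_only"
  out[ok & !s & r] <- "response_only"
  out[ok & !s & !r] <- "neither"
  out
}

#' Ordered trial-type labels
#'
#' @return Character vector of the four defined trial types, in the
#'   conventional plotting order.
#' @export
trial_types <- function() {
  c("both_regular", "stimulus_only", "response_only", "neither")
}
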