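# Trace layout: each memory row has width 4 * vector_length, laid out as
# [current stimulus | previous stimulus | current (given) response |
#  previous (given) response].  The probe omits the current-response
# segment, so it aligns to row segments 1, 2 and 4.

.seg_cols <- function(seg, w) ((seg - 1L) * w + 1L):(seg * w)

.probe_cols <- function(w) c(.seg_cols(1L, w), .seg_cols(2L, w), .seg_cols(4L, w))

# Exact 4-segment episode vector (before probabilistic storage).
.episode_vector <- function(bank, s_now, s_prev, r_given, r_prev) {
  c(bank$stimulus[s_now, ], bank$stimulus[s_prev, ],
    bank$response[r_given, ], bank$response[r_prev, ])
}

#' Initialise memory with pre-experimental traces
#'
#' Builds the instance memory with `n` rows encoding episodes whose
#' current/previous stimulus and response indices are independent uniform
#' draws (no sequential structure), each feature stored with probability
#' `L` and zeroed otherwise.
#'
#' @param bank A [sample_symbol_bank()] object.
#' @param n Number of pre-experimental traces (default 200).
#' @param L Learning rate: per-feature storage probability (default 0.8).
#' @return An object of class `instance_memory`: a list with `traces`
#'   (numeric matrix, one row per instance, entries in \{-1, 0, +1\}),
#'   `vector_length`, and `bank`.
#' @examples
#' set.seed(1)
#' mem <- init_preexperimental(sample_symbol_bank())
#' dim(mem$traces)  # 200 120
#' @export
init_preexperimental <- function(bank, n = 200L, L = 0.8) {
  stopifnot(inherits(bank, "symbol_bank"), n >= 0L, L > 0, L <= 1)
  w <- bank$vector_length
  n_s <- nrow(bank$stimulus)
  n_r <- nrow(bank$response)
  traces <- matrix(0, nrow = n, ncol = 4L * w)
  if (n > 0L) {
    for (i in seq_len(n)) {
      ep <- .episode_vector(bank,
                            sample.int(n_s, 1L), sample.int(n_s, 1L),
                            sample.int(n_r, 1L), sample.int(n_r, 1L))
      traces[i, ] <- ep * (stats::runif(4L * w) < L)
    }
  }
  structure(list(traces = traces, vector_length = w, bank = bank),
            class = "instance_memory")
}

#' @export
print.instance_memory <- function(x, ...) {
  cat(sprintf("<instance_memory> %d traces of width %d\n",
              nrow(x$traces), ncol(x$traces)))
  invisible(x)
}

#' Encode one trial as a new memory trace
#'
#' Appends one row encoding the episode (current stimulus, previous
#' stimulus, response **given** -- including erroneous responses -- and
#' previous given response).  Each of the features is independently kept
#' with probability `L` and replaced by zero otherwise; a nonzero stored
#' feature always equals the corresponding bank-vector entry.
#'
#' @param memory An [init_preexperimental()] object.
#' @param s_now,s_prev Stimulus indices of the current and previous trial.
#' @param r_given,r_prev Indices of the response actually given on the
#'   current and previous trial.
#' @param L Learning rate (default 0.8).
#' @return The updated `instance_memory` (one more row).
#' @export
encode_instance <- function(memory, s_now, s_prev, r_given, r_prev, L = 0.8) {
  stopifnot(inherits(memory, "instance_memory"), L > 0, L <= 1)
  w <- memory$vector_length
  ep <- .episode_vector(memory$bank, s_now, s_prev, r_given, r_prev)
  row <- ep * (stats::runif(4L * w) < L)
  memory$traces <- rbind(memory$traces, row, deparse.level = 0L)
  memory
}

#' Build the retrieval probe
#'
#' Concatenates the exact bank vectors of the information available
#' before a response is selected: the current stimulus, the previous
#' stimulus, and the previous given response.  The probe is never
#' degraded by the learning rate.
#'
#' @param bank A `symbol_bank`.
#' @param s_now,s_prev Stimulus indices.
#' @param r_prev Index of the previous given response.
#' @return A numeric vector of width `3 * vector_length` with entries
#'   in \{-1, +1\}.
#' @export
build_probe <- function(bank, s_now, s_prev, r_prev) {
  c(bank$stimulus[s_now, ], bank$stimulus[s_prev, ], bank$response[r_prev, ])
}

# Core probe-trace similarity on a raw trace matrix: for each row i,
# S_i = (1/J) sum_j P_j M_ij over the J = 3*vector_length probe-aligned
# columns.  J is a constant; zeros stored in memory lower the similarity
# rather than shrinking the normaliser.
.similarities_core <- function(traces, probe, w) {
  drop(traces[, .probe_cols(w), drop = FALSE] %*% probe) / length(probe)
}

#' Probe-trace similarities
#'
#' For every stored instance, the similarity between the probe and the
#' probe-aligned features of the trace (current stimulus, previous
#' stimulus, previous response segments), normalised by the fixed probe
#' width J = 90.
#'
#' @param memory An `instance_memory` with at least one trace.
#' @param probe A [build_probe()] vector.
#' @return Numeric vector of per-instance similarities.
#' @export
trace_similarities <- function(memory, probe) {
  stopifnot(inherits(memory, "instance_memory"))
  if (nrow(memory$traces) == 0L) stop("memory holds no traces")
  if (length(probe) != 3L * memory$vector_length) {
    stop("probe width does not match the memory layout")
  }
  .similarities_core(memory$traces, probe, memory$vector_length)
}

# Echo content/intensity on raw pieces; shared by the exported API and
# the simulation hot loop (where traces beyond the active row count are
# all-zero and contribute nothing).
.echo_core <- function(traces, probe, w) {
  s <- .similarities_core(traces, probe, w)
  a <- s^3
  content <- drop(crossprod(traces, a))
  intensity <- sum(probe * content[.probe_cols(w)])
  list(similarities = s, activations = a, content = content,
       response_content = content[.seg_cols(3L, w)], intensity = intensity,
       activation_sum = sum(a))
}

#' Retrieve the memory echo
#'
#' Computes per-instance similarities S, activations A = S^3, the echo
#' content C (the activation-weighted sum of all traces across the full
#' trace width, including the current-response segment), the
#' current-response segment C* of the content, and the echo intensity
#' I = sum over probe-aligned positions of P_j C_j.  Algebraically
#' I = J * sum(S^4) >= 0.
#'
#' Two summary measures of retrieval strength are returned: `intensity`,
#' the probe-content match I above, and `activation_sum`, the summed
#' activation `sum(A)` -- the classical global-matching echo intensity.
#' The two behave very differently as memory grows: signed activations of
#' unrelated traces cancel in `activation_sum`, whereas `intensity`
#' accumulates a strictly positive partial-match floor proportional to
#' the trace count.  See the package vignette for why the drift coupling
#' defaults to the summed activation.
#'
#' @inheritParams trace_similarities
#' @return A list of class `echo_result` with elements `similarities`,
#'   `activations`, `content`, `response_content`, `intensity`,
#'   `activation_sum`.
#' @export
retrieve_echo <- function(memory, probe) {
  stopifnot(inherits(memory, "instance_memory"))
  if (nrow(memory$traces) == 0L) stop("memory holds no traces")
  out <- .echo_core(memory$traces, probe, memory$vector_length)
  class(out) <- "echo_result"
  out
}

#' Signal-to-noise ratio of the response echo
#'
#' The unsigned similarity (cosine plus one) between the echo's
#' current-response content and the bank vector of the to-be-pressed
#' response, divided by the summed unsigned similarities over all
#' candidate responses.  Lies in (0, 1); an uninformative echo gives 1/K.
#'
#' @param response_content The current-response segment of the echo
#'   content (`$response_content` of [retrieve_echo()]).
#' @param bank A `symbol_bank`.
#' @param correct_index Index of the required (correct) response.
#' @return A scalar in (0, 1).  If the response content is exactly zero
#'   (possible only in degenerate tiny-memory configurations) the cosine
#'   is undefined and the uninformative baseline `1/K` is returned.
#' @export
response_snr <- function(response_content, bank, correct_index) {
  K <- nrow(bank$response)
  norm_c <- sqrt(sum(response_content^2))
  if (norm_c == 0) return(1 / K)
  cosines <- drop(bank$response %*% response_content) /
    (norm_c * sqrt(rowSums(bank$response^2)))
  (1 + cosines[correct_index]) / sum(1 + cosines)
}

#' Drift input from echo intensity and SNR
#'
#' The product SNR x I is fed into the diffusion drift rate, bounded
#' below by `floor` (default 3): `max(floor, snr * intensity)`.  The
#' bound mode is configurable for sensitivity analyses.
#'
#' @param snr Signal-to-noise ratio from [response_snr()].
#' @param intensity Echo intensity from [retrieve_echo()].
#' @param floor Bound value (default 3).
#' @param floor_mode `"floor"` (default) applies `max(floor, .)`;
#'   `"cap"` applies `min(floor, .)`; `"none"` passes the product through.
#' @return The drift rate delta.
#' @export
drift_input <- function(snr, intensity, floor = 3,
                        floor_mode = c("floor", "cap", "none")) {
  floor_mode <- match.arg(floor_mode)
  x <- snr * intensity
  switch(floor_mode,
         floor = pmax(floor, x),
         cap = pmin(floor, x),
         none = x)
}
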