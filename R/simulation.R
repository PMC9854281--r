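#' Experiment configuration
#'
#' Collects every tunable of the simulated SRTT design.  The defaults
#' reproduce the reference design: 1,000 datasets of 40 participants, six
#' blocks of 180 trials, a 7-item stimulus and a 6-item response sequence
#' each with 50% regular transitions, 13 feature vectors of length 30
#' capped at pairwise cosine .4, 200 pre-experimental traces, learning
#' rate L = .8, and diffusion parameters alpha = 1.5, beta = .2,
#' tau = .3 with drift floor 3.
#'
#' @param n_datasets,n_participants,n_blocks,trials_per_block Design
#'   dimensions.
#' @param n_stimuli,n_responses Number of stimulus and response items.
#' @param p_regular_stimulus,p_regular_response Regular-transition
#'   probabilities of the two streams.
#' @param stimulus_sequence_enabled,response_sequence_enabled Disable a
#'   stream to remove its sequential structure (items then drawn
#'   uniformly subject to no-repetition; the basis for null and
#'   single-sequence designs).
#' @param vector_length,max_cos,cap_mode Symbol-bank settings (see
#'   [sample_symbol_bank()]).
#' @param L Learning rate: per-feature storage probability.
#' @param n_pre Number of pre-experimental memory traces.
#' @param alpha,beta,tau Diffusion parameters (see [diffusion_params()]).
#' @param drift_floor,floor_mode Drift bound (see [drift_input()]).
#' @param drift_coupling Which retrieval-strength measure is multiplied
#'   by the SNR to form the drift input: `"activation"` (default) uses
#'   the summed activation `sum(S^3)`, the classical global-matching
#'   echo intensity, under which the drift floor binds early and releases
#'   as matching traces accumulate; `"content"` uses the probe-content
#'   match `sum(P * C)` (identically `90 * sum(S^4)`), whose
#'   trace-count-proportional partial-match floor saturates the drift so
#'   errors all but vanish; `"content_normalized"` uses
#'   `sum(P * C) / 90`.  See the vignette.
#' @param censor_at First-passage censoring deadline in seconds.
#' @param track_given_response If `TRUE` (default) the previous-trial
#'   response register carries the response actually given, so after an
#'   error the next probe and trace hold the wrong key; `FALSE` tracks
#'   the required response instead (sensitivity analysis).
#' @param master_seed Integer master seed from which all dataset and
#'   participant seeds are derived.
#' @param diagnostics If `TRUE`, per-trial `snr`, `intensity` and `drift`
#'   columns are included in the trial table.
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config(n_datasets = 2, n_participants = 3)
#' @export
experiment_config <- function(n_datasets = 1000L, n_participants = 40L,
                              n_blocks = 6L, trials_per_block = 180L,
                              n_stimuli = 7L, n_responses = 6L,
                              p_regular_stimulus = 0.5,
                              p_regular_response = 0.5,
                              stimulus_sequence_enabled = TRUE,
                              response_sequence_enabled = TRUE,
                              vector_length = 30L, max_cos = 0.4,
                              cap_mode = "signed",
                              L = 0.8, n_pre = 200L,
                              alpha = 1.5, beta = 0.2, tau = 0.3,
                              drift_floor = 3, floor_mode = "floor",
                              drift_coupling = c("activation", "content",
                                                 "content_normalized"),
                              censor_at = 10,
                              track_given_response = TRUE,
                              master_seed = 1L, diagnostics = FALSE) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_stimuli = as.integer(n_stimuli),
    n_responses = as.integer(n_responses),
    p_regular_stimulus = p_regular_stimulus,
    p_regular_response = p_regular_response,
    stimulus_sequence_enabled = isTRUE(stimulus_sequence_enabled),
    response_sequence_enabled = isTRUE(response_sequence_enabled),
    vector_length = as.integer(vector_length),
    max_cos = max_cos, cap_mode = cap_mode,
    L = L, n_pre = as.integer(n_pre),
    alpha = alpha, beta = beta, tau = tau,
    drift_floor = drift_floor, floor_mode = floor_mode,
    drift_coupling = match.arg(drift_coupling),
    censor_at = censor_at,
    track_given_response = isTRUE(track_given_response),
    master_seed = as.integer(master_seed),
    diagnostics = isTRUE(diagnostics)
  )
  with(cfg, {
    stopifnot(n_datasets >= 1L, n_participants >= 1L, n_blocks >= 1L,
              trials_per_block >= 1L, n_stimuli >= 3L, n_responses >= 3L,
              p_regular_stimulus >= 0, p_regular_stimulus <= 1,
              p_regular_response >= 0, p_regular_response <= 1,
              vector_length >= 1L, L > 0, L <= 1, n_pre >= 0L,
              alpha > 0, beta > 0, beta < 1, tau >= 0)
  })
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d datasets x %d participants x %d blocks x %d trials\n",
    x$n_datasets, x$n_participants, x$n_blocks, x$trials_per_block))
  cat(sprintf(
    "  sequences: %d stimuli (p=%.2f%s), %d responses (p=%.2f%s); L=%.2f, n_pre=%d\n",
    x$n_stimuli, x$p_regular_stimulus,
    if (x$stimulus_sequence_enabled) "" else ", disabled",
    x$n_responses, x$p_regular_response,
    if (x$response_sequence_enabled) "" else ", disabled",
    x$L, x$n_pre))
  cat(sprintf(
    "  diffusion: alpha=%.2f beta=%.2f tau=%.2f drift %s %.1f\n",
    x$alpha, x$beta, x$tau, x$floor_mode, x$drift_floor))
  invisible(x)
}

#' Run a single trial through the full model cycle
#'
#' Functional single-trial reference: builds the probe from the current
#' stimulus and the previous-trial registers, retrieves the echo,
#' computes SNR (keyed to the required response) and the drift input,
#' samples the diffusion, selects the given response, encodes the trial
#' (with the response actually given) and advances the registers.
#' [run_participant()] executes the identical cycle in an optimised
#' in-place loop; the two agree draw-for-draw under a common seed.
#'
#' @param state A list with `memory` (an [init_preexperimental()]
#'   object), `prev_stimulus`, `prev_response`.
#' @param stimulus Current stimulus index.
#' @param required_response Index of the to-be-pressed response.
#' @param config An [experiment_config()].
#' @return A list with `record` (given_response, rt_s, correct, censored,
#'   snr, intensity, drift) and the advanced `state`.
#' @export
run_trial <- function(state, stimulus, required_response, config) {
  bank <- state$memory$bank
  probe <- build_probe(bank, stimulus, state$prev_stimulus,
                       state$prev_response)
  e <- retrieve_echo(state$memory, probe)
  snr <- response_snr(e$response_content, bank, required_response)
  strength <- switch(config$drift_coupling,
                     activation = e$activation_sum,
                     content = e$intensity,
                     content_normalized = e$intensity / length(probe))
  drift <- drift_input(snr, strength, config$drift_floor,
                       config$floor_mode)
  w <- sample_wiener(1L, diffusion_params(config$alpha, config$beta,
                                          config$tau),
                     drift, config$censor_at)
  given <- select_response(w$upper, required_response, config$n_responses)
  state$memory <- encode_instance(state$memory, stimulus,
                                  state$prev_stimulus, given,
                                  state$prev_response, config$L)
  state$prev_stimulus <- stimulus
  state$prev_response <- if (config$track_given_response) given else
    required_response
  list(record = list(given_response = given, rt_s = w$rt,
                     correct = w$upper, censored = w$censored,
                     snr = snr, intensity = e$intensity, drift = drift),
       state = state)
}

#' Simulate one participant's session
#'
#' Generates the participant's trial plan, initialises a fresh
#' pre-experimental memory, and runs the per-trial
#' probe -> echo -> decide -> encode cycle continuously over all blocks.
#' Deterministic given `seed`.
#'
#' @param config An [experiment_config()].
#' @param bank The dataset's [sample_symbol_bank()].
#' @param stimulus_spec,response_spec The dataset's sequence specs.
#' @param seed Participant seed.
#' @param dataset,participant Identifiers recorded in the output.
#' @return A `data.table` with one row per trial: `dataset`,
#'   `participant`, `block`, `trial`, `stimulus`, `required_response`,
#'   `given_response`, `stimulus_regular`, `response_regular`,
#'   `trial_type`, `rt_s`, `correct`, `censored` (plus `snr`,
#'   `intensity`, `drift` when `config$diagnostics`).
#' @export
run_participant <- function(config, bank, stimulus_spec, response_spec,
                            seed, dataset = 1L, participant = 1L) {
  set.seed(seed)
  n_trials <- config$n_blocks * config$trials_per_block
  plan <- generate_trial_plan(stimulus_spec, response_spec,
                              config$n_blocks, config$trials_per_block)
  memory <- init_preexperimental(bank, config$n_pre, config$L)
  prev_s <- sample.int(config$n_stimuli, 1L)
  prev_r <- sample.int(config$n_responses, 1L)

  w <- config$vector_length
  pcols <- .probe_cols(w)
  rcols <- .seg_cols(3L, w)
  cap <- config$n_pre + n_trials
  # probe-aligned and response-segment views of the trace store,
  # zero-padded to final capacity (all-zero rows have zero similarity and
  # activation, so they contribute nothing to echo content or intensity)
  Mp <- matrix(0, cap, length(pcols))
  Mc <- matrix(0, cap, w)
  if (config$n_pre > 0L) {
    Mp[seq_len(config$n_pre), ] <- memory$traces[, pcols]
    Mc[seq_len(config$n_pre), ] <- memory$traces[, rcols]
  }
  n_rows <- config$n_pre

  dparams <- diffusion_params(config$alpha, config$beta, config$tau)
  J <- length(pcols)
  resp_norm <- sqrt(rowSums(bank$response^2))
  given <- integer(n_trials)
  rt <- numeric(n_trials)
  correct <- logical(n_trials)
  censored <- logical(n_trials)
  snr_v <- numeric(n_trials)
  int_v <- numeric(n_trials)
  drift_v <- numeric(n_trials)
  stim <- plan$stimulus
  req <- plan$required_response

  for (t in seq_len(n_trials)) {
    probe <- c(bank$stimulus[stim[t], ], bank$stimulus[prev_s, ],
               bank$response[prev_r, ])
    s_i <- drop(Mp %*% probe) / J
    a_i <- s_i^3
    c_star <- drop(crossprod(Mc, a_i))
    intensity <- J * sum(a_i * s_i)                  # = sum_j P_j C_j exactly
    norm_c <- sqrt(sum(c_star^2))
    snr <- if (norm_c == 0) 1 / config$n_responses else {
      cosines <- drop(bank$response %*% c_star) / (norm_c * resp_norm)
      (1 + cosines[req[t]]) / sum(1 + cosines)
    }
    strength <- switch(config$drift_coupling,
                       activation = sum(a_i),
                       content = intensity,
                       content_normalized = intensity / J)
    drift <- drift_input(snr, strength, config$drift_floor,
                         config$floor_mode)
    wres <- sample_wiener(1L, dparams, drift, config$censor_at)
    g <- select_response(wres$upper, req[t], config$n_responses)

    # encode the trial with the response actually given
    ep <- c(bank$stimulus[stim[t], ], bank$stimulus[prev_s, ],
            bank$response[g, ], bank$response[prev_r, ])
    row <- ep * (stats::runif(4L * w) < config$L)
    n_rows <- n_rows + 1L
    Mp[n_rows, ] <- row[pcols]
    Mc[n_rows, ] <- row[rcols]

    given[t] <- g
    rt[t] <- wres$rt
    correct[t] <- wres$upper
    censored[t] <- wres$censored
    snr_v[t] <- snr
    int_v[t] <- intensity
    drift_v[t] <- drift
    prev_s <- stim[t]
    prev_r <- if (config$track_given_response) g else req[t]
  }

  out <- data.table::data.table(
    dataset = dataset, participant = participant,
    block = plan$block, trial = plan$trial,
    stimulus = stim, required_response = req, given_response = given,
    stimulus_regular = plan$stimulus_regular,
    response_regular = plan$response_regular,
    trial_type = plan$trial_type,
    rt_s = rt, correct = correct, censored = censored
  )
  if (config$diagnostics) {
    out[, `:=`(snr = snr_v, intensity = int_v, drift = drift_v)]
  }
  out
}

#' Simulate one dataset (a group of participants)
#'
#' Draws one symbol bank and one successor cycle per stream for the whole
#' dataset, derives per-participant seeds from the dataset seed, and runs
#' every participant on a fresh pre-experimental memory.
#'
#' @param config An [experiment_config()].
#' @param dataset_index 1-based dataset identifier.
#' @param dataset_seed Seed for this dataset (derived from the master
#'   seed by [run_experiment()]).
#' @return A list with `trials` (a `data.table` of
#'   `n_participants * n_blocks * trials_per_block` rows), `bank`, and
#'   `metadata` (seeds, cycles, config echo).
#' @export
run_dataset <- function(config, dataset_index, dataset_seed) {
  set.seed(dataset_seed)
  bank <- sample_symbol_bank(config$n_stimuli, config$n_responses,
                             config$vector_length, config$max_cos,
                             config$cap_mode)
  stim_spec <- make_sequence_spec(config$n_stimuli,
                                  config$p_regular_stimulus,
                                  config$stimulus_sequence_enabled)
  resp_spec <- make_sequence_spec(config$n_responses,
                                  config$p_regular_response,
                                  config$response_sequence_enabled)
  participant_seeds <- sample.int(.Machine$integer.max - 1L,
                                  config$n_participants)
  trials <- data.table::rbindlist(lapply(
    seq_len(config$n_participants),
    function(p) run_participant(config, bank, stim_spec, resp_spec,
                                participant_seeds[p],
                                dataset = dataset_index, participant = p)
  ))
  metadata <- list(
    dataset = dataset_index,
    dataset_seed = dataset_seed,
    participant_seeds = participant_seeds,
    stimulus_cycle = stim_spec$successor,
    response_cycle = resp_spec$successor,
    package_version = as.character(utils::packageVersion("srtecho"))
  )
  list(trials = trials, bank = bank, metadata = metadata,
       stimulus_spec = stim_spec, response_spec = resp_spec)
}

#' Run the full simulation experiment
#'
#' Maps [run_dataset()] over `config$n_datasets` datasets, with dataset
#' seeds derived from `config$master_seed`, and aggregates the results
#' into the block x trial-type summary.  The result is bit-identical for
#' a given config regardless of how datasets are scheduled, because every
#' dataset re-seeds from its own derived seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, each dataset's
#'   trial table is written as `dataset-<i>.csv` (RFC-4180, UTF-8), its
#'   symbol bank as `dataset-<i>-bank.txt`, and its metadata as
#'   `dataset-<i>-meta.json`, plus the grand `summary.csv`.
#' @param keep_trials Keep all trial tables in memory and return them
#'   (default `TRUE`; set to `FALSE` for large runs written to disk).
#' @param verbose Print per-dataset progress.
#' @return A list of class `srt_experiment` with `trials` (or `NULL`),
#'   `summary` (an [aggregate_trials()] object), `metadata` (one entry
#'   per dataset) and `config`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(n_datasets = 2, n_participants = 2,
#'                          n_blocks = 2, trials_per_block = 30,
#'                          n_pre = 20, master_seed = 7)
#' ex <- run_experiment(cfg)
#' ex$summary$summary
#' }
#' @export
run_experiment <- function(config, out_dir = NULL, keep_trials = TRUE,
                           verbose = FALSE) {
  set.seed(config$master_seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, config$n_datasets)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  all_trials <- vector("list", config$n_datasets)
  all_cells <- vector("list", config$n_datasets)
  all_meta <- vector("list", config$n_datasets)
  for (i in seq_len(config$n_datasets)) {
    ds <- run_dataset(config, i, dataset_seeds[i])
    all_cells[[i]] <- .participant_cells(ds$trials)
    all_meta[[i]] <- ds$metadata
    if (!is.null(out_dir)) {
      data.table::fwrite(ds$trials,
                         file.path(out_dir, sprintf("dataset-%d.csv", i)))
      write_symbol_bank(ds$bank,
                        file.path(out_dir, sprintf("dataset-%d-bank.txt", i)))
      meta <- ds$metadata
      meta$bank_file <- sprintf("dataset-%d-bank.txt", i)
      meta$config <- unclass(config)
      jsonlite::write_json(meta,
                           file.path(out_dir, sprintf("dataset-%d-meta.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
    if (keep_trials) all_trials[[i]] <- ds$trials
    if (verbose) {
      message(sprintf("dataset %d/%d done (%d trials)", i,
                      config$n_datasets, nrow(ds$trials)))
    }
  }
  cells <- data.table::rbindlist(all_cells)
  summary <- .summarise_cells(cells)
  if (!is.null(out_dir)) {
    data.table::fwrite(summary$summary, file.path(out_dir, "summary.csv"))
  }
  structure(
    list(trials = if (keep_trials) data.table::rbindlist(all_trials) else NULL,
         summary = summary, metadata = all_meta, config = config),
    class = "srt_experiment"
  )
}

#' @export
print.srt_experiment <- function(x, ...) {
  cat(sprintf("<srt_experiment> %d dataset(s), %d participants each\n",
              x$config$n_datasets, x$config$n_participants))
  print(x$summary$summary)
  invisible(x)
}
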