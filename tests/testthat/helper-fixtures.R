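# Shared fixtures and independent brute-force oracles.

tiny_config <- function(...) {
  defaults <- list(n_datasets = 1L, n_participants = 2L, n_blocks = 2L,
                   trials_per_block = 15L, n_pre = 20L, master_seed = 99L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# Naive per-row, per-position similarity: an independent reimplementation
# of the probe-trace match used to validate the vectorised production code.
naive_similarities <- function(memory, probe) {
  w <- memory$vector_length
  cols <- c(1:(2 * w), (3 * w + 1):(4 * w))
  sapply(seq_len(nrow(memory$traces)), function(i) {
    s <- 0
    for (j in seq_along(cols)) s <- s + probe[j] * memory$traces[i, cols[j]]
    s / length(cols)
  })
}

# Naive echo: explicit loops over traces and positions.
naive_echo <- function(memory, probe) {
  s <- naive_similarities(memory, probe)
  a <- s^3
  w <- memory$vector_length
  content <- numeric(4 * w)
  for (j in seq_len(4 * w)) {
    for (i in seq_len(nrow(memory$traces))) {
      content[j] <- content[j] + a[i] * memory$traces[i, j]
    }
  }
  cols <- c(1:(2 * w), (3 * w + 1):(4 * w))
  intensity <- sum(probe * content[cols])
  list(similarities = s, content = content, intensity = intensity,
       response_content = content[(2 * w + 1):(3 * w)])
}

# Naive aggregation: nested loops over the trial table.
naive_aggregate <- function(trials) {
  trials <- as.data.frame(trials)
  trials <- trials[trials$trial_type != "undefined", ]
  keys <- unique(trials[, c("dataset", "participant", "block", "trial_type")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    k <- keys[r, ]
    sub <- trials[trials$dataset == k$dataset &
                    trials$participant == k$participant &
                    trials$block == k$block &
                    trials$trial_type == k$trial_type, ]
    ok <- sub$correct & !sub$censored
    out[[r]] <- data.frame(
      k,
      mean_rt_s = if (any(ok)) mean(sub$rt_s[ok]) else NA_real_,
      error_rate = mean(!sub$correct),
      n_trials = nrow(sub))
  }
  do.call(rbind, out)
}
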