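test_that("config defaults reproduce the reference design and are validated", {
  cfg <- experiment_config()
  expect_identical(cfg$n_datasets, 1000L)
  expect_identical(cfg$n_participants, 40L)
  expect_identical(cfg$n_blocks * cfg$trials_per_block, 1080L)
  expect_identical(c(cfg$n_stimuli, cfg$n_responses), c(7L, 6L))
  expect_equal(c(cfg$p_regular_stimulus, cfg$p_regular_response), c(.5, .5))
  expect_equal(c(cfg$vector_length, cfg$n_pre), c(30L, 200L))
  expect_equal(c(cfg$L, cfg$max_cos), c(.8, .4))
  expect_equal(c(cfg$alpha, cfg$beta, cfg$tau, cfg$drift_floor),
               c(1.5, .2, .3, 3))
  expect_error(experiment_config(n_participants = 0), "n_participants")
  expect_error(experiment_config(L = 0), "L")
})

test_that("a participant session has the right shape and bookkeeping", {
  set.seed(1)
  cfg <- tiny_config()
  bank <- sample_symbol_bank()
  ss <- make_sequence_spec(7)
  rs <- make_sequence_spec(6)
  tr <- run_participant(cfg, bank, ss, rs, seed = 77L,
                        dataset = 3L, participant = 9L)
  expect_identical(nrow(tr), 30L)
  expect_identical(unique(tr$dataset), 3L)
  expect_identical(unique(tr$participant), 9L)
  expect_true(all(tr$rt_s > cfg$tau))
  expect_identical(tr$correct, tr$given_response == tr$required_response)
  expect_identical(tr$trial_type[1], "undefined")
  expect_identical(tr$trial_type[-1],
                   classify_trial(tr$stimulus_regular[-1],
                                  tr$response_regular[-1]))
  # identical seed, identical table
  tr2 <- run_participant(cfg, bank, ss, rs, seed = 77L,
                         dataset = 3L, participant = 9L)
  expect_identical(tr, tr2)
})

test_that("run_trial and the optimised session loop agree draw-for-draw", {
  cfg <- tiny_config(diagnostics = TRUE)
  set.seed(5)
  bank <- sample_symbol_bank()
  ss <- make_sequence_spec(7)
  rs <- make_sequence_spec(6)
  fast <- run_participant(cfg, bank, ss, rs, seed = 123L)

  # reference loop over the exported functional operations, consuming the
  # random stream in the same documented order
  set.seed(123L)
  plan <- generate_trial_plan(ss, rs, cfg$n_blocks, cfg$trials_per_block)
  state <- list(memory = init_preexperimental(bank, cfg$n_pre, cfg$L),
                prev_stimulus = sample.int(7, 1),
                prev_response = sample.int(6, 1))
  for (t in seq_len(nrow(plan))) {
    step <- run_trial(state, plan$stimulus[t], plan$required_response[t], cfg)
    state <- step$state
    rec <- step$record
    expect_identical(fast$given_response[t], rec$given_response)
    expect_equal(fast$rt_s[t], rec$rt_s)
    expect_identical(fast$correct[t], rec$correct)
    expect_equal(fast$snr[t], rec$snr)
    expect_equal(fast$intensity[t], rec$intensity)
    expect_equal(fast$drift[t], rec$drift)
  }
  # memory-size ledger: initial traces plus one appended row per trial
  expect_identical(nrow(state$memory$traces),
                   cfg$n_pre + nrow(plan))
})

test_that("after an error the probe registers carry the given response", {
  cfg <- tiny_config()
  set.seed(8)
  bank <- sample_symbol_bank()
  state <- list(memory = init_preexperimental(bank, cfg$n_pre, cfg$L),
                prev_stimulus = 1L, prev_response = 1L)
  # force an error by rerunning until one occurs
  repeat {
    step <- run_trial(state, 2L, 3L, cfg)
    if (!step$record$correct) break
  }
  expect_false(step$record$given_response == 3L)
  expect_identical(step$state$prev_response, step$record$given_response)
  # the encoded trace's current-response segment matches the given key
  row <- step$state$memory$traces[nrow(step$state$memory$traces), ]
  seg <- row[61:90]
  given_vec <- bank$response[step$record$given_response, ]
  expect_true(all(seg[seg != 0] == given_vec[seg != 0]))
})

test_that("datasets draw fresh banks and are internally reproducible", {
  cfg <- tiny_config()
  d1 <- run_dataset(cfg, 1L, dataset_seed = 101L)
  d2 <- run_dataset(cfg, 2L, dataset_seed = 202L)
  expect_identical(nrow(d1$trials),
                   cfg$n_participants * cfg$n_blocks * cfg$trials_per_block)
  expect_false(identical(d1$bank, d2$bank))
  expect_false(identical(d1$metadata$stimulus_cycle,
                         d2$metadata$stimulus_cycle) &&
                 identical(d1$metadata$response_cycle,
                           d2$metadata$response_cycle))
  d1b <- run_dataset(cfg, 1L, dataset_seed = 101L)
  expect_identical(d1$trials, d1b$trials)
  expect_identical(d1$bank, d1b$bank)
})

test_that("the experiment writes per-dataset artefacts and a summary", {
  cfg <- tiny_config(n_datasets = 2L)
  out <- withr::local_tempdir()
  ex <- run_experiment(cfg, out_dir = out)
  expect_identical(nrow(ex$trials), 2L * 2L * 30L)
  for (i in 1:2) {
    expect_true(file.exists(file.path(out, sprintf("dataset-%d.csv", i))))
    expect_true(file.exists(file.path(out, sprintf("dataset-%d-bank.txt", i))))
    expect_true(file.exists(file.path(out, sprintf("dataset-%d-meta.json", i))))
  }
  expect_true(file.exists(file.path(out, "summary.csv")))
  # metadata reproduces the bank byte-for-byte
  meta <- jsonlite::read_json(file.path(out, "dataset-1-meta.json"),
                              simplifyVector = TRUE)
  redrawn <- run_dataset(cfg, 1L, meta$dataset_seed)
  stored <- read_symbol_bank(file.path(out, "dataset-1-bank.txt"))
  expect_equal(stored$stimulus, redrawn$bank$stimulus)
  expect_equal(stored$response, redrawn$bank$response)
  # the CSV round-trips the trial table
  back <- data.table::fread(file.path(out, "dataset-1.csv"))
  expect_identical(nrow(back), 2L * 30L)
  expect_equal(back$rt_s, ex$trials[dataset == 1, rt_s])
  # rerunning the config reproduces the experiment bit-for-bit
  ex2 <- run_experiment(cfg)
  expect_identical(ex$trials, ex2$trials)
})
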