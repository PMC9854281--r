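test_that("pre-experimental memory has the stated size and storage rate", {
  set.seed(2)
  bank <- sample_symbol_bank()
  mem <- init_preexperimental(bank)
  expect_identical(dim(mem$traces), c(200L, 120L))
  expect_true(all(mem$traces %in% c(-1, 0, 1)))
  # L = .8: nonzero fraction near .8 (4-sigma binomial band at 24,000)
  expect_lt(abs(mean(mem$traces != 0) - 0.8), 4 * sqrt(0.8 * 0.2 / 24000))
  # L = 1: no zeros at all
  full <- init_preexperimental(bank, n = 50L, L = 1)
  expect_false(any(full$traces == 0))
})

test_that("encoding appends exactly one subset-of-episode row", {
  set.seed(6)
  bank <- sample_symbol_bank()
  mem <- init_preexperimental(bank, n = 5L)
  mem2 <- encode_instance(mem, 2L, 5L, 3L, 1L, L = 1)
  expect_identical(nrow(mem2$traces), 6L)
  episode <- c(bank$stimulus[2L, ], bank$stimulus[5L, ],
               bank$response[3L, ], bank$response[1L, ])
  expect_equal(mem2$traces[6L, ], episode)   # L = 1: stored verbatim
  # at L = .8 every nonzero entry equals the episode entry (no flips) and
  # about 24 of 120 positions are zeroed
  zeros <- replicate(200, {
    m <- encode_instance(mem, 2L, 5L, 3L, 1L, L = 0.8)
    row <- m$traces[6L, ]
    stopifnot(all(row[row != 0] == episode[row != 0]))
    sum(row == 0)
  })
  expect_lt(abs(mean(zeros) - 24), 4 * sqrt(120 * 0.2 * 0.8 / 200))
})

test_that("the probe is the exact 90-wide concatenation, never degraded", {
  set.seed(10)
  bank <- sample_symbol_bank()
  p1 <- build_probe(bank, 4L, 7L, 2L)
  p2 <- build_probe(bank, 4L, 7L, 2L)
  expect_identical(length(p1), 90L)
  expect_true(all(p1 %in% c(-1, 1)))
  expect_identical(p1, p2)
  expect_equal(p1, c(bank$stimulus[4L, ], bank$stimulus[7L, ],
                     bank$response[2L, ]))
})

test_that("similarities follow the fixed-J probe alignment", {
  set.seed(14)
  bank <- sample_symbol_bank()
  mem <- init_preexperimental(bank, n = 0L)
  # fully stored matching trace: S = 1 exactly
  mem <- encode_instance(mem, 1L, 2L, 3L, 4L, L = 1)
  probe <- build_probe(bank, 1L, 2L, 4L)
  expect_equal(trace_similarities(mem, probe), 1)
  # a trace that is all-zero on the probe-aligned positions scores 0
  mem$traces[1, c(1:60, 91:120)] <- 0
  expect_equal(trace_similarities(mem, probe), 0)
  # partial storage: E[S] = L (each position contributes L/J in expectation)
  set.seed(14)
  s_vals <- replicate(400, {
    m <- encode_instance(init_preexperimental(bank, n = 0L),
                         1L, 2L, 3L, 4L, L = 0.8)
    trace_similarities(m, probe)
  })
  expect_lt(abs(mean(s_vals) - 0.8), 4 * sqrt(0.8 * 0.2 / (400 * 90)))
})

test_that("echo matches the brute-force loop oracle on random memories", {
  set.seed(19)
  bank <- sample_symbol_bank()
  for (rep in 1:5) {
    mem <- init_preexperimental(bank, n = 10L)
    probe <- build_probe(bank, sample.int(7, 1), sample.int(7, 1),
                         sample.int(6, 1))
    got <- retrieve_echo(mem, probe)
    want <- naive_echo(mem, probe)
    expect_equal(got$similarities, want$similarities, tolerance = 1e-12)
    expect_equal(got$content, want$content, tolerance = 1e-12)
    expect_equal(got$response_content, want$response_content,
                 tolerance = 1e-12)
    expect_equal(got$intensity, want$intensity, tolerance = 1e-12)
    expect_equal(got$activations, got$similarities^3)
    expect_equal(got$activation_sum, sum(got$similarities^3))
  }
})

test_that("a single fully stored matching trace gives the degenerate echo", {
  set.seed(22)
  bank <- sample_symbol_bank()
  mem <- encode_instance(init_preexperimental(bank, n = 0L),
                         3L, 1L, 5L, 2L, L = 1)
  probe <- build_probe(bank, 3L, 1L, 2L)
  e <- retrieve_echo(mem, probe)
  expect_equal(e$similarities, 1)
  expect_equal(e$activations, 1)
  expect_equal(e$content, mem$traces[1, ])
  expect_equal(e$intensity, 90)
})

test_that("echo intensity equals 90 * sum(S^4) identically", {
  set.seed(25)
  bank <- sample_symbol_bank()
  for (rep in 1:20) {
    mem <- init_preexperimental(bank, n = sample(1:30, 1))
    probe <- build_probe(bank, sample.int(7, 1), sample.int(7, 1),
                         sample.int(6, 1))
    e <- retrieve_echo(mem, probe)
    expect_equal(e$intensity, 90 * sum(e$similarities^4),
                 tolerance = 1e-9)
    expect_gte(e$intensity, 0)
  }
})

test_that("cubing preserves the sign of the similarity", {
  expect_equal((-0.5)^3, -0.125)
  set.seed(26)
  bank <- sample_symbol_bank()
  mem <- init_preexperimental(bank, n = 20L)
  probe <- build_probe(bank, 1L, 2L, 3L)
  e <- retrieve_echo(mem, probe)
  expect_identical(sign(e$activations), sign(e$similarities))
})

test_that("response SNR follows the unsigned-similarity share formula", {
  set.seed(28)
  bank <- sample_symbol_bank()
  # direct evaluation against an explicit computation
  mem <- init_preexperimental(bank, n = 30L)
  probe <- build_probe(bank, 2L, 4L, 1L)
  cstar <- retrieve_echo(mem, probe)$response_content
  sims <- 1 + apply(bank$response, 1L, vector_cosine, v = cstar)
  for (m in 1:6) {
    expect_equal(response_snr(cstar, bank, m), sims[m] / sum(sims))
  }
  # the shares normalise to one over the candidate set
  shares <- sapply(1:6, response_snr, response_content = cstar, bank = bank)
  expect_equal(sum(shares), 1)
  # C* perfectly aligned with the correct response, orthogonal-by-construction
  # cosines elsewhere contribute 1 each: SNR = 2 / (2 + 5) when the five
  # other cosines are zero
  snr_perfect <- (1 + 1) / ((1 + 1) + 5 * (1 + 0))
  expect_equal(snr_perfect, 2 / 7)
  # all-zero response content falls back to the uninformative 1/K
  expect_equal(response_snr(rep(0, 30), bank, 3L), 1 / 6)
  expect_true(all(shares > 0 & shares < 1))
})

test_that("the drift input applies the configured bound to SNR x intensity", {
  expect_equal(drift_input(0.5, 20), 10)       # above the floor: unchanged
  expect_equal(drift_input(0.5, 2), 3)         # below the floor: floored
  expect_equal(drift_input(0.5, 2, floor_mode = "cap"), 1)
  expect_equal(drift_input(0.5, 20, floor_mode = "cap"), 3)
  expect_equal(drift_input(0.5, 2, floor_mode = "none"), 1)
  # nondecreasing in the product
  x <- seq(0, 20, by = 0.5)
  expect_true(all(diff(drift_input(1, x)) >= 0))
})
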