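test_that("band-pass removes DC, passes 10 Hz, attenuates 60 Hz", {
  fs <- 250
  n <- fs * 20
  t <- (seq_len(n) - 1) / fs
  core <- (2 * fs + 1):(n - 2 * fs)   # discard 2-s edges

  dc <- bandpass_filter(new_recording("d", "O1", fs, matrix(100, 1, n)))
  expect_lt(sqrt(mean(dc$data[1, core]^2)), 0.1)

  s10 <- bandpass_filter(new_recording("s", "O1", fs,
                                       matrix(sin(2 * pi * 10 * t), 1)))
  amp10 <- max(abs(s10$data[1, core]))
  expect_gte(amp10, 0.99)
  expect_lte(amp10, 1.01)

  s60 <- bandpass_filter(new_recording("s", "O1", fs,
                                       matrix(sin(2 * pi * 60 * t), 1)))
  expect_lt(max(abs(s60$data[1, core])), 0.05)

  # the designed response itself (forward-backward => squared magnitude)
  expect_equal(bandpass_gain_sq(10, 1, 45, fs), 1, tolerance = 1e-4)
  expect_lt(bandpass_gain_sq(60, 1, 45, fs), 0.05)
  expect_equal(bandpass_gain_sq(0, 1, 45, fs), 0)

  expect_error(bandpass_filter(dc, low = 50, high = 45), "invalid cutoffs")
  expect_error(bandpass_filter(dc, low = 1, high = 130), "invalid cutoffs")
})

test_that("filtering commutes with epoch extraction away from boundaries", {
  set.seed(11)
  fs <- 250
  rec <- new_recording("c", c("O1", "O2"), fs,
                       matrix(rnorm(2 * fs * 60, sd = 10), 2))
  whole <- bandpass_filter(rec)
  # epoch samples 20-40 s cut first, then filtered
  cut <- new_recording("c", c("O1", "O2"), fs,
                       rec$data[, (20 * fs + 1):(40 * fs)])
  piece <- bandpass_filter(cut)
  # compare the interior of the epoch (2-s guard on each side)
  a <- whole$data[, (22 * fs + 1):(38 * fs)]
  b <- piece$data[, (2 * fs + 1):(18 * fs)]
  expect_lt(max(abs(a - b)), 0.05 * stats::sd(a))
})

test_that("T9/T10 re-referencing is common-mode-removing and idempotent", {
  fs <- 100
  n <- 500
  m <- MONTAGE
  common <- sin(2 * pi * 3 * (1:n) / fs)
  X <- matrix(rep(common, each = 25), 25, n)
  rec <- new_recording("r", m$name, fs, X)
  rr <- rereference(rec)
  expect_lt(max(abs(rr$data)), 1e-12)
  expect_identical(rr$reference, "T9T10")

  # O1 = r(t) + s(t), T9 = T10 = r(t)  ->  output O1 = s(t) exactly
  s <- cos(2 * pi * 7 * (1:n) / fs)
  X2 <- X
  X2[m$name == "O1", ] <- common + s
  rec2 <- new_recording("r", m$name, fs, X2)
  rr2 <- rereference(rec2)
  expect_equal(rr2$data[m$name == "O1", ], s, tolerance = 1e-12)

  # idempotence
  set.seed(3)
  rec3 <- new_recording("r", m$name, fs, matrix(rnorm(25 * n), 25))
  once <- rereference(rec3)
  twice <- rereference(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)

  expect_error(rereference(new_recording("x", c("O1", "O2"), fs,
                                         matrix(0, 2, n))),
               "reference channel")
})

test_that("epoch screening ranks by peak-to-peak score with onset tie-break", {
  # equal scores: first 8 candidates by onset
  rec <- recording_with_scores(rep(10, 10))
  ep <- screen_epochs(rec, n_select = 8, epoch_len = 20)
  expect_identical(ep$selected, 1:8)
  expect_equal(ep$epoch_onsets, (0:7) * 20)

  # worked ranking: the 8 smallest of [30,10,20,40,25,15,35,22,18,90]
  rec2 <- recording_with_scores(c(30, 10, 20, 40, 25, 15, 35, 22, 18, 90))
  ep2 <- screen_epochs(rec2, n_select = 8, epoch_len = 20)
  expect_identical(ep2$selected, c(2L, 6L, 9L, 3L, 8L, 5L, 1L, 7L))
  expect_equal(ep2$screening_scores,
               c(30, 10, 20, 40, 25, 15, 35, 22, 18, 90))

  # hard threshold: a 500 uV transient epoch is excluded outright
  scores <- c(rep(20, 9), 500)
  ep3 <- screen_epochs(recording_with_scores(scores), n_select = 8)
  expect_false(10L %in% ep3$selected)

  # epochs are exactly 20 s and non-overlapping
  expect_equal(dim(ep2$epochs)[3], 20 * rec2$fs)
  expect_false(any(duplicated(ep2$epoch_onsets)))

  # quality error lists scores when too few candidates survive
  expect_error(screen_epochs(recording_with_scores(rep(900, 10))),
               "below the 400 uV.*scores")
  expect_error(screen_epochs(recording_with_scores(rep(10, 5))),
               "admits only 5")
})

test_that("screening is deterministic and the chain preserves layout", {
  rec <- quick_subject("det", seed = 21)
  cfg <- default_config()
  a <- preprocess_recording(rec, cfg)
  b <- preprocess_recording(rec, cfg)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$channels, rec$channels)
  expect_equal(a$fs, rec$fs)
  expect_equal(dim(a$epochs), c(8, 25, 20 * 250))
})

test_that("blink-correlated components are removed, posterior channels spared", {
  set.seed(5)
  fs <- 250
  n <- fs * 40
  chans <- c("Fp1", "Fp2", "O1", "O2", "Cz")
  # heavy-tailed independent background so the decomposition is well posed
  X <- matrix(rt(5 * n, df = 5), 5, n)
  # alpha-ish oscillation posteriorly
  X[3, ] <- X[3, ] + 4 * sin(2 * pi * 10 * (1:n) / fs)
  X[4, ] <- X[4, ] + 4 * sin(2 * pi * 10 * (1:n) / fs + 1)
  ep_clean <- epochs_from_matrix(X, chans, fs, n_epochs = 2)
  out_clean <- remove_artifact_components(ep_clean)
  expect_identical(attr(out_clean, "n_removed"), 0L)
  expect_equal(out_clean$epochs, ep_clean$epochs, tolerance = 1e-6)

  # inject a strong common blink train on the frontal channels
  blink <- numeric(n)
  starts <- seq(fs, n - fs, by = 2 * fs)
  wave <- 150 * sin(2 * pi * seq_len(fs / 2) / (fs / 2))
  for (s0 in starts) blink[s0:(s0 + fs / 2 - 1)] <- wave
  Xb <- X
  Xb[1, ] <- Xb[1, ] + blink
  Xb[2, ] <- Xb[2, ] + 0.9 * blink
  ep_blink <- epochs_from_matrix(Xb, chans, fs, n_epochs = 2)
  out <- remove_artifact_components(ep_blink)
  expect_gte(attr(out, "n_removed"), 1L)
  v_before <- var(as.vector(ep_blink$epochs[, 1, ]))
  v_after <- var(as.vector(out$epochs[, 1, ]))
  expect_lt(v_after, 0.5 * v_before)
  o1_before <- var(as.vector(ep_blink$epochs[, 3, ]))
  o1_after <- var(as.vector(out$epochs[, 3, ]))
  expect_lt(abs(o1_after - o1_before) / o1_before, 0.1)
  # shape and units unchanged
  expect_identical(dim(out$epochs), dim(ep_blink$epochs))
})
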