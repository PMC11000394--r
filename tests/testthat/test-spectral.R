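test_that("Welch PSD is Parseval-normalized and frequency-accurate", {
  set.seed(13)
  fs <- 250
  # white noise, sigma^2 = 4: integral of the one-sided PSD ~ variance
  X <- matrix(rnorm(2 * fs * 160, sd = 2), 2)
  ep <- epochs_from_matrix(X, c("O1", "O2"), fs, n_epochs = 8)
  sp <- compute_psd(ep)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_equal(df, 0.25)
  expect_equal(sum(sp$psd[1, ]) * df, 4, tolerance = 0.05 * 4)
  expect_true(all(sp$psd >= 0))
  expect_equal(sp$n_epochs_averaged, 8)

  # unit 10 Hz sinusoid: 9-11 Hz band power ~ A^2/2 = 0.5
  t <- (seq_len(fs * 160) - 1) / fs
  eps <- epochs_from_matrix(matrix(sin(2 * pi * 10 * t), 1), "O1", fs,
                            n_epochs = 8)
  sps <- compute_psd(eps)
  band <- sps$freqs >= 9 & sps$freqs <= 11
  expect_equal(sum(sps$psd[1, band]) * df, 0.5, tolerance = 0.05 * 0.5)

  # zero signal -> identically zero PSD
  ep0 <- epochs_from_matrix(matrix(0, 1, fs * 20), "O1", fs)
  expect_true(all(compute_psd(ep0)$psd == 0))

  # epoch shorter than one segment is a parameter error
  expect_error(compute_psd(epochs_from_matrix(matrix(0, 1, fs * 2), "O1", fs)),
               "shorter than")
})

test_that("PSD agrees with an independent periodogram oracle", {
  # oracle: single rectangular-window periodogram via raw FFT on one epoch
  set.seed(17)
  fs <- 100
  n <- fs * 20
  x <- rnorm(n)
  ep <- epochs_from_matrix(matrix(x, 1), "O1", fs)
  sp <- compute_psd(ep, seg_len = 20)          # one segment = whole epoch
  xc <- x - mean(x)
  # Hann-windowed oracle, same normalization convention
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))
  X <- fft(xc * w)
  nf <- n %/% 2 + 1
  P <- Mod(X[1:nf])^2 / (fs * sum(w^2))
  P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
  expect_equal(sp$psd[1, ], P, tolerance = 1e-10)
})

test_that("IAF detection follows the peak / boundary / flat rules", {
  freqs <- seq(0, 125, 0.25)
  # single spectral line at 10 Hz
  p <- numeric(length(freqs)); p[freqs == 10] <- 2
  d <- detect_iaf(spectrum_from_psd(p, freqs), "O1")
  expect_equal(d$iaf, 10)
  expect_identical(d$peak_quality, "distinct_peak")

  # two alpha lines, 9 Hz (power 4) beats 12 Hz (power 1)
  p2 <- numeric(length(freqs)); p2[freqs == 9] <- 4; p2[freqs == 12] <- 1
  d2 <- detect_iaf(spectrum_from_psd(p2, freqs), "O1")
  expect_equal(d2$iaf, 9)
  expect_identical(d2$peak_quality, "distinct_peak")

  # strictly decreasing 1/f-like spectrum: lower edge, boundary quality
  d3 <- detect_iaf(spectrum_from_psd(1 / (1 + freqs), freqs), "O1")
  expect_equal(d3$iaf, 8)
  expect_identical(d3$peak_quality, "boundary_peak")

  # constant band: lower edge, flat
  d4 <- detect_iaf(spectrum_from_psd(rep(1, length(freqs)), freqs), "O1")
  expect_equal(d4$iaf, 8)
  expect_identical(d4$peak_quality, "flat")

  # ties break toward the lower frequency
  p5 <- numeric(length(freqs)); p5[freqs %in% c(9, 12)] <- 3
  expect_equal(detect_iaf(spectrum_from_psd(p5, freqs), "O1")$iaf, 9)

  expect_error(detect_iaf(spectrum_from_psd(p, freqs), "O1",
                          band = c(8, 200)), "outside the frequency grid")
})

test_that("alpha-band PSD is the mean over the closed IAF +/- 1 Hz window", {
  freqs <- seq(0, 125, 0.25)
  # constant spectrum: mean is the constant, for any IAF
  sc <- spectrum_from_psd(rep(3.5, length(freqs)), freqs)
  expect_equal(alpha_band_psd(sc, "O1", 9.0), 3.5)
  expect_equal(alpha_band_psd(sc, "O1", 12.8), 3.5)
  # identity ramp: symmetric window around 10 averages to 10
  sr <- spectrum_from_psd(freqs, freqs)
  expect_equal(alpha_band_psd(sr, "O1", 10), 10)
  # window follows the IAF beyond the 13 Hz band edge (no clipping):
  # [11.8, 13.8] covers the grid bins 12.00..13.75
  expect_equal(alpha_band_psd(sr, "O1", 12.8), mean(seq(12, 13.75, 0.25)))
  expect_error(alpha_band_psd(sr, "O1", 125), "outside the frequency grid")

  # sinusoid at 10.3 Hz: window mean ~ (A^2/2) / 2 Hz
  fs <- 250
  t <- (seq_len(fs * 160) - 1) / fs
  A <- 3
  ep <- epochs_from_matrix(matrix(A * sin(2 * pi * 10.3 * t), 1), "O1", fs,
                           n_epochs = 8)
  sp <- compute_psd(ep)
  expect_equal(alpha_band_psd(sp, "O1", 10.3), (A^2 / 2) / 2,
               tolerance = 0.1 * (A^2 / 2) / 2)
})

test_that("spectral pipeline is scale-equivariant (k^2 law)", {
  set.seed(19)
  fs <- 250
  X <- matrix(rnorm(fs * 40), 1) + 3 * sin(2 * pi * 10 * (1:(fs * 40)) / fs)
  k <- 7
  ep1 <- epochs_from_matrix(X, "O1", fs, n_epochs = 2)
  ep2 <- epochs_from_matrix(k * X, "O1", fs, n_epochs = 2)
  s1 <- compute_psd(ep1)
  s2 <- compute_psd(ep2)
  expect_equal(s2$psd, k^2 * s1$psd, tolerance = 1e-12)
  d1 <- detect_iaf(s1, "O1"); d2 <- detect_iaf(s2, "O1")
  expect_equal(d1$iaf, d2$iaf)
  expect_equal(alpha_band_psd(s2, "O1", d2$iaf),
               k^2 * alpha_band_psd(s1, "O1", d1$iaf), tolerance = 1e-12)
})

test_that("alpha_band_psd is monotone in the generated alpha amplitude", {
  m <- MONTAGE
  vals <- sapply(c(0.5, 1, 2, 4), function(a) {
    rec <- simulate_subject(subject_spec("m", iaf_true = 10, alpha_amp = a,
                                         artifact_rate = 0),
                            m, 180, 250, seed = 33)
    sp <- compute_psd(screen_epochs(rec))
    alpha_band_psd(sp, "O1", 10)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("subject metrics support per-electrode and occipital-mean IAF modes", {
  rec <- quick_subject("iafmode", seed = 9, iaf_true = 10.3)
  ep <- screen_epochs(bandpass_filter(rec))
  per <- subject_alpha_metrics(ep)
  expect_s3_class(per, "alpha_metrics")
  expect_setequal(per$channel, MONTAGE$name)
  o1 <- per[per$channel == "O1", ]
  expect_identical(o1$peak_quality, "distinct_peak")
  expect_lt(abs(o1$iaf - 10.3), 0.3)

  occ <- subject_alpha_metrics(ep, mode = "occipital_mean")
  o12 <- per$iaf[per$channel %in% c("O1", "O2")]
  expect_true(all(abs(occ$iaf - mean(o12)) < 1e-12))
})
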