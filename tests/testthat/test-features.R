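fs <- 128
tt <- function(n, fs = 128) (seq_len(n) - 1) / fs

test_that("rhythm band-pass passes its band and rejects others", {
  x <- sin(2 * pi * 10 * tt(10 * fs))          # 10 Hz, inside alpha
  bands <- rhythm_bands()
  y_alpha <- bandpass_rhythm(x, fs, bands$alpha)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(y_alpha) - rms(x)) / rms(x), 0.05)
  y_gamma <- bandpass_rhythm(x, fs, bands$gamma)
  expect_lt(rms(y_gamma), 0.05)
  expect_identical(length(y_alpha), length(x))

  expect_error(bandpass_rhythm(x, fs, c(30, 70)), "Nyquist")
  expect_error(bandpass_rhythm(x, fs, c(13, 8)), "low < high")
  expect_error(bandpass_rhythm(x[1:10], fs, bands$alpha), "warm-up")
})

test_that("Hjorth parameters match their definitions", {
  expect_identical(hjorth_parameters(c(5, 5, 5, 5)),
                   c(activity = 0, mobility = 0, complexity = 0))
  expect_error(hjorth_parameters(c(1, 2)), "3 samples")

  # pure sine: activity = A^2/2, complexity ~ 1
  x <- sin(2 * pi * 4 * tt(10 * fs))
  hp <- hjorth_parameters(x)
  expect_lt(abs(hp[["activity"]] - 0.5) / 0.5, 0.01)
  expect_lt(abs(hp[["complexity"]] - 1), 0.01)
  # definition check against direct evaluation on the samples
  expect_equal(hp[["activity"]], mean((x - mean(x))^2))
  v <- function(z) mean((z - mean(z))^2)
  expect_equal(hp[["mobility"]], sqrt(v(diff(x)) / v(x)))
  expect_equal(hp[["complexity"]],
               sqrt(v(diff(diff(x))) / v(diff(x))) / sqrt(v(diff(x)) / v(x)))

  set.seed(7)
  expect_gt(hjorth_parameters(rnorm(10000))[["complexity"]], 1)
})

test_that("standard deviation uses the population convention by default", {
  expect_identical(signal_sd(c(1, 1, 1)), 0)
  expect_identical(signal_sd(c(0, 2)), 1)
  expect_identical(signal_sd(c(0, 2), population = FALSE), sd(c(0, 2)))
  expect_error(signal_sd(1), "2 samples")
  set.seed(11)
  expect_lt(abs(signal_sd(rnorm(1e5)) - 1), 0.01)
})

test_that("Welch band power resolves rhythms and matches its conventions", {
  expect_identical(psd_band_power(rep(0, 1024), fs, c(8, 13)), 0)

  x <- sin(2 * pi * 10 * tt(60 * fs))
  pa <- psd_band_power(x, fs, c(8, 13))
  pt <- psd_band_power(x, fs, c(3, 7))
  expect_gt(pa, 100 * pt)
  # a unit sine carries power 0.5 in one 0.5 Hz bin; the 11-bin alpha mean
  # is 0.5 / 0.5 / 11 (independently computed with scipy.signal.welch)
  expect_equal(pa, 0.0909090909090909, tolerance = 1e-12)

  # 8-s segments give 0.125 Hz spacing: at least 40 bins average over alpha
  est <- stsbssvm:::welch_psd(x, fs, seg_s = 8)
  expect_gte(sum(est$freq >= 8 & est$freq <= 13), 40)

  expect_error(psd_band_power(x[1:100], fs, c(8, 13)), "shorter")
  expect_error(psd_band_power(x, fs, c(10.1, 10.2), seg_s = 0.25), "no PSD bin")
})

test_that("sample entropy equals the brute-force template counter", {
  expect_identical(sample_entropy(rep(3, 50)), 0)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "m \\+ 2")

  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               sampen_bruteforce(x, m = 2, r = 0.5), tolerance = 1e-12)

  set.seed(19)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5) * signal_sd(x)
    expect_equal(sample_entropy(x, m, r), sampen_bruteforce(x, m, r),
                 tolerance = 1e-12)
  }

  # disorder ordering: noise is less predictable than a sine
  set.seed(23)
  noise <- runif(500)
  sine <- sin(2 * pi * 4 * tt(500))
  expect_gt(sample_entropy(noise), sample_entropy(sine))
})

test_that("wavelet entropy follows the Shannon closed forms and bounds", {
  expect_equal(energy_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(energy_entropy(rep(0.2, 5)), log(5), tolerance = 1e-12)
  expect_error(energy_entropy(c(0.7, 0.7)), "sum to 1")

  # frozen cross-check of the db4 periodized decomposition (PyWavelets,
  # wavedec mode='periodization', level=4, on this exact signal)
  i <- 0:511
  x <- sin(2 * pi * 10 * i / fs) + 0.1 * sin(2 * pi * 43 * i / fs)
  p <- wavelet_energy_distribution(x)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, c(0.00143950, 0.12819361, 0.81292455, 0.04781305,
                    0.00962929), tolerance = 1e-6)
  expect_equal(wavelet_entropy(x), 0.63120863240923, tolerance = 1e-10)

  set.seed(29)
  y <- sin(2 * pi * 10 * tt(512)) + 0.05 * rnorm(512)
  we <- wavelet_entropy(y)
  expect_gt(we, 0); expect_lt(we, log(5))

  expect_error(wavelet_entropy(rep(0, 64)), "degenerate")
  expect_equal(wavelet_entropy(rep(0, 64), zero = "uniform"), log(5))
  expect_error(wavelet_entropy(rnorm(8), levels = 4), "too short")
})

test_that("extractors scale as documented under amplitude scaling", {
  set.seed(31)
  for (k in 1:5) {
    x <- rnorm(512) + sin(2 * pi * 9 * tt(512))
    a <- runif(1, 0.5, 5)
    hx <- hjorth_parameters(x); ha <- hjorth_parameters(a * x)
    expect_equal(ha[["activity"]], a^2 * hx[["activity"]])
    expect_equal(ha[["mobility"]], hx[["mobility"]])
    expect_equal(ha[["complexity"]], hx[["complexity"]])
    expect_equal(signal_sd(a * x), a * signal_sd(x))
    expect_equal(wavelet_entropy(a * x), wavelet_entropy(x),
                 tolerance = 1e-10)
    # sample entropy with the relative tolerance rule is scale-invariant
    expect_equal(sample_entropy(a * x), sample_entropy(x), tolerance = 1e-12)
  }
})

test_that("the assembled matrix has channel-by-feature structure", {
  ts <- make_tiny_trialset(n_trials = 1, n_channels = 2, n_samples = 512,
                           ratings = 8)
  fm <- assemble_feature_matrix(ts)
  expect_identical(dim(fm), c(1L, 20L))
  expect_identical(anyDuplicated(colnames(fm$values)), 0L)
  expect_identical(colnames(fm$values)[1:10],
                   paste0("ch01__", c("hjorth_activity", "hjorth_mobility",
                                      "hjorth_complexity", "std", "psd_alpha",
                                      "psd_beta", "psd_gamma", "psd_theta",
                                      "sampen", "we")))

  # row order preserves trial order; columns = channels x 10
  ts4 <- make_tiny_trialset(n_trials = 4, n_channels = 3, n_samples = 512,
                            ratings = c(8, 2, 7, 3))
  fm4 <- assemble_feature_matrix(ts4)
  expect_identical(dim(fm4), c(4L, 30L))
  one <- assemble_feature_matrix(subset_trials_for_test(ts4, 3))
  expect_equal(unname(fm4$values[3, ]), unname(one$values[1, ]))
  expect_identical(fm4$labels, c(1L, 0L, 1L, 0L))
})
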