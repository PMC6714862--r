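test_that("trialset constructor enforces its invariants", {
  ts <- make_tiny_trialset()
  expect_s3_class(ts, "trialset")
  expect_identical(dim(ts), c(4L, 2L, 256L))
  sig <- ts$signals
  expect_error(trialset(sig, fs = -1, rep(1, 4), ratings = rep(5, 4)),
               "positive")
  expect_error(trialset(sig, 128, rep(1, 3), ratings = rep(5, 4)),
               "n_trials")
  expect_error(trialset(sig, 128, rep(1, 4), ratings = rep(5, 4),
                        channel_names = c("Fp1", "Fp1")), "unique")
  expect_error(trialset(sig, 128, rep(1, 4), ratings = rep(5, 4),
                        channel_names = "Fp1"), "length")
  expect_error(trialset(sig, 128, rep(1, 4),
                        ratings = c("positive", "bogus", "negative", "neutral")),
               "unknown categorical")
})

test_that("valence binarization assigns classes by the threshold", {
  lv <- binarize_valence(c(7, 3, 9))
  expect_identical(lv$values, c(1L, 0L, 1L))
  expect_true(all(lv$kept_mask))

  # boundary rating is dropped by default, assignable to negative by flag
  expect_identical(sum(binarize_valence(5)$kept_mask), 0L)
  lv5 <- binarize_valence(5, equal = "negative")
  expect_identical(lv5$values, 0L)

  expect_error(binarize_valence(c(0.5, 7)), "within")
  expect_error(binarize_valence(c(7, 9.5)), "within")
})

test_that("binarization partitions kept trials and balances uniform draws", {
  set.seed(101)
  ratings <- runif(1000, 1, 9)
  lv <- binarize_valence(ratings)
  # every kept trial gets exactly one label, by comparison to the threshold
  expect_identical(length(lv$values), sum(lv$kept_mask))
  expect_identical(lv$values, as.integer(ratings[lv$kept_mask] > 5))
  expect_lt(abs(mean(lv$values) - 0.5), 0.05)
})

test_that("positive/negative selection drops neutral trials", {
  ts <- make_tiny_trialset(n_trials = 15, ratings = rep(
    c("positive", "neutral", "negative"), each = 5))
  out <- select_pos_neg(ts)
  expect_identical(dim(out$trialset)[1L], 10L)
  expect_identical(sum(out$labels$values), 5L)
  expect_identical(out$labels$kept_mask, ts$ratings != "neutral")

  ts_allneutral <- make_tiny_trialset(n_trials = 3,
                                      ratings = rep("neutral", 3))
  expect_error(select_pos_neg(ts_allneutral), "degenerate")
})

test_that("a full 15x3x15 categorical layout keeps 450 trials", {
  desc <- new_descriptor(n_subjects = 15, trials_per_subject_session = 15,
                         n_sessions = 3, n_channels = 2, fs_hz = 64,
                         trial_duration_s = 1, rating_kind = "categorical")
  gen <- generate_trialset(desc, effect_spec(effect_size = 1, seed = 4,
                                             band = "theta"))
  out <- select_pos_neg(gen$trialset)
  expect_identical(dim(out$trialset)[1L], 450L)
})

test_that("middle-window extraction uses the floor/half-open convention", {
  # 240 s at 200 Hz -> 60 s window covers 0-based samples [18000, 30000)
  n <- 48000L
  sig <- array(as.numeric(seq_len(n)), c(1L, 1L, n))
  ts <- trialset(sig, 200, 1L, ratings = 7)
  win <- extract_middle_window(ts, 60)
  expect_identical(dim(win)[3L], 12000L)
  expect_identical(win$signals[1, 1, 1], 18001)     # 1-based value of x[18000]
  expect_identical(win$signals[1, 1, 12000], 30000)

  # trial exactly the window length is unchanged; idempotent once applied
  ts60 <- make_tiny_trialset(n_samples = 256, fs = 128)
  win2 <- extract_middle_window(ts60, 2)
  expect_identical(win2$signals, ts60$signals)
  expect_identical(extract_middle_window(win, 60)$signals, win$signals)

  expect_error(extract_middle_window(make_tiny_trialset(n_samples = 128), 2),
               "exceeds")
})

test_that("layout descriptors carry the published counts", {
  d <- deap_descriptor()
  expect_identical(c(d$n_subjects, d$trials_per_subject_session, d$n_sessions,
                     d$n_channels), c(32L, 40L, 1L, 32L))
  expect_identical(c(d$fs_hz, d$trial_duration_s), c(128, 60))
  expect_identical(d$rating_kind, "continuous_valence")
  s <- seed_descriptor()
  expect_identical(c(s$n_subjects, s$trials_per_subject_session, s$n_sessions,
                     s$n_channels), c(15L, 15L, 3L, 62L))
  expect_identical(c(s$fs_hz, s$trial_duration_s), c(200, 240))
  expect_identical(s$rating_kind, "categorical")
  expect_error(new_descriptor(0, 1, 1, 1, 100, 10), ">= 1")
})
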