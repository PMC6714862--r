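small_desc <- function(duration = 4, subjects = 4, trials = 10, channels = 3,
                       kind = "continuous_valence") {
  new_descriptor(n_subjects = subjects, trials_per_subject_session = trials,
                 n_sessions = 1, n_channels = channels, fs_hz = 128,
                 trial_duration_s = duration, rating_kind = kind)
}

test_that("generated layouts have the descriptor-implied shape", {
  gen <- generate_trialset(small_desc(), effect_spec(seed = 171))
  expect_identical(dim(gen$trialset), c(40L, 3L, 512L))
  expect_identical(length(gen$labels), 40L)
  expect_true(all(gen$trialset$ratings[gen$labels == 1L] > 5))
  expect_true(all(gen$trialset$ratings[gen$labels == 0L] < 5))

  # categorical mode: 5/5/5 per session, ground truth NA for neutral
  desc <- new_descriptor(3, 15, 2, 2, 128, 2, rating_kind = "categorical")
  genc <- generate_trialset(desc, effect_spec(seed = 173))
  expect_identical(dim(genc$trialset)[1L], 90L)
  tab <- table(genc$trialset$ratings[1:15])
  expect_identical(as.integer(tab[c("positive", "neutral", "negative")]),
                   rep(5L, 3))
  expect_identical(sum(is.na(genc$labels)), 30L)
})

test_that("generation is bit-reproducible under a fixed seed", {
  eff <- effect_spec(discriminative_channels = 1:2, effect_size = 2,
                     seed = 179)
  g1 <- generate_trialset(small_desc(duration = 2), eff)
  g2 <- generate_trialset(small_desc(duration = 2), eff)
  expect_identical(g1$trialset$signals, g2$trialset$signals)
  expect_identical(g1$labels, g2$labels)

  t1 <- generate_feature_table(3, 6, 10, 2, 1, seed = 181)
  t2 <- generate_feature_table(3, 6, 10, 2, 1, seed = 181)
  expect_identical(t1$values, t2$values)
  # and the generator restores the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(generate_feature_table(2, 4, 3, 0, 0, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("the spectral background follows a decreasing 1/f trend", {
  eff <- effect_spec(effect_size = 1, noise_exponent = 1.5,
                     noise_scale = 1, seed = 191)
  gen <- generate_trialset(small_desc(duration = 8, subjects = 2, trials = 2,
                                      channels = 1), eff)
  x <- gen$trialset$signals[1, 1, ]
  lowp <- psd_band_power(x, 128, c(1, 2))
  highp <- psd_band_power(x, 128, c(50, 60))
  expect_gt(lowp, 5 * highp)
})

test_that("effect specification validates its fields", {
  expect_error(effect_spec(effect_size = 0.5), ">= 1")
  expect_error(effect_spec(subject_sd = -1), ">= 0")
  expect_error(effect_spec(integer(0), effect_size = 2), "non-empty")
  expect_error(effect_spec(band = "delta"), "band must be")
  expect_error(generate_trialset(small_desc(), effect_spec(
    discriminative_channels = 99, seed = 1)), "out of range")
})

test_that("tabular generator plants recoverable class structure", {
  # null: retention near alpha
  null_fm <- generate_feature_table(6, 20, 400, 0, 0, subject_sd = 0,
                                    seed = 193)
  sel0 <- significance_filter(null_fm$values, null_fm$labels, test = "t_test")
  expect_lt(sel0$retained_count / 400, 0.12)

  # strong effect: all informative columns retained
  fm <- generate_feature_table(6, 20, 50, 5, delta = 2, seed = 197)
  sel <- significance_filter(fm$values, fm$labels, test = "t_test")
  expect_true(all(attr(fm, "informative") %in%
                  sel$table$name[sel$table$h == 1L]))
})

test_that("LOSO accuracy does not decrease with the planted effect size", {
  accs <- vapply(c(1, 2, 3), function(es) {
    eff <- effect_spec(discriminative_channels = 1:2, band = "alpha",
                       effect_size = es, subject_sd = 0.1, seed = 199)
    gen <- generate_trialset(small_desc(duration = 4, subjects = 4,
                                        trials = 12, channels = 3), eff)
    fm <- assemble_feature_matrix(gen$trialset)
    loso_evaluate(fm, "svm")$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})
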