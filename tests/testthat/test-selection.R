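test_that("class splitting partitions the rows", {
  m <- matrix(rnorm(60), 6, 10)
  parts <- split_by_label(m, c(1, 0, 1, 0, 1, 0))
  expect_identical(nrow(parts$pos), 3L)
  expect_identical(nrow(parts$neg), 3L)
  expect_equal(rbind(parts$pos, parts$neg)[order(c(1, 3, 5, 2, 4, 6)), ], m)
  expect_error(split_by_label(m, rep(1, 6)), "degenerate")

  fm <- generate_feature_table(8, 20, 5, 0, 0, seed = 2)
  parts2 <- split_by_label(fm$values, fm$labels)
  expect_identical(nrow(parts2$pos) + nrow(parts2$neg), nrow(fm$values))
  expect_identical(nrow(parts2$pos), 80L)   # labels balanced within subject
})

test_that("the normality vote picks t for Gaussian, KS for skewed columns", {
  set.seed(41)
  n <- 200
  labels <- rep(c(1L, 0L), each = n)
  gauss <- matrix(rnorm(2 * n * 50), 2 * n, 50)
  expect_identical(normality_decision(gauss, labels), "t_test")
  skewed <- matrix(rexp(2 * n * 50), 2 * n, 50)
  expect_identical(normality_decision(skewed, labels), "ks_test")

  # an exact 50% pass rate goes to the nonparametric branch:
  # two columns normal in both halves, two exponential in both halves
  set.seed(43)
  half <- cbind(matrix(rnorm(2 * n * 2), 2 * n, 2),
                matrix(rexp(2 * n * 2), 2 * n, 2))
  expect_identical(normality_decision(half, labels), "ks_test")

  expect_error(normality_decision(gauss[1:4, , drop = FALSE],
                                  c(1L, 1L, 0L, 0L)), "at least 3")
})

test_that("the significance filter keeps null retention near alpha", {
  fm <- generate_feature_table(n_subjects = 10, n_trials = 20,
                               n_features = 2000, n_informative = 0,
                               delta = 0, subject_sd = 0, seed = 47)
  sel <- significance_filter(fm$values, fm$labels, alpha = 0.05,
                             test = "t_test")
  # 99% binomial band around 0.05 at 2000 columns
  band <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(sel$retained_count, band[1])
  expect_lte(sel$retained_count, band[2])
  expect_identical(sel$retained_count, sum(sel$table$h))
  expect_identical(ncol(sel$filtered), sel$retained_count)
  expect_identical(sel$table$h, as.integer(sel$table$p_value < 0.05))
})

test_that("a huge class effect is always retained", {
  set.seed(53)
  n <- 100
  labels <- rep(c(1L, 0L), each = n)
  m <- matrix(rnorm(2 * n * 21), 2 * n, 21)
  m[labels == 1L, 1] <- m[labels == 1L, 1] + 2
  colnames(m) <- sprintf("c%02d", 1:21)
  sel <- significance_filter(m, labels, test = "t_test")
  expect_true("c01" %in% sel$table$name[sel$table$h == 1L])
  # retained columns keep their original order
  kept <- sel$table$name[sel$table$h == 1L]
  expect_identical(colnames(sel$filtered), kept)
  expect_false(is.unsorted(match(kept, colnames(m))))
})

test_that("filter retention is invariant to row permutation", {
  fm <- generate_feature_table(6, 10, 40, 5, delta = 1.5, seed = 59)
  sel <- significance_filter(fm$values, fm$labels, test = "t_test")
  set.seed(61); perm <- sample(nrow(fm$values))
  sel_p <- significance_filter(fm$values[perm, ], fm$labels[perm],
                               test = "t_test")
  expect_identical(sel$retained_mask, sel_p$retained_mask)
  expect_equal(sel$table$p_value, sel_p$table$p_value)
})

test_that("an empty selection raises rather than returning nothing", {
  fm <- generate_feature_table(4, 10, 10, 0, 0, subject_sd = 0, seed = 67)
  expect_error(significance_filter(fm$values, fm$labels, alpha = 1e-12,
                                   test = "t_test"), "empty selection")
})

test_that("selection results serialize to JSON + CSV", {
  fm <- generate_feature_table(4, 10, 12, 3, delta = 2, seed = 71)
  sel <- significance_filter(fm$values, fm$labels, test = "t_test")
  path <- file.path(withr::local_tempdir(), "sel.json")
  save_selection_result(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$retained_count, sel$retained_count)
  expect_true(file.exists(sub("\\.json$", "_filtered.csv", path)))
})
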