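# Shared fixtures and independent oracles, built in code at test time.

# Small trialset with deterministic sinusoid-plus-noise signals.
make_tiny_trialset <- function(n_trials = 4, n_channels = 2, n_samples = 256,
                               fs = 128, ratings = NULL, seed = 42) {
  set.seed(seed)
  signals <- array(rnorm(n_trials * n_channels * n_samples, sd = 0.3),
                   c(n_trials, n_channels, n_samples))
  tt <- (seq_len(n_samples) - 1) / fs
  for (i in seq_len(n_trials))
    for (ch in seq_len(n_channels))
      signals[i, ch, ] <- signals[i, ch, ] + sin(2 * pi * (8 + i) * tt)
  if (is.null(ratings)) ratings <- seq(2, 8, length.out = n_trials)
  trialset(signals, fs, subject_id = rep(1L, n_trials), ratings = ratings)
}

# Independent O(n^2 * m) brute-force sample-entropy oracle: enumerates every
# template pair explicitly (same Richman-Moorman convention and caps).
sampen_bruteforce <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L) return(2 * log(n))
  if (A == 0L) return(log(B) + log(n))
  -log(A / B)
}

# Minimal EDF writer used to produce a known file for the reader test.
# Follows the EDF layout directly: 256-byte fixed header, 256 bytes per
# signal of field blocks, then 16-bit little-endian data records.
write_edf_fixture <- function(path, signals, fs, phys_min = -100,
                              phys_max = 100, labels = NULL,
                              patient = "test subject") {
  ns <- nrow(signals); n <- ncol(signals)
  stopifnot(n %% fs == 0)
  n_records <- n / fs          # 1-s records
  if (is.null(labels)) labels <- sprintf("EEG %d", seq_len(ns))
  pad <- function(x, w) formatC(as.character(x), width = -w)
  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(patient, 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("AgAgCl", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((signals - phys_min) / (phys_max - phys_min) * 65535 - 32768)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns))
      writeBin(as.integer(dig[s, idx]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# Cheap SBS evaluator for contract tests: accuracy of a 1-nearest-centroid
# rule, deterministic and fast.
centroid_evaluator <- function(values, labels) {
  mu1 <- colMeans(values[labels == 1L, , drop = FALSE])
  mu0 <- colMeans(values[labels == 0L, , drop = FALSE])
  d1 <- sweep(values, 2, mu1); d0 <- sweep(values, 2, mu0)
  pred <- as.integer(rowSums(d1^2) < rowSums(d0^2))
  mean(pred == labels)
}

subset_trials_for_test <- function(ts, idx) stsbssvm:::subset_trials(ts, idx)
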