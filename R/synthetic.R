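#' Class-effect specification for the synthetic EEG generator
#'
#' Describes where and how strongly the emotion class is encoded in the
#' generated signals: which channels are discriminative, which rhythm
#' carries the effect, the positive-class amplitude multiplier for that
#' rhythm, the spread of persistent per-subject amplitude offsets, and the
#' slope of the 1/f^beta background noise.
#'
#' @param discriminative_channels channel indices carrying the class effect.
#' @param band rhythm carrying the effect (default `"alpha"`).
#' @param effect_size band-amplitude multiplier for positive trials on the
#'   discriminative channels; 1 means no class information.
#' @param subject_sd standard deviation of the per-subject amplitude gain
#'   offset (gain = 1 + N(0, subject_sd), floored at 0.2).
#' @param noise_exponent beta of the 1/f^beta background (default 1).
#' @param noise_scale standard deviation of the background noise (default 1,
#'   same scale as the unit-amplitude band oscillators).
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(discriminative_channels = 1L, band = "alpha",
                        effect_size = 2, subject_sd = 0.1,
                        noise_exponent = 1, noise_scale = 1, seed = 1L) {
  if (effect_size < 1) stop("effect_size must be >= 1")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (effect_size > 1 && !length(discriminative_channels))
    stop("discriminative_channels must be non-empty when effect_size > 1")
  if (!band %in% names(rhythm_bands()))
    stop("band must be one of: ", paste(names(rhythm_bands()), collapse = ", "))
  structure(list(discriminative_channels = as.integer(discriminative_channels),
                 band = band, effect_size = effect_size,
                 subject_sd = subject_sd, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "effect_spec")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 1/f^beta noise via spectral shaping of white Gaussian noise; returned with
# standard deviation `scale`.
colored_noise <- function(n, beta, scale = 1) {
  if (beta == 0 || scale == 0) return(stats::rnorm(n, sd = scale))
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # symmetric frequency index, keeps conjugacy
  f[1L] <- 1                   # DC: no divergence
  shaped <- Re(stats::fft(sp * f^(-beta / 2), inverse = TRUE)) / n
  s <- stats::sd(shaped)
  if (s == 0) return(rep(0, n))
  shaped / s * scale
}

#' Generate a synthetic multichannel EEG trial set
#'
#' Each trial and channel is the sum of a 1/f^beta background and one
#' unit-amplitude sinusoidal oscillator per rhythm (random frequency inside
#' the band, random phase).  Positive-class trials multiply the chosen
#' rhythm's amplitude by `effect_size` on the discriminative channels; every
#' subject carries a persistent multiplicative amplitude gain
#' `1 + N(0, subject_sd)`.  Continuous-valence layouts emit class-consistent
#' ratings (positive trials Uniform(6, 9), negative Uniform(1, 4), avoiding
#' the class boundary at 5); categorical layouts emit 5 positive, 5 neutral
#' and 5 negative trials per session in that order.
#'
#' @param descriptor a `dataset_descriptor`, see [deap_descriptor()].
#' @param effect an [effect_spec].
#' @return list with `trialset`, `labels` (ground-truth 0/1 per trial, `NA`
#'   for neutral trials), and `planted` (column names of the effect-band
#'   power features on the discriminative channels).
#' @export
generate_trialset <- function(descriptor, effect = effect_spec()) {
  stopifnot(inherits(descriptor, "dataset_descriptor"),
            inherits(effect, "effect_spec"))
  fs <- descriptor$fs_hz
  n <- as.integer(round(descriptor$trial_duration_s * fs))
  nc <- descriptor$n_channels
  bands <- rhythm_bands()
  if (bands[[effect$band]][2L] >= fs / 2)
    stop("effect band exceeds Nyquist at fs = ", fs)
  usable <- Filter(function(b) b[2L] < fs / 2, bands)
  bad_ch <- setdiff(effect$discriminative_channels, seq_len(nc))
  if (length(bad_ch)) stop("discriminative channel out of range")
  nt_ss <- descriptor$trials_per_subject_session
  total <- descriptor$n_subjects * descriptor$n_sessions * nt_ss
  categorical <- descriptor$rating_kind == "categorical"
  if (categorical && nt_ss %% 3L != 0L)
    stop("categorical layouts need trials_per_subject_session divisible by 3")
  with_seed(effect$seed, {
    gains <- pmax(0.2, 1 + stats::rnorm(descriptor$n_subjects,
                                        sd = effect$subject_sd))
    signals <- array(NA_real_, c(total, nc, n))
    subject_id <- integer(total); session_id <- integer(total)
    labels <- integer(total)
    ratings <- if (categorical) character(total) else numeric(total)
    tt <- (seq_len(n) - 1L) / fs
    row <- 0L
    for (s in seq_len(descriptor$n_subjects)) {
      for (sess in seq_len(descriptor$n_sessions)) {
        if (categorical) {
          per <- nt_ss %/% 3L
          cls <- rep(c("positive", "neutral", "negative"), each = per)
        } else {
          cls <- rep(c(1L, 0L), length.out = nt_ss)
          cls <- sample(cls)   # shuffle within subject-session
        }
        for (k in seq_len(nt_ss)) {
          row <- row + 1L
          subject_id[row] <- s; session_id[row] <- sess
          if (categorical) {
            ratings[row] <- cls[k]
            labels[row] <- switch(cls[k], positive = 1L, negative = 0L,
                                  NA_integer_)
          } else {
            labels[row] <- cls[k]
            ratings[row] <- if (cls[k] == 1L) stats::runif(1, 6, 9)
                            else stats::runif(1, 1, 4)
          }
          positive <- identical(labels[row], 1L)
          for (ch in seq_len(nc)) {
            x <- colored_noise(n, effect$noise_exponent, effect$noise_scale)
            for (bn in names(usable)) {
              b <- usable[[bn]]
              fb <- stats::runif(1, b[1L], b[2L])
              ph <- stats::runif(1, 0, 2 * pi)
              amp <- 1
              if (positive && bn == effect$band &&
                  ch %in% effect$discriminative_channels)
                amp <- effect$effect_size
              x <- x + amp * sin(2 * pi * fb * tt + ph)
            }
            signals[row, ch, ] <- gains[s] * x
          }
        }
      }
    }
    ts <- trialset(signals, fs, subject_id, session_id, ratings)
    planted <- paste0(ts$channel_names[effect$discriminative_channels],
                      "__psd_", effect$band)
    list(trialset = ts, labels = labels, planted = planted)
  })
}

#' Generate a tabular feature matrix directly
#'
#' Fast generator that bypasses the signal level: feature values are
#' standard normal draws, the first `n_informative` columns are mean-shifted
#' by `delta` between the classes (+delta/2 for positive rows, -delta/2 for
#' negative), and each subject adds a persistent N(0, subject_sd) intercept
#' per column.  Labels are balanced within each subject.  Used for fast
#' selection and classification tests.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject (even numbers give exact balance).
#' @param n_features total feature columns.
#' @param n_informative number of class-informative columns (first columns).
#' @param delta between-class mean shift of the informative columns.
#' @param subject_sd spread of per-subject, per-column intercepts.
#' @param seed RNG seed.
#' @return a [feature_matrix]; the informative column names are in
#'   `attr(, "informative")`.
#' @export
generate_feature_table <- function(n_subjects, n_trials, n_features,
                                   n_informative, delta, subject_sd = 0.5,
                                   seed = 1L) {
  if (n_informative > n_features)
    stop("n_informative must be <= n_features")
  if (n_subjects < 1 || n_trials < 2) stop("need >= 1 subject, >= 2 trials")
  with_seed(seed, {
    n <- n_subjects * n_trials
    values <- matrix(stats::rnorm(n * n_features), n, n_features)
    colnames(values) <- sprintf("f%03d", seq_len(n_features))
    subject_id <- rep(seq_len(n_subjects), each = n_trials)
    labels <- as.vector(vapply(seq_len(n_subjects),
                               function(s) sample(rep(c(1L, 0L),
                                                      length.out = n_trials)),
                               integer(n_trials)))
    if (n_informative > 0) {
      shift <- ifelse(labels == 1L, delta / 2, -delta / 2)
      values[, seq_len(n_informative)] <-
        values[, seq_len(n_informative), drop = FALSE] + shift
    }
    if (subject_sd > 0) {
      icpt <- matrix(stats::rnorm(n_subjects * n_features, sd = subject_sd),
                     n_subjects, n_features)
      values <- values + icpt[subject_id, , drop = FALSE]
    }
    fm <- feature_matrix(values, labels, subject_id)
    attr(fm, "informative") <- colnames(values)[seq_len(n_informative)]
    fm
  })
}
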