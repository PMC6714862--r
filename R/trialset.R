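#' Multichannel EEG trial container
#'
#' A `trialset` bundles a dense `n_trials x n_channels x n_samples` signal
#' array (microvolt-scale) with its sampling rate and per-trial metadata:
#' subject, session, and either a continuous 1-9 valence rating or a
#' categorical emotion label (`"positive"`, `"neutral"`, `"negative"`).
#'
#' @param signals numeric 3-D array, `n_trials x n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param subject_id per-trial subject identifier (length `n_trials`).
#' @param session_id per-trial session identifier; defaults to 1 for
#'   single-session recordings.
#' @param ratings per-trial continuous valence score in `[1, 9]`, or a
#'   character/factor vector of categorical labels.
#' @param channel_names ordered channel labels; defaults to `ch01`, `ch02`, ...
#'
#' @return an object of class `trialset`.
#' @export
trialset <- function(signals, fs, subject_id, session_id = NULL, ratings,
                     channel_names = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stop("`signals` must be a 3-D array (trials x channels x samples)")
  d <- dim(signals)
  n_trials <- d[1L]; n_channels <- d[2L]
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(session_id)) session_id <- rep(1L, n_trials)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(n_channels))
  if (length(subject_id) != n_trials || length(session_id) != n_trials ||
      length(ratings) != n_trials)
    stop("subject_id, session_id and ratings must all have length n_trials = ",
         n_trials)
  if (length(channel_names) != n_channels)
    stop("channel_names must have length n_channels = ", n_channels)
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (is.factor(ratings)) ratings <- as.character(ratings)
  if (is.character(ratings)) {
    bad <- setdiff(unique(ratings), c("positive", "neutral", "negative"))
    if (length(bad))
      stop("unknown categorical labels: ", paste(bad, collapse = ", "))
  } else if (!is.numeric(ratings)) {
    stop("`ratings` must be numeric (continuous valence) or character/factor")
  }
  structure(
    list(signals = signals, fs = fs,
         subject_id = subject_id, session_id = session_id,
         ratings = ratings, channel_names = channel_names),
    class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$signals)
  kind <- if (is.character(x$ratings)) "categorical" else "continuous valence"
  cat(sprintf(paste0(
    "trialset: %d trials x %d channels x %d samples @ %g Hz (%.1f s)\n",
    "  subjects: %d  sessions: %d  ratings: %s\n"),
    d[1], d[2], d[3], x$fs, d[3] / x$fs,
    length(unique(x$subject_id)), length(unique(x$session_id)), kind))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$signals)

n_trials <- function(ts) dim(ts$signals)[1L]

# Row-subset a trialset (trials only), keeping metadata aligned.
subset_trials <- function(ts, idx) {
  trialset(ts$signals[idx, , , drop = FALSE], ts$fs,
           ts$subject_id[idx], ts$session_id[idx], ts$ratings[idx],
           ts$channel_names)
}

#' Dataset layout descriptors
#'
#' Compact descriptions of the two benchmark layouts the pipeline emulates:
#' a 32-subject layout with 40 one-minute trials per subject at 128 Hz over
#' 32 channels with continuous 1-9 valence ratings, and a 15-subject,
#' 3-session layout with 15 four-minute trials per session at 200 Hz over
#' 62 channels labelled positive/neutral/negative (5 each per session).
#' `trial_duration_s` may be overridden for reduced-duration runs; all other
#' counts are fixed by the layout.
#'
#' @param trial_duration_s trial length in seconds.
#' @return an object of class `dataset_descriptor`.
#' @export
deap_descriptor <- function(trial_duration_s = 60) {
  new_descriptor(n_subjects = 32L, trials_per_subject_session = 40L,
                 n_sessions = 1L, n_channels = 32L, fs_hz = 128,
                 trial_duration_s = trial_duration_s,
                 rating_kind = "continuous_valence", name = "deap")
}

#' @rdname deap_descriptor
#' @export
seed_descriptor <- function(trial_duration_s = 240) {
  new_descriptor(n_subjects = 15L, trials_per_subject_session = 15L,
                 n_sessions = 3L, n_channels = 62L, fs_hz = 200,
                 trial_duration_s = trial_duration_s,
                 rating_kind = "categorical", name = "seed")
}

#' @rdname deap_descriptor
#' @param n_subjects,trials_per_subject_session,n_sessions,n_channels counts
#'   (all at least 1).
#' @param fs_hz sampling rate in Hz.
#' @param rating_kind `"continuous_valence"` or `"categorical"`.
#' @param name optional layout tag.
#' @export
new_descriptor <- function(n_subjects, trials_per_subject_session, n_sessions,
                           n_channels, fs_hz, trial_duration_s,
                           rating_kind = c("continuous_valence", "categorical"),
                           name = "custom") {
  rating_kind <- match.arg(rating_kind)
  counts <- c(n_subjects = n_subjects,
              trials_per_subject_session = trials_per_subject_session,
              n_sessions = n_sessions, n_channels = n_channels)
  if (any(counts < 1)) stop("all descriptor counts must be >= 1")
  if (fs_hz <= 0 || trial_duration_s <= 0)
    stop("fs_hz and trial_duration_s must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject_session = as.integer(trials_per_subject_session),
                 n_sessions = as.integer(n_sessions),
                 n_channels = as.integer(n_channels),
                 fs_hz = fs_hz, trial_duration_s = trial_duration_s,
                 rating_kind = rating_kind, name = name),
            class = "dataset_descriptor")
}

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat(sprintf(paste0("dataset_descriptor '%s': %d subjects x %d sessions x ",
                     "%d trials, %d channels @ %g Hz, %g s trials, %s ratings\n"),
              x$name, x$n_subjects, x$n_sessions, x$trials_per_subject_session,
              x$n_channels, x$fs_hz, x$trial_duration_s, x$rating_kind))
  invisible(x)
}

#' Binarize continuous valence ratings
#'
#' Ratings above `threshold` become 1 (positive emotion), ratings below it
#' become 0 (negative emotion).  A rating exactly at the threshold belongs to
#' neither stated class; by default such trials are dropped from `kept_mask`
#' (`equal = "drop"`), or they may be assigned to the negative class
#' (`equal = "negative"`).
#'
#' @param ratings numeric vector of valence scores in `[1, 9]`.
#' @param threshold class boundary, default 5.
#' @param equal treatment of ratings exactly equal to the threshold.
#' @return an object of class `label_vector`: `values` (0/1 for kept trials)
#'   and `kept_mask` (logical over the original trials).
#' @export
binarize_valence <- function(ratings, threshold = 5,
                             equal = c("drop", "negative")) {
  equal <- match.arg(equal)
  if (!is.numeric(ratings)) stop("`ratings` must be numeric")
  if (any(!is.finite(ratings)) || any(ratings < 1 | ratings > 9))
    stop("ratings must lie within [1, 9]")
  kept <- if (equal == "drop") ratings != threshold else rep(TRUE, length(ratings))
  values <- as.integer(ratings[kept] > threshold)
  label_vector(values, kept)
}

label_vector <- function(values, kept_mask) {
  stopifnot(all(values %in% c(0L, 1L)), sum(kept_mask) == length(values))
  structure(list(values = as.integer(values), kept_mask = kept_mask),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label_vector: %d kept of %d trials (%d positive, %d negative)\n",
              length(x$values), length(x$kept_mask),
              sum(x$values == 1L), sum(x$values == 0L)))
  invisible(x)
}

#' Keep only positive- and negative-labelled trials
#'
#' For categorically labelled recordings, drops neutral trials and returns the
#' reduced trial set together with 1/0 labels (positive/negative).
#'
#' @param ts a [trialset] with categorical ratings.
#' @return list with elements `trialset` and `labels` (a `label_vector` over
#'   the original trials).
#' @export
select_pos_neg <- function(ts) {
  stopifnot(inherits(ts, "trialset"))
  if (!is.character(ts$ratings))
    stop("select_pos_neg() needs categorical ratings")
  kept <- ts$ratings %in% c("positive", "negative")
  values <- as.integer(ts$ratings[kept] == "positive")
  if (!any(values == 1L) || !any(values == 0L))
    stop("degenerate classes: need at least one positive and one negative trial")
  list(trialset = subset_trials(ts, which(kept)),
       labels = label_vector(values, kept))
}

#' Crop every trial to a centered time window
#'
#' Extracts `window_s` seconds from the middle of each trial.  The window is
#' half-open `[start, start + window_s * fs)` in 0-based sample coordinates
#' with `start = floor((n_samples - window_s * fs) / 2)`.
#'
#' @param ts a [trialset].
#' @param window_s window length in seconds (default 60).
#' @return a [trialset] with `window_s * fs` samples per trial.
#' @export
extract_middle_window <- function(ts, window_s = 60) {
  stopifnot(inherits(ts, "trialset"))
  n_samples <- dim(ts$signals)[3L]
  len <- as.integer(round(window_s * ts$fs))
  if (len > n_samples)
    stop(sprintf("window of %g s (%d samples) exceeds trial length (%d samples)",
                 window_s, len, n_samples))
  start <- (n_samples - len) %/% 2L            # 0-based
  idx <- seq.int(start + 1L, start + len)      # 1-based slice
  trialset(ts$signals[, , idx, drop = FALSE], ts$fs, ts$subject_id,
           ts$session_id, ts$ratings, ts$channel_names)
}
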