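#' Trial-by-feature matrix container
#'
#' Holds the `trials x (channels x feature types)` value matrix together with
#' per-row labels (1 positive / 0 negative), subject and session identifiers.
#' Column names are `"<channel>__<feature>"`.
#'
#' @param values numeric matrix with unique column names and no NaN/Inf.
#' @param labels integer 0/1 vector, one per row.
#' @param subject_id per-row subject identifier.
#' @param session_id per-row session identifier (default all 1).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_id, session_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` needs unique column names")
  if (any(!is.finite(values)))
    stop("feature matrix contains non-finite values")
  n <- nrow(values)
  if (length(labels) != n || length(subject_id) != n)
    stop("labels and subject_id must match the row count")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(session_id)) session_id <- rep(1L, n)
  structure(list(values = values, labels = as.integer(labels),
                 subject_id = subject_id, session_id = session_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(paste0("feature_matrix: %d trials x %d features ",
                     "(%d positive / %d negative, %d subjects)\n"),
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 0L),
              length(unique(x$subject_id))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Row subset keeping metadata aligned.
fm_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$labels[idx],
                 fm$subject_id[idx], fm$session_id[idx])
}

# Ordered feature-type names; PSD features follow the rhythm order
# alpha, beta, gamma, theta after the four time-domain descriptors.
feature_type_names <- function() {
  c("hjorth_activity", "hjorth_mobility", "hjorth_complexity", "std",
    "psd_alpha", "psd_beta", "psd_gamma", "psd_theta", "sampen", "we")
}

#' Extract the ten-feature matrix from a trial set
#'
#' For every trial and channel, computes the ten descriptors in canonical
#' order: Hjorth activity, mobility, complexity, standard deviation,
#' PSD-alpha, PSD-beta, PSD-gamma, PSD-theta, sample entropy and wavelet
#' entropy.  The four band powers are measured on the corresponding
#' band-pass-filtered signal (4th-order zero-phase Butterworth) averaged over
#' that rhythm's frequency bins; all other features use the broadband signal
#' as stored.  One row per trial; columns are grouped by channel, ten per
#' channel, named `"<channel>__<feature>"`.
#'
#' @param ts a [trialset].
#' @param labels optional `label_vector` or plain 0/1 vector aligned with the
#'   trials of `ts`.  When a `label_vector` with a partial `kept_mask` is
#'   given, only the kept trials are extracted.
#' @param bands rhythm bands, see [rhythm_bands()].
#' @param config list of extractor settings: `filter_order`, `welch_seg_s`,
#'   `welch_overlap`, `sampen_m`, `sampen_r_factor`, `wavelet_levels`,
#'   `wavelet_family`.
#' @return a [feature_matrix] with `n_channels * 10` columns.
#' @export
assemble_feature_matrix <- function(ts, labels = NULL, bands = rhythm_bands(),
                                    config = list()) {
  stopifnot(inherits(ts, "trialset"))
  cfg <- utils::modifyList(
    list(filter_order = 4, welch_seg_s = 2, welch_overlap = 0.5,
         sampen_m = 2, sampen_r_factor = 0.2,
         wavelet_levels = 4, wavelet_family = "db4"),
    config)
  if (inherits(labels, "label_vector")) {
    if (length(labels$kept_mask) != n_trials(ts))
      stop("label_vector kept_mask does not match the trial count")
    ts <- subset_trials(ts, which(labels$kept_mask))
    lab <- labels$values
  } else if (!is.null(labels)) {
    if (length(labels) != n_trials(ts))
      stop("labels must match the trial count")
    lab <- as.integer(labels)
  } else if (is.character(ts$ratings)) {
    stop("categorical trial sets need explicit labels; see select_pos_neg()")
  } else {
    lab <- binarize_valence(ts$ratings)
    if (!all(lab$kept_mask))
      stop("ratings at the class boundary present; binarize explicitly first")
    lab <- lab$values
  }
  d <- dim(ts$signals)
  nt <- d[1L]; nc <- d[2L]
  ftypes <- feature_type_names()
  nf <- length(ftypes)
  cn <- as.vector(t(outer(ts$channel_names, ftypes, paste, sep = "__")))
  values <- matrix(NA_real_, nt, nc * nf, dimnames = list(NULL, cn))
  band_order <- c("alpha", "beta", "gamma", "theta")
  missing_b <- setdiff(band_order, names(bands))
  if (length(missing_b))
    stop("bands must name: ", paste(band_order, collapse = ", "))
  for (i in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      x <- ts$signals[i, ch, ]
      hp <- hjorth_parameters(x)
      psd <- vapply(band_order, function(b) {
        xb <- bandpass_rhythm(x, ts$fs, bands[[b]], order = cfg$filter_order)
        psd_band_power(xb, ts$fs, bands[[b]],
                       seg_s = cfg$welch_seg_s, overlap = cfg$welch_overlap)
      }, numeric(1))
      feats <- c(hp, signal_sd(x), psd,
                 sample_entropy(x, m = cfg$sampen_m,
                                r = cfg$sampen_r_factor * signal_sd(x)),
                 wavelet_entropy(x, levels = cfg$wavelet_levels,
                                 family = cfg$wavelet_family,
                                 zero = "uniform"))
      if (any(!is.finite(feats)))
        stop(sprintf("non-finite feature for trial %d, channel %s: %s",
                     i, ts$channel_names[ch],
                     paste(ftypes[!is.finite(feats)], collapse = ", ")))
      values[i, ((ch - 1L) * nf + 1L):(ch * nf)] <- feats
    }
  }
  feature_matrix(values, lab, ts$subject_id, ts$session_id)
}
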