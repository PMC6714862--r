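#' Read and write the on-disk trial container
#'
#' The container is a directory holding one CSV per trial
#' (`trial_0001.csv`, ..., channels as columns with a header row of channel
#' names) plus a `metadata.json` sidecar carrying the sampling rate and the
#' per-trial subject, session and rating vectors.  `save_trialset()` /
#' `load_trialset()` round-trip a [trialset] through this layout; signals are
#' written at full double precision so the round-trip is bit-exact.
#'
#' @param ts a [trialset].
#' @param path container directory.
#' @param format input format: `"csv-dir"` (the container) or `"edf"`
#'   (a single EDF recording read as one trial, see [read_edf()]).
#' @return `load_trialset()` returns a [trialset]; `save_trialset()` returns
#'   `path` invisibly.
#' @export
save_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ts$signals)
  meta <- list(fs = ts$fs, n_trials = d[1L], n_channels = d[2L],
               n_samples = d[3L], subject_id = ts$subject_id,
               session_id = ts$session_id, ratings = ts$ratings,
               rating_kind = if (is.character(ts$ratings)) "categorical"
                             else "continuous_valence",
               channel_names = ts$channel_names)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(d[1L])) {
    m <- t(ts$signals[i, , , drop = TRUE])   # samples x channels
    if (d[2L] == 1L) m <- matrix(m, ncol = 1L)
    colnames(m) <- ts$channel_names
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, sprintf("trial_%04d.csv", i)),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname save_trialset
#' @export
load_trialset <- function(path, format = c("csv-dir", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  if (!dir.exists(path)) stop("container directory not found: ", path)
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("container is missing metadata.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("fs", "n_trials", "n_channels", "n_samples", "subject_id",
            "session_id", "ratings", "channel_names")
  missing_f <- setdiff(need, names(meta))
  if (length(missing_f))
    stop("metadata.json is missing fields: ", paste(missing_f, collapse = ", "))
  files <- file.path(path, sprintf("trial_%04d.csv", seq_len(meta$n_trials)))
  if (!all(file.exists(files)))
    stop("container is missing trial files")
  signals <- array(NA_real_,
                   c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (i in seq_along(files)) {
    m <- as.matrix(utils::read.csv(files[i], check.names = FALSE))
    if (nrow(m) != meta$n_samples || ncol(m) != meta$n_channels)
      stop(sprintf("trial %d has shape %d x %d, expected %d x %d",
                   i, nrow(m), ncol(m), meta$n_samples, meta$n_channels))
    signals[i, , ] <- t(m)
  }
  ratings <- if (identical(meta$rating_kind, "categorical"))
    as.character(meta$ratings) else as.numeric(meta$ratings)
  trialset(signals, as.numeric(meta$fs), meta$subject_id, meta$session_id,
           ratings, as.character(meta$channel_names))
}

#' Read a European Data Format (EDF) recording as a single trial
#'
#' Minimal read-only parser for uncompressed EDF: the fixed 256-byte header,
#' the 256-byte per-signal header block, and 16-bit little-endian data
#' records, converted to physical units with each signal's digital/physical
#' calibration.  All channels must share one sampling rate; annotation
#' channels are not supported.  The whole recording becomes one trial.
#'
#' @param path EDF file.
#' @param rating rating to attach to the trial (default `NA`).
#' @return a [trialset] with `n_trials = 1`.
#' @export
read_edf <- function(path, rating = NA_real_) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr_chr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  version <- hdr_chr(8L)
  patient <- hdr_chr(80L); hdr_chr(80L)            # recording id
  hdr_chr(8L); hdr_chr(8L)                         # start date/time
  n_header_bytes <- as.integer(hdr_chr(8L))
  hdr_chr(44L)                                     # reserved
  n_records <- as.integer(hdr_chr(8L))
  record_dur <- as.numeric(hdr_chr(8L))
  ns <- as.integer(hdr_chr(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count")
  field <- function(nc) vapply(seq_len(ns), function(i) hdr_chr(nc), "")
  labels   <- field(16L); field(80L); field(8L)    # label, transducer, unit
  phys_min <- as.numeric(field(8L)); phys_max <- as.numeric(field(8L))
  dig_min  <- as.numeric(field(8L)); dig_max  <- as.numeric(field(8L))
  field(80L)                                       # prefiltering
  spr <- as.integer(field(8L))                     # samples per record
  field(32L)                                       # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing samples-per-record are not supported")
  if (any(dig_max == dig_min)) stop("malformed EDF: zero digital range")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  fs <- spr[1L] / record_dur
  n_samples <- n_records * spr[1L]
  sig <- matrix(NA_real_, ns, n_samples)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
      sig[s, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  signals <- array(NA_real_, c(1L, ns, n_samples))
  signals[1L, , ] <- sig
  subj <- if (nzchar(patient)) patient else "edf"
  trialset(signals, fs, subject_id = subj, ratings = rating,
           channel_names = labels)
}

#' Write / read a dataset descriptor as JSON
#'
#' @param desc a `dataset_descriptor` (see [deap_descriptor()]).
#' @param path JSON file path.
#' @export
save_descriptor <- function(desc, path) {
  stopifnot(inherits(desc, "dataset_descriptor"))
  jsonlite::write_json(unclass(desc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_descriptor
#' @export
load_descriptor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_descriptor(x$n_subjects, x$trials_per_subject_session, x$n_sessions,
                 x$n_channels, as.numeric(x$fs_hz),
                 as.numeric(x$trial_duration_s), x$rating_kind,
                 name = x$name %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature matrix
#'
#' Values go to a CSV with the column names as header; labels, subject and
#' session vectors go to a JSON sidecar (`<stem>_meta.json`).
#'
#' @param fm a [feature_matrix].
#' @param path CSV file path.
#' @export
save_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- fm$values
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE,
                     col.names = TRUE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    list(labels = fm$labels, subject_id = fm$subject_id,
         session_id = fm$session_id, column_names = colnames(m)),
    paste0(side, "_meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_feature_matrix
#' @export
load_feature_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- paste0(sub("\\.csv$", "", path), "_meta.json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  feature_matrix(m, labels = as.integer(meta$labels),
                 subject_id = meta$subject_id,
                 session_id = meta$session_id)
}
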