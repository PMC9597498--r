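#' Construct a multichannel EEG recording
#'
#' @param data Channels x samples numeric matrix, voltages in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#'   Legacy 10-20 names (T3/T4/T5/T6) are normalized to T7/T8/P7/P8.
#' @param subject_id,visit,condition Metadata carried through the pipeline;
#'   `visit` is `"baseline"` or `"end"`.
#' @return An `eeg_recording` object.
#' @export
recording <- function(data, fs, channel_labels,
                      subject_id = NA_character_,
                      visit = c("baseline", "end"),
                      condition = "resting") {
  data <- as.matrix(data)
  visit <- match.arg(visit)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite numeric, no NaN/Inf", call. = FALSE)
  if (length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  channel_labels <- normalize_channel_labels(as.character(channel_labels),
                                             warn = FALSE)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row required", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, visit = visit,
                 condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %s/%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$subject_id, x$visit))
  invisible(x)
}

#' Write a recording as a documented CSV pair
#'
#' The on-disk form is `<path>.csv` (one labeled row per channel, columns are
#' samples) plus `<path>.meta.json` holding the sampling rate and metadata.
#'
#' @param rec An [recording()].
#' @param path Base path (no extension).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(channel = rec$channel_labels,
                   rec$data, check.names = FALSE)
  names(df) <- c("channel", paste0("s", seq_len(ncol(rec$data))))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = rec$fs, subject_id = rec$subject_id, visit = rec$visit,
               condition = rec$condition, unit = "uV",
               channel_labels = rec$channel_labels)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' Channel labels are normalized through the legacy alias map (T3 -> T7,
#' T4 -> T8, T5 -> P7, T6 -> P8); a message notes any rewrite.  Labels
#' outside the 19-channel 10-20 montage produce a warning but the channel
#' is retained.
#'
#' @param path Base path given to [write_recording_csv()].
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path) {
  csv <- paste0(path, ".csv")
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(csv) || !file.exists(meta_path))
    stop("recording files not found at base path: ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs))
    stop("malformed recording metadata: missing numeric 'fs' in ",
         meta_path, call. = FALSE)
  df <- utils::read.csv(csv, check.names = FALSE)
  if (!"channel" %in% names(df))
    stop("malformed recording CSV: no 'channel' column in ", csv,
         call. = FALSE)
  labels <- normalize_channel_labels(as.character(df$channel))
  unknown <- setdiff(labels, montage_1020())
  if (length(unknown))
    warning("channel labels outside the 10-20 montage retained: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  if (!is.numeric(mat))
    stop("malformed recording CSV: non-numeric samples in ", csv,
         call. = FALSE)
  recording(mat, fs = meta$fs, channel_labels = labels,
            subject_id = meta$subject_id %||% NA_character_,
            visit = meta$visit %||% "baseline",
            condition = meta$condition %||% "resting")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
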