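#' Zero-phase band-pass filter a recording
#'
#' A 4th-order Butterworth band-pass applied forward-backward
#' (zero-phase) per channel.  The high-pass and low-pass halves are
#' cascaded separately, which keeps the recursion numerically stable at
#' very low normalized corner frequencies such as 0.5 Hz at 250 Hz.
#'
#' @param rec An [recording()].
#' @param low,high Pass-band edges in Hz; `0 < low < high < fs/2`.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 70) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (low <= 0 || low >= high)
    stop("need 0 < low < high", call. = FALSE)
  if (high >= rec$fs / 2)
    stop("high edge must be below the Nyquist frequency fs/2 = ",
         rec$fs / 2, call. = FALSE)
  hp <- signal::butter(4, low / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, high / (rec$fs / 2), type = "low")
  rec$data <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive windows of `epoch_length` seconds with fractional `overlap`;
#' a trailing partial window is discarded.
#'
#' @param rec An [recording()].
#' @param epoch_length Seconds; `epoch_length * fs` must be whole.
#' @param overlap Fraction in `[0, 1)`.
#' @return An `eeg_epochs` object: `epochs` array (epoch x channel x
#'   sample), `fs`, `channel_labels`, `epoch_length`, `kept_mask`,
#'   `rejection_report`.
#' @export
epoch_recording <- function(rec, epoch_length = 4, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ep_samp <- epoch_length * rec$fs
  if (abs(n_ep_samp - round(n_ep_samp)) > 1e-9)
    stop("epoch_length * fs must be a whole number of samples", call. = FALSE)
  n_ep_samp <- round(n_ep_samp)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  n <- ncol(rec$data)
  if (n < n_ep_samp)
    stop("recording shorter than one epoch", call. = FALSE)
  step <- round(n_ep_samp * (1 - overlap))
  starts <- seq(1, n - n_ep_samp + 1, by = step)
  ep <- array(0, c(length(starts), nrow(rec$data), n_ep_samp))
  for (k in seq_along(starts))
    ep[k, , ] <- rec$data[, starts[k]:(starts[k] + n_ep_samp - 1)]
  structure(list(epochs = ep, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 epoch_length = epoch_length,
                 kept_mask = rep(TRUE, length(starts)),
                 rejection_report = data.frame(
                   epoch = seq_along(starts), kept = TRUE,
                   reason = "", stringsAsFactors = FALSE),
                 subject_id = rec$subject_id, visit = rec$visit),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d kept epochs x %d ch x %d samples (%g s) @ %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_length, x$fs))
  invisible(x)
}

#' Threshold-based rejection of artifact epochs
#'
#' An epoch is dropped when any channel's peak-to-peak amplitude exceeds
#' `amplitude_threshold`, any channel's range falls below
#' `flatness_threshold`, or any sample-to-sample jump exceeds
#' `jump_threshold`.  The report records the first triggering rule
#' (checked in the order amplitude, flat, jump) for every dropped epoch.
#'
#' @param ep An `eeg_epochs` object.
#' @param amplitude_threshold Peak-to-peak limit (microvolts).
#' @param flatness_threshold Minimum channel range (microvolts).
#' @param jump_threshold Maximum sample-to-sample step (microvolts/sample).
#' @return The `eeg_epochs` restricted to kept epochs, with `kept_mask`
#'   and `rejection_report` updated.
#' @export
reject_bad_epochs <- function(ep, amplitude_threshold = 100,
                              flatness_threshold = 0.5,
                              jump_threshold = 25) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (amplitude_threshold <= 0 || flatness_threshold <= 0 ||
      jump_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  n_ep <- dim(ep$epochs)[1]
  reason <- character(n_ep)
  for (k in seq_len(n_ep)) {
    seg <- ep$epochs[k, , , drop = FALSE][1, , ]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = dim(ep$epochs)[2])
    rng <- apply(seg, 1, function(v) diff(range(v)))
    if (any(rng > amplitude_threshold)) {
      reason[k] <- "amplitude"
    } else if (any(rng < flatness_threshold)) {
      reason[k] <- "flat"
    } else if (max(abs(seg[, -1, drop = FALSE] -
                       seg[, -ncol(seg), drop = FALSE])) > jump_threshold) {
      reason[k] <- "jump"
    }
  }
  keep <- reason == ""
  report <- data.frame(epoch = seq_len(n_ep), kept = keep, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(keep)) {
    cond <- structure(class = c("qeeg_no_usable_data", "error", "condition"),
                      list(message = "all epochs rejected; no usable data",
                           call = sys.call(-1), report = report))
    stop(cond)
  }
  ep$epochs <- ep$epochs[keep, , , drop = FALSE]
  ep$kept_mask <- keep
  ep$rejection_report <- report
  ep
}
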