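#' Canonical EEG frequency band scheme
#'
#' Returns the eight-band partition conventionally used in quantitative EEG:
#' delta 1--4, theta 4--8, alpha1 8--10, alpha2 10--12, beta1 12--15,
#' beta2 15--20, beta3 20--30 and gamma 30--45 Hz.  Band membership is
#' half-open, `[f_low, f_high)`, so shared edges (4, 8, 10, 12, 15, 20,
#' 30 Hz) belong to exactly one band and the scheme partitions 1--45 Hz
#' with no double counting.
#'
#' @param bands Optional data frame with columns `name`, `f_low`, `f_high`
#'   (Hz) to replace the default scheme.  Bands must be non-overlapping and
#'   contiguous in increasing frequency order.
#' @return A `band_scheme` data frame with columns `name`, `f_low`, `f_high`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name = c("delta", "theta", "alpha1", "alpha2",
               "beta1", "beta2", "beta3", "gamma"),
      f_low = c(1, 4, 8, 10, 12, 15, 20, 30),
      f_high = c(4, 8, 10, 12, 15, 20, 30, 45),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(bands),
            all(c("name", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low >= bands$f_high))
    stop("each band must satisfy f_low < f_high", call. = FALSE)
  if (nrow(bands) > 1) {
    if (any(diff(bands$f_low) <= 0))
      stop("bands must be in increasing frequency order", call. = FALSE)
    if (any(abs(bands$f_high[-nrow(bands)] - bands$f_low[-1]) > 1e-12))
      stop("bands must be contiguous (f_high[i] == f_low[i+1])", call. = FALSE)
  }
  if (anyDuplicated(bands$name))
    stop("band names must be unique", call. = FALSE)
  class(bands) <- c("band_scheme", "data.frame")
  bands
}

#' Frequency-bin membership of a band
#'
#' @param freq Numeric vector of frequencies (Hz).
#' @param scheme A [band_scheme()].
#' @param band Band name.
#' @return Logical vector: `f_low <= freq < f_high`.
#' @keywords internal
band_bins <- function(freq, scheme, band) {
  i <- match(band, scheme$name)
  if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
  freq >= scheme$f_low[i] & freq < scheme$f_high[i]
}
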