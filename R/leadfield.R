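#' Build a toy spherical leadfield for 68 cortical regions
#'
#' Sensors sit on the upper cap of a unit sphere and sources on an inner
#' sphere (radius 0.8); the gain from source to sensor decays with squared
#' distance, `g = 1 / (eps + d^2)` with `eps = 0.1` of the sphere radius.
#' This produces smooth, full-rank, volume-conduction-like instantaneous
#' mixing without an anatomical head model.  Columns are normalized and the
#' matrix scaled so that unit-variance sources project to EEG-scale sensor
#' amplitudes of a few microvolts.
#'
#' @param n_sensors Number of sensors (>= 2); 19 matches the 10-20 montage.
#' @param sources_per_roi Sources per region (>= 1).
#' @param seed Integer seed; the source-point jitter is deterministic in it.
#' @return A `leadfield` list: `gain` (sensors x sources), `source_labels`
#'   (ROI label of each source), `roi_of_source` (integer map), and
#'   `roi_labels` (the 68 Desikan-Killiany names).
#' @export
make_toy_leadfield <- function(n_sensors = 19, sources_per_roi = 1, seed = 1) {
  if (n_sensors < 2) stop("n_sensors must be >= 2", call. = FALSE)
  if (sources_per_roi < 1) stop("sources_per_roi must be >= 1", call. = FALSE)
  rois <- dk_roi_labels()
  n_src <- length(rois) * sources_per_roi

  # Fibonacci lattice on a spherical cap/sphere gives well-spread points.
  fib_points <- function(n, z_lo, z_hi, radius) {
    i <- seq_len(n) - 0.5
    z <- z_lo + (z_hi - z_lo) * i / n
    phi <- i * pi * (3 - sqrt(5))
    r <- sqrt(pmax(0, 1 - z^2))
    radius * cbind(r * cos(phi), r * sin(phi), z)
  }
  sensors <- fib_points(n_sensors, 0.15, 0.98, 1)
  set.seed(seed)
  sources <- fib_points(n_src, -0.35, 0.95, 0.8)
  sources <- sources + matrix(stats::rnorm(3 * n_src, sd = 0.02), n_src, 3)

  d2 <- outer(rowSums(sensors^2), rowSums(sources^2), "+") -
    2 * sensors %*% t(sources)
  gain <- 1 / (0.1 + pmax(d2, 0))
  gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/") / 3

  roi_of_source <- rep(seq_along(rois), each = sources_per_roi)
  lf <- list(gain = gain,
             source_labels = rois[roi_of_source],
             roi_of_source = roi_of_source,
             roi_labels = rois,
             sensor_labels = if (n_sensors == 19) montage_1020() else
               paste0("S", seq_len(n_sensors)))
  rownames(lf$gain) <- lf$sensor_labels
  colnames(lf$gain) <- make.unique(lf$source_labels)
  class(lf) <- "leadfield"
  validate_leadfield(lf)
  lf
}

validate_leadfield <- function(lf) {
  if (!all(is.finite(lf$gain)))
    stop("leadfield gain must be finite", call. = FALSE)
  if (any(rowSums(abs(lf$gain)) == 0) || any(colSums(abs(lf$gain)) == 0))
    stop("leadfield has an all-zero row or column", call. = FALSE)
  if (!all(seq_along(lf$roi_labels) %in% lf$roi_of_source))
    stop("every ROI must have at least one source", call. = FALSE)
  invisible(lf)
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources (%d ROIs)\n",
              nrow(x$gain), ncol(x$gain), length(x$roi_labels)))
  invisible(x)
}
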