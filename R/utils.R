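# Internal numeric helpers.

#' Moore-Penrose pseudo-inverse via SVD
#' @param m Real matrix.
#' @param tol Relative singular-value cutoff.
#' @return Pseudo-inverse of `m`.
#' @keywords internal
pinv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Derive a child seed from a master seed and integer offsets; kept well
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in off) s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

#' The 19-channel 10-20 montage used at the sensor level
#' @return Character vector of channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
    "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

# Legacy 10-20 names map onto the modern equivalents.
channel_alias_map <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalize channel labels through the legacy alias map
#'
#' T3/T4/T5/T6 are accepted as aliases of T7/T8/P7/P8.
#' @param labels Character vector of channel labels.
#' @param warn Emit a message when an alias is rewritten.
#' @return Normalized labels.
#' @export
normalize_channel_labels <- function(labels, warn = TRUE) {
  hit <- labels %in% names(channel_alias_map)
  if (any(hit)) {
    if (warn)
      message("channel alias applied: ",
              paste(labels[hit], "->", channel_alias_map[labels[hit]],
                    collapse = ", "))
    labels[hit] <- channel_alias_map[labels[hit]]
  }
  labels
}

#' Desikan-Killiany cortical region labels (68 regions)
#'
#' The 34 cortical parcels per hemisphere, prefixed `lh_` / `rh_`.  The
#' labels are carried as region names only; no anatomical geometry is
#' attached.
#' @return Character vector of length 68.
#' @export
dk_roi_labels <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
  c(paste0("lh_", base), paste0("rh_", base))
}

# Two-sided FFT-grid frequencies (absolute value) for n samples at fs.
fft_freqs <- function(n, fs) {
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  pmin(f, fs - f)
}

# Amplitude transfer of a forward-backward (zero-phase) order-`order`
# Butterworth band-pass: |H(f)|^2 with |H| the single-pass magnitude.
butter_zero_phase_gain <- function(f, low, high, order = 4) {
  q <- rep(Inf, length(f))
  pos <- f > 0
  q[pos] <- (f[pos]^2 - low * high) / (f[pos] * (high - low))
  g <- 1 / (1 + q^(2 * order))
  g[!is.finite(g)] <- 0
  g
}

# Zero-phase band-pass by frequency-domain multiplication with the
# squared-magnitude Butterworth response, exact on the FFT grid.
# `x` may be a vector or a samples x series matrix (filtered per column).
fft_bandpass <- function(x, low, high, fs, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  g <- butter_zero_phase_gain(fft_freqs(nrow(x), fs), low, high, order)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / nrow(x)
  if (vec) drop(y) else y
}

# Gaussian noise with the given two-sided spectral shape, drawn directly in
# the frequency domain (the FFT of white Gaussian noise is complex Gaussian
# with Hermitian symmetry, so shaping there is distribution-identical to
# filtering white noise) and brought back with a single inverse FFT per
# column.  Returns an n x m real matrix, unit SD per column.
shaped_noise <- function(n, shape, m = 1) {
  half <- 2:ceiling((n + 1) / 2)       # positive-frequency bins
  X <- matrix(complex(real = 0), n, m)
  nh <- length(half)
  X[half, ] <- complex(real = stats::rnorm(nh * m),
                       imaginary = stats::rnorm(nh * m)) * shape[half]
  mirror <- n + 2 - half
  dup <- mirror != half                # Nyquist bin is its own mirror
  X[mirror[dup], ] <- Conj(X[half[dup], , drop = FALSE])
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(x, 2, sdv, "/")
}

# Band-limited Gaussian noise (zero-phase Butterworth-magnitude band-pass
# of white noise), unit SD per column.
bandlimited_noise <- function(n, low, high, fs, m = 1, order = 4) {
  shaped_noise(n, butter_zero_phase_gain(fft_freqs(n, fs), low, high, order),
               m)
}

# 1/f^a ("pink" for a = 1) background noise, unit SD per column; flat
# below f_min to keep the variance finite.
pink_noise <- function(n, fs, exponent = 1, f_min = 0.5, m = 1) {
  shape <- pmax(fft_freqs(n, fs), f_min)^(-exponent / 2)
  shape[1] <- 0                        # no DC
  shaped_noise(n, shape, m)
}

# Circular integer-sample delay: y[t] = x[t - d] with wrap-around.
circular_shift <- function(x, d) {
  n <- length(x)
  d <- ((d %% n) + n) %% n
  if (d == 0) return(x)
  c(x[(n - d + 1):n], x[1:(n - d)])
}
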