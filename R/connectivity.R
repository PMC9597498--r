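#' Epoch-averaged cross-spectral density
#'
#' `S_ij(f) = mean over epochs of X_i(f) conj(X_j(f))`, density-scaled (so
#' the diagonal matches the two-sided power spectral density), with an
#' optional Hann taper; Hermitian at every frequency with real
#' non-negative diagonal.  At least two epochs are required (single-epoch
#' coherency is degenerate: it is identically 1 in magnitude).
#'
#' @param roi_epochs Array epoch x entity x sample (e.g. from
#'   [aggregate_rois()], or an `eeg_epochs$epochs` array).
#' @param fs Sampling rate (Hz).
#' @param taper `"hann"` or `"none"`.
#' @param fmax Keep frequencies up to this limit (default Nyquist).
#' @return A `cross_spectra` list: `freq`, `S` (entity x entity x freq,
#'   complex), `labels`, `n_epochs`.
#' @export
cross_spectra <- function(roi_epochs, fs, taper = c("hann", "none"),
                          fmax = NULL) {
  taper <- match.arg(taper)
  n_ep <- dim(roi_epochs)[1]
  if (is.na(n_ep) || n_ep < 2)
    stop("cross-spectra need at least 2 epochs", call. = FALSE)
  n_ent <- dim(roi_epochs)[2]
  n <- dim(roi_epochs)[3]
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
  freq <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  if (is.null(fmax)) fmax <- fs / 2
  keep <- which(freq <= fmax + 1e-9)
  nf <- length(keep)
  S <- array(complex(real = 0), c(n_ent, n_ent, nf))
  # Fourier coefficients per epoch: nf x entity
  X <- array(complex(real = 0), c(n_ep, nf, n_ent))
  for (k in seq_len(n_ep)) {
    seg <- matrix(roi_epochs[k, , ], nrow = n_ent)
    seg <- sweep(seg, 2, w, "*")
    X[k, , ] <- stats::mvfft(t(seg))[keep, , drop = FALSE]
  }
  u <- fs * sum(w^2)                        # density normalization
  for (f in seq_len(nf)) {
    A <- matrix(X[, f, ], nrow = n_ep)      # epochs x entities
    S[, , f] <- t(Conj(t(A)) %*% A) / (n_ep * u)
  }
  labels <- dimnames(roi_epochs)[[2]]
  if (is.null(labels)) labels <- paste0("e", seq_len(n_ent))
  structure(list(freq = freq[keep], S = S, labels = labels,
                 n_epochs = n_ep),
            class = "cross_spectra")
}

#' Complex coherency from a cross-spectral density
#'
#' `C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`; bins where an
#' auto-spectrum is zero are flagged `NA` rather than silently divided.
#'
#' @param csd A [cross_spectra()] result.
#' @return A `coherency` list: `freq`, `C` (complex array), `labels`.
#' @export
coherency <- function(csd) {
  stopifnot(inherits(csd, "cross_spectra"))
  nf <- length(csd$freq)
  C <- csd$S
  for (f in seq_len(nf)) {
    d <- Re(diag(csd$S[, , f]))
    scale <- sqrt(outer(d, d))
    Cf <- csd$S[, , f] / scale
    Cf[scale == 0] <- NA_complex_
    C[, , f] <- Cf
  }
  structure(list(freq = csd$freq, C = C, labels = csd$labels,
                 n_epochs = csd$n_epochs),
            class = "coherency")
}

#' Band-wise imaginary-coherence connectivity
#'
#' For each band, `iCoh_ij = mean over bins f in [f_low, f_high) of
#' |Im C_ij(f)|`; the diagonal is forced to zero.  The absolute imaginary
#' part is insensitive to instantaneous (volume-conducted) mixing, whose
#' coherency is purely real.
#'
#' @param coh A [coherency()] result.
#' @param scheme A [band_scheme()]; only bands covered by the coherency's
#'   frequency axis may be requested.
#' @param bands Band names to compute (default: all in the scheme).
#' @return Named list of `connectivity_matrix` objects (symmetric,
#'   zero-diagonal, values in `[0, 1]`), one per band.
#' @export
imaginary_coherence <- function(coh, scheme = band_scheme(),
                                bands = scheme$name) {
  stopifnot(inherits(coh, "coherency"))
  out <- list()
  for (b in bands) {
    bins <- band_bins(coh$freq, scheme, b)
    if (!any(bins))
      stop("band ", b, " has zero frequency bins", call. = FALSE)
    m <- apply(abs(Im(coh$C[, , bins, drop = FALSE])), c(1, 2), mean)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(coh$labels, coh$labels)
    attr(m, "band") <- b
    attr(m, "n_epochs") <- coh$n_epochs
    attr(m, "n_bins") <- sum(bins)
    class(m) <- c("connectivity_matrix", "matrix")
    out[[b]] <- m
  }
  out
}
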