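#' Epoch-averaged power spectral density
#'
#' Per-epoch periodograms (squared FFT amplitudes with density scaling,
#' optional Hann taper) averaged across epochs — Welch's estimate with the
#' epochs as segments.  The spectrum is one-sided in microvolts squared per
#' Hz, with resolution `1 / epoch_length`.
#'
#' @param ep An `eeg_epochs` object with at least one kept epoch.
#' @param taper `"hann"` (default; leakage control for adjacent narrow
#'   bands) or `"none"`.
#' @return A `power_spectrum` list: `freq` (Hz), `psd` (entity x
#'   frequency), `labels`, `n_epochs`.
#' @export
power_spectrum <- function(ep, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  stopifnot(inherits(ep, "eeg_epochs"))
  n_ep <- dim(ep$epochs)[1]
  if (n_ep < 1) stop("no usable epochs", call. = FALSE)
  n_ch <- dim(ep$epochs)[2]
  n <- dim(ep$epochs)[3]
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
  u <- ep$fs * sum(w^2)               # density normalization
  n_keep <- floor(n / 2) + 1
  psd <- matrix(0, n_ch, n_keep)
  for (k in seq_len(n_ep)) {
    seg <- matrix(ep$epochs[k, , ], nrow = n_ch)
    seg <- sweep(seg, 2, w, "*")
    ft <- t(stats::mvfft(t(seg)))[, seq_len(n_keep), drop = FALSE]
    p <- (Mod(ft)^2) / u
    # one-sided: double everything except DC (and Nyquist when n is even)
    dbl <- rep(2, n_keep); dbl[1] <- 1
    if (n %% 2 == 0) dbl[n_keep] <- 1
    psd <- psd + sweep(p, 2, dbl, "*")
  }
  psd <- psd / n_ep
  structure(list(freq = (seq_len(n_keep) - 1) * ep$fs / n,
                 psd = psd, labels = ep$channel_labels, n_epochs = n_ep),
            class = "power_spectrum")
}

#' Absolute band powers from a spectrum
#'
#' Absolute power per band is the rectangle-rule integral of the PSD over
#' the half-open band, `sum(psd[f_low <= f < f_high]) * df`.
#'
#' @param spectrum A [power_spectrum()].
#' @param scheme A [band_scheme()].
#' @return A `band_power_table`: list with `absolute` (entity x band matrix,
#'   microvolts squared), `scheme`, `labels`; `relative` and `ratios` are
#'   filled by [relative_powers()] and [band_ratios()].
#' @export
band_powers <- function(spectrum, scheme = band_scheme()) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  df <- spectrum$freq[2] - spectrum$freq[1]
  fmax <- max(spectrum$freq) + df
  for (b in seq_len(nrow(scheme)))
    if (scheme$f_low[b] < min(spectrum$freq) - 1e-9 ||
        scheme$f_high[b] > fmax + 1e-9)
      stop("spectrum does not cover band ", scheme$name[b], call. = FALSE)
  absb <- sapply(seq_len(nrow(scheme)), function(b) {
    bins <- band_bins(spectrum$freq, scheme, scheme$name[b])
    rowSums(spectrum$psd[, bins, drop = FALSE]) * df
  })
  absb <- matrix(absb, nrow = nrow(spectrum$psd),
                 dimnames = list(spectrum$labels, scheme$name))
  structure(list(absolute = absb, relative = NULL, ratios = NULL,
                 alpha_peak = NULL, scheme = scheme,
                 labels = spectrum$labels),
            class = "band_power_table")
}

#' Fill relative band powers
#'
#' Relative power is each band's absolute power divided by the total over
#' the scheme's bands (1--45 Hz for the default eight), so rows sum to 1.
#' Entities with zero total power are flagged in
#' `attr(, "undefined_entities")` and set to `NA` rather than silently NaN.
#'
#' @param table A [band_powers()] result.
#' @return The table with `relative` filled.
#' @export
relative_powers <- function(table) {
  stopifnot(inherits(table, "band_power_table"), !is.null(table$absolute))
  tot <- rowSums(table$absolute)
  rel <- sweep(table$absolute, 1, tot, "/")
  bad <- tot == 0
  rel[bad, ] <- NA_real_
  table$relative <- rel
  attr(table, "undefined_entities") <- table$labels[bad]
  table
}

#' Fill band power ratios
#'
#' TAR = theta / (alpha1 + alpha2), DAR = delta / (alpha1 + alpha2),
#' TBR = theta / (beta1 + beta2 + beta3), TB2R = theta / beta2.  The
#' composites follow the band names: "alpha" pools its two subbands and
#' "beta" its three, while TB2R uses beta2 alone as its name dictates.
#' Zero denominators yield `NA` and are flagged.
#'
#' @param table A [band_powers()] result.
#' @return The table with a `ratios` matrix (TAR, DAR, TBR, TB2R) filled.
#' @export
band_ratios <- function(table) {
  stopifnot(inherits(table, "band_power_table"), !is.null(table$absolute))
  a <- table$absolute
  need <- c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "beta3")
  if (!all(need %in% colnames(a)))
    stop("ratio computation needs the canonical eight-band scheme",
         call. = FALSE)
  alpha <- a[, "alpha1"] + a[, "alpha2"]
  beta <- a[, "beta1"] + a[, "beta2"] + a[, "beta3"]
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  r <- cbind(TAR = safe_div(a[, "theta"], alpha),
             DAR = safe_div(a[, "delta"], alpha),
             TBR = safe_div(a[, "theta"], beta),
             TB2R = safe_div(a[, "theta"], a[, "beta2"]))
  rownames(r) <- table$labels
  table$ratios <- r
  table
}

#' Alpha peak frequency of one entity
#'
#' The frequency of the largest strict local maximum of the PSD within the
#' search range, refined by three-point quadratic interpolation.  Returns
#' `NA` (peak absent) when no strict local maximum exists, e.g. for a
#' monotone spectrum.
#'
#' @param spectrum A [power_spectrum()].
#' @param entity Channel/entity label, e.g. `"O1"`.
#' @param search Two-element Hz range, default `c(7, 13)`.
#' @return Peak frequency in Hz, or `NA_real_` when absent.
#' @export
alpha_peak_frequency <- function(spectrum, entity, search = c(7, 13)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  i <- match(entity, spectrum$labels)
  if (is.na(i)) stop("entity not in spectrum: ", entity, call. = FALSE)
  f <- spectrum$freq
  if (min(f) > search[1] || max(f) < search[2])
    stop("spectrum does not cover the search range", call. = FALSE)
  y <- spectrum$psd[i, ]
  idx <- which(f >= search[1] & f <= search[2])
  # strict local maxima (interior bins of the full spectrum)
  cand <- idx[idx > 1 & idx < length(f)]
  cand <- cand[y[cand] > y[cand - 1] & y[cand] > y[cand + 1]]
  if (!length(cand)) return(NA_real_)
  j <- cand[which.max(y[cand])]
  dfq <- f[2] - f[1]
  denom <- y[j - 1] - 2 * y[j] + y[j + 1]
  delta <- if (denom < 0) 0.5 * (y[j - 1] - y[j + 1]) / denom else 0
  f[j] + max(min(delta, 0.5), -0.5) * dfq
}
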