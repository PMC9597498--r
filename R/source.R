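#' Build a standardized minimum-norm (sLORETA-style) inverse operator
#'
#' The minimum-norm kernel is `K = L' (L L' + alpha I)^+` (pseudo-inverse,
#' tolerant of rank deficiency).  Each source estimate is standardized by
#' the square root of the corresponding diagonal entry of the resolution
#' matrix `R = K L`; with `alpha = 0` this standardization gives zero
#' localization error for noiseless single sources.
#'
#' @param leadfield A [make_toy_leadfield()]-shaped leadfield.
#' @param alpha Tikhonov regularization (>= 0).  Default `NULL` means
#'   `0.05 * mean(eigenvalues(L L'))`, a signal-to-noise-agnostic choice.
#' @return An `inverse_operator` list: `kernel` (sources x sensors),
#'   `standardization` (per-source positive scale), `alpha`,
#'   `sensor_labels`, and a leadfield `fingerprint`.
#' @export
build_inverse <- function(leadfield, alpha = NULL) {
  L <- leadfield$gain
  if (all(L == 0)) stop("all-zero leadfield", call. = FALSE)
  G <- L %*% t(L)
  if (is.null(alpha)) alpha <- 0.05 * mean(eigen(G, symmetric = TRUE,
                                                 only.values = TRUE)$values)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  K <- t(L) %*% pinv(G + alpha * diag(nrow(G)))
  std <- sqrt(pmax(rowSums(K * t(L)), 0))   # diag(K L)
  if (any(std <= 0))
    stop("non-positive standardization; leadfield column degenerate",
         call. = FALSE)
  structure(list(kernel = K, standardization = std, alpha = alpha,
                 sensor_labels = rownames(L),
                 source_labels = colnames(L),
                 roi_of_source = leadfield$roi_of_source,
                 roi_labels = leadfield$roi_labels,
                 fingerprint = sum(L * seq_along(L))),
            class = "inverse_operator")
}

#' Apply an inverse operator to epoched sensor data
#'
#' Per epoch, the kernel is applied to the channel x sample matrix and each
#' source row divided by its standardization scale.  Channels are aligned
#' to the operator's sensor order by label.
#'
#' @param ep An `eeg_epochs` object.
#' @param op An [build_inverse()] operator.
#' @return Array epoch x source x sample of standardized source activity
#'   (unitless after standardization).
#' @export
apply_inverse <- function(ep, op) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(op, "inverse_operator"))
  ord <- match(op$sensor_labels, ep$channel_labels)
  if (anyNA(ord))
    stop("epochs lack operator channels: ",
         paste(op$sensor_labels[is.na(ord)], collapse = ", "), call. = FALSE)
  n_ep <- dim(ep$epochs)[1]
  n_samp <- dim(ep$epochs)[3]
  n_src <- nrow(op$kernel)
  out <- array(0, c(n_ep, n_src, n_samp))
  for (k in seq_len(n_ep)) {
    seg <- matrix(ep$epochs[k, , ], nrow = dim(ep$epochs)[2])[ord, ,
                                                              drop = FALSE]
    out[k, , ] <- (op$kernel %*% seg) / op$standardization
  }
  out
}

#' Aggregate source activity into region time series
#'
#' Each region's series is the unweighted mean of its member sources after
#' sign-aligning every member to the region's leading singular vector (so
#' two members that differ only by a sign flip reinforce instead of
#' cancel).  With one source per region this is the identity.
#'
#' @param source_activity Array epoch x source x sample from
#'   [apply_inverse()].
#' @param op The `inverse_operator` (carries the source-to-region map).
#' @return Array epoch x region x sample with region labels on dim 2.
#' @export
aggregate_rois <- function(source_activity, op) {
  roi_of <- op$roi_of_source
  n_roi <- length(op$roi_labels)
  if (length(roi_of) != dim(source_activity)[2])
    stop("source count does not match the region map", call. = FALSE)
  if (!all(seq_len(n_roi) %in% roi_of))
    stop("a region has zero sources", call. = FALSE)
  n_ep <- dim(source_activity)[1]
  n_samp <- dim(source_activity)[3]
  out <- array(0, c(n_ep, n_roi, n_samp))
  for (r in seq_len(n_roi)) {
    mem <- which(roi_of == r)
    if (length(mem) == 1) {
      out[, r, ] <- source_activity[, mem, ]
    } else {
      # stack members across epochs to fix one sign per member
      stacked <- do.call(cbind, lapply(seq_len(n_ep), function(k)
        matrix(source_activity[k, mem, ], nrow = length(mem))))
      sv <- svd(stacked, nu = 1, nv = 0)
      signs <- sign(sv$u[, 1])
      signs[signs == 0] <- 1
      # anchor the overall sign to the first member
      signs <- signs * signs[1]
      for (k in seq_len(n_ep))
        out[k, r, ] <- colMeans(signs *
                                  matrix(source_activity[k, mem, ],
                                         nrow = length(mem)))
    }
  }
  dimnames(out) <- list(NULL, op$roi_labels, NULL)
  out
}
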