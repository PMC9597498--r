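# Shared fixtures and independent oracles used across test files.

# sinusoidal recording: one channel per row of `freqs`, amplitude `amps`
sine_recording <- function(freqs, amps, fs = 250, duration = 20,
                           labels = NULL) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  data <- t(sapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t)))
  if (is.null(labels)) labels <- montage_1020()[seq_along(freqs)]
  recording(data, fs = fs, channel_labels = labels)
}

# epochs array built directly from a channels x samples matrix
as_epochs <- function(mat, fs, epoch_length) {
  rec <- recording(mat, fs = fs,
                   channel_labels = montage_1020()[seq_len(nrow(mat))])
  epoch_recording(rec, epoch_length = epoch_length)
}

# Floyd-Warshall all-pairs distances: the independent oracle for BFS
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# exact Mann-Whitney two-sided p by full enumeration of labelings
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_stat(x, y)
  m <- length(pooled)
  combs <- utils::combn(m, nx)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- nx * (m - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force BH: search every rejection threshold among the p-values
bh_brute_reject <- function(p, q) {
  m <- length(p)
  best <- numeric(0)
  for (thr in sort(p)) {
    k <- sum(p <= thr)
    if (thr <= k * q / m) best <- which(p <= thr)
  }
  rej <- logical(m)
  rej[best] <- TRUE
  rej
}

# small random graph with guaranteed symmetry and zero diagonal
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  A + t(A)
}

# strip binary-graph attributes for raw matrix comparisons
unclass_g <- function(g) {
  a <- unclass(g); attributes(a)[c("density", "n_edges")] <- NULL
  class(a) <- NULL
  a
}
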