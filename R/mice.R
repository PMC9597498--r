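#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fully conditional specification: cycle over the incomplete variables;
#' for each, regress its observed values on all other variables (current
#' completed values), draw the coefficients and residual variance from
#' their approximate Bayesian posterior, predict the missing entries, and
#' impute each by the observed value of a donor drawn uniformly from the
#' `k_donors` cases with the closest predicted mean.  `m` independent
#' chains each run `iterations` cycles.  Every imputed value is therefore
#' an observed value of its variable (the PMM property), and cells that
#' were observed are never altered.
#'
#' Only numeric columns are imputed; complete columns (numeric or factor)
#' act as predictors through a standard design matrix.
#'
#' @param data Data frame with missing cells.
#' @param m Number of imputations (chains).
#' @param iterations Cycles of the imputation model per chain.
#' @param k_donors Donor pool size for predictive mean matching.
#' @param seed Integer seed.
#' @return An `imputed_set`: `imputations` (list of `m` completed data
#'   frames), `m`, `iterations`, `k_donors`, `seed`, and `chain_means`
#'   (array iteration x variable x chain of imputed-cell means, for
#'   convergence checks).
#' @export
mice_pmm <- function(data, m = 20, iterations = 20, k_donors = 5, seed = 1) {
  if (k_donors < 1) stop("k_donors must be >= 1", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  miss <- vapply(data, function(x) anyNA(x), logical(1))
  incomplete <- names(data)[miss]
  for (v in incomplete) {
    if (!is.numeric(data[[v]]))
      stop("only numeric variables can be imputed: ", v, call. = FALSE)
    n_obs <- sum(!is.na(data[[v]]))
    if (n_obs == 0) stop("variable entirely missing: ", v, call. = FALSE)
    if (n_obs < k_donors)
      stop("variable ", v, " has fewer observed values than k_donors",
           call. = FALSE)
  }
  if (!length(incomplete)) {
    return(structure(list(imputations = rep(list(data), m), m = m,
                          iterations = iterations, k_donors = k_donors,
                          seed = seed, chain_means = NULL),
                     class = "imputed_set"))
  }
  set.seed(seed)
  chain_means <- array(NA_real_, c(iterations, length(incomplete), m),
                       dimnames = list(NULL, incomplete, NULL))
  imputations <- vector("list", m)
  for (chain in seq_len(m)) {
    d <- data
    # initial fill: random draws from each variable's observed values
    for (v in incomplete) {
      na_idx <- which(is.na(d[[v]]))
      obs <- d[[v]][!is.na(d[[v]])]
      d[[v]][na_idx] <- sample(obs, length(na_idx), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in incomplete) {
        na_idx <- which(is.na(data[[v]]))
        obs_idx <- which(!is.na(data[[v]]))
        X <- stats::model.matrix(
          stats::reformulate(setdiff(names(d), v)), data = d)
        y <- data[[v]][obs_idx]
        Xo <- X[obs_idx, , drop = FALSE]
        Xm <- X[na_idx, , drop = FALSE]
        p <- ncol(Xo)
        ridge <- 1e-6 * mean(diag(crossprod(Xo)))
        XtX <- crossprod(Xo) + ridge * diag(p)
        XtXi <- solve(XtX)
        beta_hat <- XtXi %*% crossprod(Xo, y)
        resid <- y - Xo %*% beta_hat
        df_res <- max(length(obs_idx) - p, 1)
        sigma2 <- sum(resid^2) / stats::rchisq(1, df_res)
        beta_draw <- beta_hat +
          t(chol(sigma2 * (XtXi + t(XtXi)) / 2)) %*% stats::rnorm(p)
        pred_obs <- as.numeric(Xo %*% beta_hat)
        pred_mis <- as.numeric(Xm %*% beta_draw)
        for (j in seq_along(na_idx)) {
          dist <- abs(pred_obs - pred_mis[j])
          donors <- obs_idx[order(dist)[seq_len(k_donors)]]
          d[[v]][na_idx[j]] <- data[[v]][sample(donors, 1)]
        }
        chain_means[it, v, chain] <- mean(d[[v]][na_idx])
      }
    }
    imputations[[chain]] <- d
  }
  structure(list(imputations = imputations, m = m, iterations = iterations,
                 k_donors = k_donors, seed = seed,
                 chain_means = chain_means),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("<imputed_set> m = %d chains x %d iterations, k = %d donors\n",
              x$m, x$iterations, x$k_donors))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean across imputations; total variance is the
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom follow Barnard-Rubin
#' when a complete-data df is supplied, else the classic large-sample
#' formula.
#'
#' @param estimates Per-imputation point estimates (length m >= 2).
#' @param variances Per-imputation squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom (default `Inf`).
#' @param conf_level Confidence level for the pooled interval.
#' @return List: `estimate`, `within`, `between`, `total_variance`, `df`,
#'   `ci`, `p` (test of zero).
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf,
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pooling needs m >= 2 imputations", call. = FALSE)
  if (length(variances) != m)
    stop("estimates and variances must have equal length", call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B == 0 || Tv == 0) {
    df <- dfcom
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else df <- df_old
  }
  se <- sqrt(Tv)
  tcrit <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se == 0) as.numeric(qbar != 0) * 0 + ifelse(qbar == 0, 1, 0) else
    2 * (if (is.finite(df)) stats::pt(-abs(qbar / se), df) else
      stats::pnorm(-abs(qbar / se)))
  list(estimate = qbar, within = W, between = B, total_variance = Tv,
       df = df, ci = c(qbar - tcrit * se, qbar + tcrit * se), p = p)
}
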