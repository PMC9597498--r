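#' Two-sample t test
#'
#' Student's pooled-variance variant by default (the conventional reading
#' of an "independent t-test"); Welch available by flag.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return A `stat_result` list: `test`, `estimate` (mean difference),
#'   `statistic`, `df`, `p`, `conf_int`, `n`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs size >= 2", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(stat_result("t (degenerate)", mean(x) - mean(y), 0,
                       length(x) + length(y) - 2, 1,
                       c(0, 0), c(length(x), length(y))))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  stat_result(paste0("t (", variant, ")"),
              unname(ht$estimate[1] - ht$estimate[2]),
              unname(ht$statistic), unname(ht$parameter), ht$p.value,
              unname(ht$conf.int), c(length(x), length(y)))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration when the combined sample size is at
#' most 12 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.  The mode actually used is
#' recorded.
#'
#' @param x,y Numeric samples (each size >= 1).
#' @param mode `"auto"` (the rule above), `"exact"` or `"normal"`.
#' @return A `stat_result` with the U statistic; `$mode` gives the p-value
#'   route.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("each sample needs size >= 1", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      auto = (length(x) + length(y) <= 12) && !ties,
                      exact = TRUE, normal = FALSE)
  if (length(unique(c(x, y))) == 1) {
    r <- stat_result("Mann-Whitney U", length(x) * length(y) / 2, NA, NA, 1,
                     NULL, c(length(x), length(y)))
    r$U <- length(x) * length(y) / 2
    r$mode <- "degenerate (all tied)"
    return(r)
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  r <- stat_result("Mann-Whitney U", unname(ht$statistic), NA, NA,
                   min(ht$p.value, 1), NULL, c(length(x), length(y)))
  r$U <- unname(ht$statistic)
  r$mode <- if (use_exact) "exact" else "normal-approx (tie-corrected)"
  r
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up rule over one family of p-values: reject every test with rank at
#' most `max{i : p_(i) <= i q / m}`; adjusted p-values by the standard
#' monotone cumulative-minimum transform (as in `p.adjust`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `p_adjusted` (same order as input) and logical
#'   `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(p_adjusted = numeric(), reject = logical()))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  adj <- stats::p.adjust(p, method = "BH")
  ord <- order(p)
  thresh <- p[ord] <= seq_len(m) * q / m
  k <- if (any(thresh)) max(which(thresh)) else 0
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  list(p_adjusted = adj, reject = reject)
}

#' Baseline-adjusted ANCOVA
#'
#' Linear model `outcome ~ baseline + group`; the group factor's first
#' level is the reference (put the control arm first).  Returns the group
#' F test and one contrast per non-reference level.
#'
#' @param outcome End or change score per subject.
#' @param group Factor (>= 2 levels, >= 3 subjects per level).
#' @param baseline Baseline covariate.
#' @return List with `F`, `df`, `p_group`, and a `contrasts` data frame
#'   (`level`, `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`).
#' @export
ancova_baseline_adjusted <- function(outcome, group, baseline) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 3)) stop("need >= 3 subjects per group",
                                  call. = FALSE)
  # estimability: a baseline constant within groups but differing across is
  # collinear with the group indicators
  wv <- tapply(baseline, group, stats::var)
  if (all(wv < 1e-12, na.rm = TRUE) &&
      stats::var(tapply(baseline, group, mean)) > 1e-12)
    warning("baseline is collinear with group; contrasts not estimable",
            call. = FALSE)
  fit <- stats::lm(outcome ~ baseline + group)
  an <- stats::anova(fit)
  i <- which(rownames(an) == "group")
  sm <- summary(fit)$coefficients
  rows <- grep("^group", rownames(sm))
  ci <- suppressWarnings(stats::confint(fit))
  contrasts <- data.frame(
    level = sub("^group", "", rownames(sm)[rows]),
    estimate = sm[rows, 1], se = sm[rows, 2], t = sm[rows, 3],
    p = sm[rows, 4], ci_lo = ci[rows, 1], ci_hi = ci[rows, 2],
    row.names = NULL)
  if (summary(fit)$sigma < 1e-10)
    attr(contrasts, "zero_residual_variance") <- TRUE
  list(F = an[i, "F value"], df = c(an[i, "Df"], an[nrow(an), "Df"]),
       p_group = an[i, "Pr(>F)"], contrasts = contrasts, fit = fit)
}

#' Covariate-adjusted linear regression
#'
#' Ordinary least squares of `y` on `x` adjusted for age, sex and
#' education; the reported coefficient, t-based confidence interval and
#' p-value are for `x`.
#'
#' @param y,x Numeric vectors (e.g. change scores).
#' @param age,education Numeric covariates.
#' @param sex Factor or character covariate (reference-coded).
#' @param conf_level Confidence level.
#' @return A `stat_result` with `estimate` = b, `conf_int`, `p`, `df`.
#' @export
linear_regression_adjusted <- function(y, x, age, sex, education,
                                       conf_level = 0.95) {
  df <- data.frame(y = y, x = x, age = age, sex = as.factor(sex),
                   education = education)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= 5)
    stop("need more observations than predictors", call. = FALSE)
  fit <- stats::lm(y ~ x + age + sex + education, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = conf_level)
  r <- stat_result("linear regression (adjusted)", sm["x", 1], sm["x", 3],
                   fit$df.residual, sm["x", 4], as.numeric(ci), nrow(df))
  r$se <- sm["x", 2]
  r
}

#' Baseline characteristics table tests
#'
#' Chi-square for categorical variables, one-way ANOVA for numeric
#' variables, Kruskal-Wallis for variables flagged as skewed.  Variables
#' whose chi-square expected counts include a zero are flagged and skipped.
#'
#' @param data Data frame of subject-level variables.
#' @param group Column name of the grouping factor.
#' @param variables Column names to test (default: all but `group`).
#' @param skewed Numeric variables to test by Kruskal-Wallis instead of
#'   ANOVA.
#' @return Data frame: `variable`, `test`, `statistic`, `df`, `p`, `note`.
#' @export
baseline_table_tests <- function(data, group, variables = NULL,
                                 skewed = character()) {
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(variables)) variables <- setdiff(names(data), group)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && !(v %in% skewed)) {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1]]
      data.frame(variable = v, test = "one-way ANOVA",
                 statistic = an[1, "F value"], df = an[1, "Df"],
                 p = an[1, "Pr(>F)"], note = "")
    } else if (is.numeric(x)) {
      ht <- stats::kruskal.test(x, g)
      data.frame(variable = v, test = "Kruskal-Wallis",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value, note = "")
    } else {
      tab <- table(x, g)
      exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_cnt == 0))
        return(data.frame(variable = v, test = "chi-square",
                          statistic = NA_real_, df = NA_real_, p = NA_real_,
                          note = "skipped: zero expected cell count"))
      ht <- suppressWarnings(stats::chisq.test(tab))
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value, note = "")
    }
  })
  do.call(rbind, rows)
}

stat_result <- function(test, estimate, statistic, df, p, conf_int, n) {
  structure(list(test = test, estimate = estimate, statistic = statistic,
                 df = df, p = p, conf_int = conf_int, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: estimate = %s, p = %.4g\n", x$test,
              format(x$estimate, digits = 4), x$p))
  invisible(x)
}
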