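test_that("two-sample t handles identity, shift and symmetry", {
  x <- c(1, 2, 3, 4)
  r <- two_sample_t(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(1)
  y <- c(1, 1, 1, 1) + rnorm(4, sd = 1e-3)
  r2 <- two_sample_t(c(0, 0, 0, 0) + rnorm(4, sd = 1e-3), y)
  expect_lt(r2$p, 0.01)
  a <- rnorm(10); b <- rnorm(12, 1)
  rab <- two_sample_t(a, b); rba <- two_sample_t(b, a)
  expect_equal(rab$statistic, -rba$statistic)
  expect_equal(rab$p, rba$p)
  expect_error(two_sample_t(1, c(1, 2)), "size")
  # degenerate equal constants: t = 0, p = 1, not an error
  rd <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rd$p, 1)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0, ignore_attr = TRUE)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p, mw_enum_p(c(1, 2), c(3, 4)))
  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$U, 1, ignore_attr = TRUE)
  expect_gt(r2$p, 0.3)
  expect_equal(r2$p, mw_enum_p(c(1, 3), c(2, 4)))
  # more enumeration cross-checks on random tie-free small samples
  set.seed(2)
  for (k in 1:10) {
    x <- sample(seq(1, 40), sample(2:5, 1))
    y <- sample(seq(41, 80) + 0.5, sample(2:5, 1))
    y <- y - runif(1, 0, 60)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney_u(x, y)$p, mw_enum_p(x, y),
                 tolerance = 1e-10)
  }
  # positive scaling leaves U and p unchanged
  x <- c(0.3, 1.1, 2.2); y <- c(0.7, 1.9, 3.3)
  expect_equal(mann_whitney_u(x, y)[c("U", "p")],
               mann_whitney_u(10 * x, 10 * y)[c("U", "p")])
  # all tied: p = 1
  expect_equal(mann_whitney_u(c(1, 1), c(1, 1))$p, 1)
})

test_that("BH step-up matches the worked example and brute force", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  r <- bh_fdr(p, 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$p_adjusted, p.adjust(p, "BH"))
  expect_true(all(r$p_adjusted >= p))
  r1 <- bh_fdr(1)
  expect_equal(r1$p_adjusted, 1)
  rall <- bh_fdr(rep(1, 6), 0.05)
  expect_false(any(rall$reject))
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)   # m = 1: adjusted = raw
  set.seed(3)
  for (k in 1:20) {
    pv <- runif(sample(2:12, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(pv, 0.05)$reject, bh_brute_reject(pv, 0.05))
  }
})

test_that("baseline-adjusted ANCOVA recovers a planted arm effect", {
  set.seed(4)
  # deterministic covariate: outcome = baseline exactly
  g <- factor(rep(c("ctrl", "trt"), each = 10), c("ctrl", "trt"))
  b <- rnorm(20)
  r0 <- ancova_baseline_adjusted(b, g, b)
  expect_lt(abs(r0$contrasts$estimate[1]), 1e-10)
  expect_true(isTRUE(attr(r0$contrasts, "zero_residual_variance")))
  # planted effect +5 with residual SD 8, n = 40/arm, 200 replications
  est <- replicate(200, {
    base <- rnorm(80, 50, 10)
    grp <- factor(rep(c("ctrl", "trt"), each = 40), c("ctrl", "trt"))
    chg <- 0.3 * base + ifelse(grp == "trt", 5, 0) + rnorm(80, 0, 8)
    ancova_baseline_adjusted(chg, grp, base)$contrasts$estimate[1]
  })
  expect_lt(abs(mean(est) - 5), 1)
  expect_error(ancova_baseline_adjusted(rnorm(4),
                                        factor(c("a", "a", "b", "b")),
                                        rnorm(4)), ">= 3")
})

test_that("adjusted regression is exact for exact relations", {
  set.seed(5)
  n <- 40
  x <- rnorm(n); age <- runif(n, 60, 79)
  sex <- sample(c("F", "M"), n, TRUE); edu <- rnorm(n, 10, 3)
  r <- linear_regression_adjusted(2 * x, x, age, sex, edu)
  expect_equal(r$estimate, 2, tolerance = 1e-9)
  expect_lt(diff(r$conf_int), 1e-6)
  # duplicating rows keeps b, shrinks the interval
  r2 <- linear_regression_adjusted(c(2 * x, 2 * x) + rep(rnorm(n, 0, 1), 2),
                                   c(x, x), c(age, age), c(sex, sex),
                                   c(edu, edu))
  y1 <- 2 * x + rnorm(n)
  rs <- linear_regression_adjusted(y1, x, age, sex, edu)
  rd <- linear_regression_adjusted(c(y1, y1), c(x, x), c(age, age),
                                   c(sex, sex), c(edu, edu))
  expect_equal(rd$estimate, rs$estimate, tolerance = 1e-9)
  expect_lt(diff(rd$conf_int), diff(rs$conf_int))
  # collinear design errors with the offending column named
  expect_error(linear_regression_adjusted(rnorm(n), age, age, sex, edu),
               "collinear")
  # null coverage: |b| < 2 SE in >= 93% of 200 simulations
  cover <- replicate(200, {
    xx <- rnorm(30); yy <- rnorm(30)
    rr <- linear_regression_adjusted(yy, xx, runif(30, 60, 79),
                                     sample(c("F", "M"), 30, TRUE),
                                     rnorm(30, 10, 3))
    abs(rr$estimate) < 2 * rr$se
  })
  expect_gte(mean(cover), 0.93)
})

test_that("chained-equation PMM imputes only observed donor values", {
  set.seed(6)
  n <- 120
  z <- rnorm(n)
  dat <- data.frame(a = z + rnorm(n, 0, 0.8),
                    b = 0.6 * z + rnorm(n, 0, 0.8),
                    c = rnorm(n))
  dat$a[sample(n, 30)] <- NA
  dat$b[sample(n, 25)] <- NA
  imp <- mice_pmm(dat, m = 3, iterations = 5, k_donors = 5, seed = 1)
  obs_a <- dat$a[!is.na(dat$a)]
  obs_b <- dat$b[!is.na(dat$b)]
  for (d in imp$imputations) {
    expect_false(anyNA(d))
    expect_true(all(d$a[is.na(dat$a)] %in% obs_a))
    expect_true(all(d$b[is.na(dat$b)] %in% obs_b))
    # observed cells untouched
    expect_identical(d$a[!is.na(dat$a)], obs_a)
    expect_identical(d$c, dat$c)
  }
  # no missing cells: m identical copies of the input
  imp0 <- mice_pmm(data.frame(u = 1:5, v = 6:10), m = 2)
  expect_identical(imp0$imputations[[1]], data.frame(u = 1:5, v = 6:10))
  expect_error(mice_pmm(data.frame(u = c(NA_real_, NA_real_), v = c(1, 2))),
               "entirely")
  expect_error(mice_pmm(dat, k_donors = 0), "k_donors")
})

test_that("PMM chains stabilize and Rubin pooling is calibrated", {
  set.seed(7)
  hits <- 0
  for (rep in 1:40) {
    n <- 200
    x <- rnorm(n)
    y <- 0.6 * x + rnorm(n, 0, sqrt(1 - 0.36))
    dat <- data.frame(x = x, y = y)
    dat$y[runif(n) < 0.3] <- NA
    imp <- mice_pmm(dat, m = 5, iterations = 8, k_donors = 5, seed = rep)
    est <- vapply(imp$imputations, function(d) mean(d$y), numeric(1))
    v <- vapply(imp$imputations, function(d) var(d$y) / n, numeric(1))
    pooled <- pool_rubin(est, v, dfcom = n - 1)
    if (pooled$ci[1] <= 0 && 0 <= pooled$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
  # convergence: late chain-mean spread no larger than early spread
  set.seed(8)
  n <- 150
  z <- rnorm(n)
  dat <- data.frame(a = z + rnorm(n, 0, 0.5), b = z + rnorm(n, 0, 0.5))
  dat$a[sample(n, 45)] <- NA
  imp <- mice_pmm(dat, m = 3, iterations = 12, k_donors = 5, seed = 2)
  tr <- imp$chain_means[, "a", ]
  expect_lt(mean(apply(tr[8:12, , drop = FALSE], 2, sd)),
            2 * mean(apply(tr[1:5, , drop = FALSE], 2, sd)) + 1e-9)
})

test_that("Rubin pooling reproduces the closed-form worked example", {
  r <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(r$estimate, 2)
  expect_equal(r$between, 2)
  expect_equal(r$total_variance, 1 + 1.5 * 2)
  # invariance to imputation order; degenerate identical estimates
  r2 <- pool_rubin(c(3, 1), c(1, 1))
  expect_equal(r[c("estimate", "total_variance")],
               r2[c("estimate", "total_variance")])
  r3 <- pool_rubin(c(2, 2, 2), c(0.5, 0.7, 0.6))
  expect_equal(r3$between, 0)
  expect_equal(r3$total_variance, 0.6)
  expect_error(pool_rubin(1, 1), "m >= 2")
})

test_that("baseline table dispatches chi-square, ANOVA and Kruskal-Wallis", {
  dat <- data.frame(arm = rep(c("A", "B"), each = 4),
                    sex = c("F", "F", "M", "M", "F", "F", "M", "M"),
                    age = c(60, 61, 62, 63, 60, 61, 62, 63),
                    tg = c(1, 2, 3, 10, 1.5, 2.5, 3.5, 9))
  res <- baseline_table_tests(dat, "arm", skewed = "tg")
  expect_equal(res$test[res$variable == "sex"], "chi-square")
  expect_equal(res$test[res$variable == "age"], "one-way ANOVA")
  expect_equal(res$test[res$variable == "tg"], "Kruskal-Wallis")
  # balanced 2x2 table: chi-square 0, p 1
  expect_equal(res$statistic[res$variable == "sex"], 0)
  expect_equal(res$p[res$variable == "sex"], 1)
  # two-group Kruskal-Wallis agrees with Mann-Whitney decisions
  set.seed(9)
  agree <- replicate(50, {
    x <- rnorm(12); y <- rnorm(12, sample(c(0, 1.5), 1))
    kw <- kruskal.test(list(x, y))$p.value
    mw <- mann_whitney_u(x, y)$p
    (kw < 0.05) == (mw < 0.05)
  })
  expect_gte(mean(agree), 0.95)
  # ANOVA p uniform under the null
  set.seed(10)
  ps <- replicate(200, {
    d <- data.frame(arm = rep(c("A", "B", "C"), each = 10),
                    v = rnorm(30))
    baseline_table_tests(d, "arm")$p[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
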