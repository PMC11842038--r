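test_that("correlation method is gated on normality", {
  set.seed(1)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  expect_equal(correlation_auto(x, y)$method, "pearson")
  skewed <- exp(rnorm(60, sd = 1.5))
  expect_equal(correlation_auto(skewed, y)$method, "spearman")
  # perfectly monotone nonlinear pair: rank correlation exactly 1
  z <- exp(seq(1, 5, length.out = 30))
  mono <- correlation_auto(z, z^3)
  expect_equal(mono$estimate, 1)
  expect_error(correlation_auto(rep(1, 10), rnorm(10)), "constant")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.3, 18), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.4), 1), c(0.2, 0.4))
  p <- c(0.001, 0.01, 0.2)
  expect_true(all(diff(bonferroni_adjust(p, 5)) >= 0))  # monotone
})

test_that("partially-overlapping t-test nests its limiting cases", {
  set.seed(2)
  pre <- rnorm(10); post <- rnorm(10, 0.3)
  # all-paired limit: Welch-type form equals the paired t exactly
  pt <- t.test(pre, post, paired = TRUE)
  po <- pos_ttest(pre, post, var_equal = FALSE)
  expect_equal(po$statistic, unname(pt$statistic), tolerance = 1e-8)
  expect_equal(po$df, unname(pt$parameter), tolerance = 1e-8)
  # no-pairs limit: pooled form equals Student, Welch form equals Welch
  a <- rnorm(12); b <- rnorm(9, 0.5)
  st <- t.test(a, b, var.equal = TRUE)
  po2 <- pos_ttest(pre_only = a, post_only = b, var_equal = TRUE)
  expect_equal(po2$statistic, unname(st$statistic), tolerance = 1e-8)
  expect_equal(po2$df, unname(st$parameter), tolerance = 1e-8)
  wt <- t.test(a, b)
  po3 <- pos_ttest(pre_only = a, post_only = b, var_equal = FALSE)
  expect_equal(po3$statistic, unname(wt$statistic), tolerance = 1e-8)
  expect_equal(po3$df, unname(wt$parameter), tolerance = 1e-8)
})

test_that("mixed-design pos_ttest detects a true shift", {
  set.seed(3)
  base <- rnorm(3)
  res <- pos_ttest(base + rnorm(3, sd = 0.3),
                   base + 2 + rnorm(3, sd = 0.3),
                   rnorm(11), rnorm(4, 2))
  expect_lt(res$p.value, 0.01)
  expect_lt(res$statistic, 0)
  expect_equal(unname(res$n), c(14, 7, 3))
})

test_that("residualization is exactly orthogonal to the covariate", {
  set.seed(4)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  r <- residualize(y, x)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * (x - mean(x)))), 1e-8)
  expect_equal(residualize(2 * x, x), rep(0, 50), tolerance = 1e-10)
  yy <- rnorm(30)
  expect_equal(residualize(yy, rep(0:1, 15) * 0 + seq(30))[1:30],
               unname(resid(lm(yy ~ seq(30)))), tolerance = 1e-12)
  # hand-computed 5-point OLS
  xh <- c(1, 2, 3, 4, 5); yh <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  beta <- sum((xh - 3) * (yh - mean(yh))) / sum((xh - 3)^2)
  expect_equal(residualize(yh, xh),
               unname(yh - (mean(yh) - beta * 3) - beta * xh),
               tolerance = 1e-10)
  expect_error(residualize(yh, rep(2, 5)), "constant")
})

test_that("regression reports coefficients, fit and diagnostics", {
  set.seed(5)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 2 * d$x1 - 3 * d$x2 + rnorm(n)
  fit <- fit_linear_models(d, "y", c("x1", "x2"))
  expect_equal(unname(fit$coefficients[, 1]), c(1, 2, -3), tolerance = 0.3)
  expect_true(all(abs(fit$coefficients[2:3, 1] - c(2, -3)) <
                    3 * fit$coefficients[2:3, 2]))
  expect_true(all(fit$vif < 1.2))         # independent standardized predictors
  expect_gt(fit$adj_r_squared, 0.8)
  expect_true(fit$durbin_watson > 1 && fit$durbin_watson < 3)
  fit_int <- fit_linear_models(d, "y", c("x1", "x2"), interaction = TRUE)
  expect_equal(nrow(fit_int$coefficients), 4)
  # null interaction term is not systematically significant
  set.seed(6)
  pvals <- replicate(200, {
    dd <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
    dd$y <- dd$x1 + dd$x2 + rnorm(40)
    f <- fit_linear_models(dd, "y", c("x1", "x2"), interaction = TRUE)
    f$coefficients["x1:x2", 4]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(fit_linear_models(d, "y", c("x1", "x1")), "degenerate|rank")
})

test_that("commonality components satisfy the all-subsets identity", {
  set.seed(7)
  n <- 120
  # brute-force identity for 2 predictors
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n)
  y <- x1 + x2 + rnorm(n)
  cm <- commonality(y, data.frame(x1, x2))
  r2_1 <- summary(lm(y ~ x1))$r.squared
  r2_2 <- summary(lm(y ~ x2))$r.squared
  r2_12 <- summary(lm(y ~ x1 + x2))$r.squared
  expect_equal(cm$r2[cm$component == "unique: x1"], r2_12 - r2_2,
               tolerance = 1e-10)
  expect_equal(cm$r2[cm$component == "unique: x2"], r2_12 - r2_1,
               tolerance = 1e-10)
  expect_equal(cm$r2[cm$component == "common: x1 & x2"],
               r2_1 + r2_2 - r2_12, tolerance = 1e-10)
  expect_equal(sum(cm$r2), r2_12, tolerance = 1e-10)
  expect_equal(sum(cm$pct_of_total), 100, tolerance = 1e-8)

  # orthogonal predictors: no common variance
  x1o <- rep(c(-1, 1), n / 2); x2o <- rep(c(-1, 1), each = n / 2)
  yo <- x1o + 2 * x2o + rnorm(n)
  cmo <- commonality(yo, data.frame(x1 = x1o, x2 = x2o))
  expect_equal(cmo$r2[3], 0, tolerance = 0.02)

  # three predictors: for any predictor set A, the components whose subsets
  # intersect A must sum to R^2(A) (checked by brute-force subset R^2)
  x3 <- 0.3 * x1 + rnorm(n)
  cm3 <- commonality(y, data.frame(x1, x2, x3))
  full <- summary(lm(y ~ x1 + x2 + x3))$r.squared
  expect_equal(sum(cm3$r2), full, tolerance = 1e-10)
  touches <- function(A) vapply(strsplit(sub("^[a-z]+: ", "", cm3$component),
                                         " & "), function(s)
    length(intersect(s, A)) > 0, logical(1))
  expect_equal(sum(cm3$r2[touches("x1")]),
               summary(lm(y ~ x1))$r.squared, tolerance = 1e-10)
  expect_equal(sum(cm3$r2[touches(c("x1", "x3"))]),
               summary(lm(y ~ x1 + x3))$r.squared, tolerance = 1e-10)
  # duplicated predictor: all variance is common
  cmd <- commonality(y, data.frame(a = x1, b = x1 + 1e-9 * rnorm(n)))
  expect_lt(abs(cmd$r2[1]), 1e-6)
  expect_lt(abs(cmd$r2[2]), 1e-6)
})

test_that("dB/microvolt conversion is exact", {
  expect_equal(db_to_microvolt(0), 1)
  expect_equal(db_to_microvolt(-20), 0.1)
  expect_equal(db_to_microvolt(6.0206), 2, tolerance = 1e-4)
  expect_equal(microvolt_to_db(db_to_microvolt(-7.3)), -7.3, tolerance = 1e-12)
})

test_that("piecewise growth fit identifies slopes and knee", {
  lev <- seq(20, 80, 5)
  truth <- ifelse(lev < 60, 0.01 * (lev - 60), 0.002 * (lev - 60)) + 0.1
  fit <- fit_piecewise_growth(lev, truth)
  expect_equal(fit$knee, 60)
  expect_equal(fit$slope_below, 0.01, tolerance = 1e-8)
  expect_equal(fit$slope_above, 0.002, tolerance = 1e-8)
  # a single line gives equal slopes at any knee
  line <- 0.004 * lev + 0.05
  fl <- fit_piecewise_growth(lev, line, knee = 60)
  expect_equal(fl$slope_below, fl$slope_above, tolerance = 1e-8)
  # noisy recovery of the shallow upper slope
  set.seed(8)
  ests <- replicate(50, {
    yy <- truth + rnorm(length(lev), sd = 0.005)
    fit_piecewise_growth(lev, yy, knee = 60)$slope_above
  })
  expect_lt(abs(mean(ests) - 0.002), 0.2 * 0.002 + 3 * sd(ests) / sqrt(50))
})

test_that("group summary reports margins and corrected pairwise tests", {
  co <- generate_cohort(seed = 3)
  gs <- group_summary(co, variables = c("efr_ram", "th_a"))
  expect_equal(nrow(gs$summary), 4 * 2)
  expect_true(all(gs$tests$p_adj >= gs$tests$p - 1e-15))
  expect_true(all(gs$tests$p_adj <= 1))
  # identical groups: t = 0, adjusted p = 1
  dup <- data.frame(group = rep(c("a", "b"), each = 5),
                    v = rep(c(1, 2, 3, 4, 5), 2))
  gd <- group_summary(dup, variables = "v")
  expect_equal(gd$tests$t, 0)
  expect_equal(gd$tests$p_adj, 1)
})
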