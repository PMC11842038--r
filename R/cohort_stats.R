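# Cohort-level statistics: correlation gating, Bonferroni control, the
# partially-overlapping-samples t-test, residualized SRT analysis, multiple
# regression with diagnostics, commonality variance decomposition, group
# summaries, and the piecewise growth reanalysis of EFR level series.

#' Normality-gated correlation
#'
#' Reports the Pearson correlation when both variables pass a Shapiro-Wilk
#' normality test at `alpha`, otherwise the Spearman rank correlation.
#'
#' @param x,y numeric vectors (pairwise complete, n >= 4).
#' @param alpha gate level for the Shapiro-Wilk tests (default 0.05).
#' @return list with `method` ("pearson"/"spearman"), `estimate`, `n`, `p`,
#'   and the two normality p-values used for gating.
#' @export
correlation_auto <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  method <- if (swx > alpha && swy > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method,
                    exact = if (method == "spearman") FALSE else NULL))
  list(method = method, estimate = unname(ct$estimate), n = length(x),
       p = ct$p.value, shapiro_p = c(x = swx, y = swy))
}

#' Bonferroni adjustment for a stated family size
#'
#' `p_adj = min(1, p * m)`; unlike [stats::p.adjust()] the family size `m`
#' can exceed the number of p-values supplied (as when a correction factor is
#' fixed per figure).
#'
#' @param p p-value(s).
#' @param m family size, >= 1 (default: number of p-values).
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, p * m)
}

#' Partially-overlapping-samples t-test
#'
#' Compares two samples that share some paired observations and additionally
#' contain independent (unpaired) observations on either side, using the
#' Derrick-Toher-White statistic. With `var_equal = TRUE` the pooled-variance
#' form is used; with `FALSE` the Welch-type form. In the all-paired limit
#' the Welch-type statistic equals the paired t-test exactly; with no pairs
#' both forms reduce to the corresponding independent-samples t-test.
#'
#' @param pre_paired,post_paired paired observations (equal length, possibly
#'   length 0).
#' @param pre_only,post_only independent observations in each sample.
#' @param var_equal pooled-variance (`TRUE`, default) or Welch-type form.
#' @return list with `statistic`, `df`, `p.value`, sample means, counts, and
#'   the paired correlation used.
#' @export
pos_ttest <- function(pre_paired = numeric(), post_paired = numeric(),
                      pre_only = numeric(), post_only = numeric(),
                      var_equal = TRUE) {
  if (length(pre_paired) != length(post_paired))
    stop("paired samples must have equal length")
  x1 <- c(pre_paired, pre_only)
  x2 <- c(post_paired, post_only)
  n1 <- length(x1); n2 <- length(x2); n12 <- length(pre_paired)
  na <- n1 - n12; nb <- n2 - n12
  if (n1 < 2 || n2 < 2)
    stop("need at least two observations per side")
  r <- if (n12 >= 2) stats::cor(pre_paired, post_paired) else 0
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  num <- mean(x1) - mean(x2)
  if (var_equal) {
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    stat <- num / (sp * sqrt(1 / n1 + 1 / n2 - 2 * r * n12 / (n1 * n2)))
    df <- if (n12 == 0) n1 + n2 - 2
          else if (na + nb == 0) n12 - 1
          else (n12 - 1) + ((na + nb + n12 - 1) /
                            (na + nb + 2 * (n12 - 1))) * (na + nb)
  } else {
    stat <- num / sqrt(s1^2 / n1 + s2^2 / n2 - 2 * r * n12 * s1 * s2 / (n1 * n2))
    gamma <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    df <- if (n12 == 0) gamma
          else if (na + nb == 0) n12 - 1
          else (n12 - 1) + ((gamma - n12 + 1) /
                            (na + nb + 2 * (n12 - 1))) * (na + nb)
  }
  list(statistic = stat, df = df, p.value = 2 * stats::pt(-abs(stat), df),
       means = c(mean(x1), mean(x2)),
       n = c(n1 = n1, n2 = n2, n_paired = n12),
       r_paired = r, var_equal = var_equal)
}

#' Residualize a response on a covariate
#'
#' Residuals of the ordinary least-squares regression `y ~ x`; zero-mean and
#' exactly orthogonal to `x`, used to correct speech reception thresholds for
#' hearing sensitivity before relating them to the EFR marker.
#'
#' @param y response.
#' @param x covariate (non-constant, n >= 3).
#' @return numeric residual vector.
#' @export
residualize <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (stats::sd(x) == 0) stop("degenerate design: constant covariate")
  unname(stats::resid(stats::lm(y ~ x)))
}

#' Linear regression with the diagnostics battery
#'
#' Ordinary least-squares fit of a response on one or more predictors,
#' optionally with all pairwise interactions, reporting the coefficient
#' table, adjusted R-squared, the overall F statistic, variance inflation
#' factors (computed on the additive part of the model), the Durbin-Watson
#' statistic and the Shapiro-Wilk p-value of the residuals.
#'
#' @param data data.frame holding the variables.
#' @param response response variable name.
#' @param predictors character vector of predictor names.
#' @param interaction include pairwise interactions (default `FALSE`).
#' @return object of class `srt_lm`.
#' @export
fit_linear_models <- function(data, response, predictors,
                              interaction = FALSE) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  if (anyDuplicated(predictors))
    stop("degenerate design: duplicated predictor")
  if (nrow(data) <= length(predictors) + 1)
    stop("not enough observations for the requested model")
  rhs <- paste(predictors, collapse = if (interaction) " * " else " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit)))
    stop("degenerate design: rank-deficient model matrix")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  vif <- if (length(predictors) >= 2) {
    add_fit <- stats::lm(
      stats::as.formula(paste(response, "~", paste(predictors, collapse = "+"))),
      data = data)
    car::vif(add_fit)
  } else NULL
  dw <- lmtest::dwtest(fit)
  structure(list(model = fit,
                 formula = fml,
                 coefficients = sm$coefficients,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 f_statistic = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE),
                 vif = vif,
                 durbin_watson = unname(dw$statistic),
                 durbin_watson_p = dw$p.value,
                 residual_normality_p = stats::shapiro.test(stats::resid(fit))$p.value),
            class = "srt_lm")
}

#' @export
print.srt_lm <- function(x, ...) {
  cat("Linear model:", deparse(x$formula), "\n")
  cat(sprintf("  adj. R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$adj_r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(round(x$coefficients, 4))
  if (!is.null(x$vif))
    cat("  VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                        collapse = ", "), "\n")
  cat(sprintf("  Durbin-Watson %.3f (p = %.3g); residual normality p = %.3g\n",
              x$durbin_watson, x$durbin_watson_p, x$residual_normality_p))
  invisible(x)
}

# R-squared of y on a subset of predictor columns (empty subset -> 0)
subset_r2 <- function(y, X, idx) {
  if (length(idx) == 0) return(0)
  summary(stats::lm(y ~ ., data = data.frame(X[, idx, drop = FALSE])))$r.squared
}

#' Commonality decomposition of explained variance
#'
#' Partitions the full-model R-squared of `y` on 2 or 3 predictors into the
#' unique contribution of each predictor and the common (shared)
#' contributions of every predictor subset, solving the all-subsets system
#' that requires the components touching any predictor set A to sum to
#' R-squared(A). Components sum exactly to the full-model R-squared and are
#' also reported as percentages of it.
#'
#' @param y response.
#' @param X data.frame or matrix of 2 or 3 predictors.
#' @return object of class `commonality`: data.frame with one row per
#'   predictor subset (`component`, `r2`, `pct_of_total`), plus attribute
#'   `total_r2`.
#' @export
commonality <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2 || p > 3) stop("commonality is implemented for 2 or 3 predictors")
  if (any(vapply(X, stats::sd, numeric(1)) == 0))
    stop("degenerate design: constant predictor")
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  r2 <- vapply(subsets, function(s) subset_r2(y, X, s), numeric(1))
  m <- length(subsets)
  # A[i, j] = 1 when component j's subset intersects subset i
  A <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    A[i, j] <- as.numeric(length(intersect(subsets[[i]], subsets[[j]])) > 0)
  comp <- solve(A, r2)
  labs <- vapply(subsets, function(s)
    paste(colnames(X)[s], collapse = " & "), character(1))
  total <- r2[m]
  out <- data.frame(component = ifelse(lengths(subsets) == 1,
                                       paste("unique:", labs),
                                       paste("common:", labs)),
                    r2 = comp,
                    pct_of_total = 100 * comp / total)
  attr(out, "total_r2") <- total
  class(out) <- c("commonality", "data.frame")
  out
}

#' @export
print.commonality <- function(x, ...) {
  cat(sprintf("Commonality decomposition (total R^2 = %.4f)\n",
              attr(x, "total_r2")))
  df <- as.data.frame(x)
  df$r2 <- round(df$r2, 4)
  df$pct_of_total <- round(df$pct_of_total, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Continuous two-segment (piecewise linear) growth fit
#'
#' Fits `y = a + b_lo * min(x - knee, 0) + b_hi * max(x - knee, 0)` by least
#' squares. With `knee = NULL` every interior grid level with at least two
#' points per side is tried and the knee minimizing the residual sum of
#' squares is kept — the form used for EFR amplitude growth with a
#' compression knee-point near 60 dB SPL.
#'
#' @param levels stimulus levels, dB SPL.
#' @param amplitudes response amplitudes (uV, or dB per configuration).
#' @param knee fixed knee level, or `NULL` to scan the level grid.
#' @return list with `slope_below`, `slope_above` (per dB), `knee`,
#'   `intercept` (fitted value at the knee), `fitted`, and `rss`.
#' @export
fit_piecewise_growth <- function(levels, amplitudes, knee = NULL) {
  stopifnot(length(levels) == length(amplitudes))
  fit_at <- function(k) {
    lo <- pmin(levels - k, 0)
    hi <- pmax(levels - k, 0)
    if (sum(levels < k) < 2 || sum(levels > k) < 2) return(NULL)
    f <- stats::lm(amplitudes ~ lo + hi)
    list(k = k, fit = f, rss = sum(stats::resid(f)^2))
  }
  if (is.null(knee)) {
    cands <- sort(unique(levels))
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0) stop("need at least 2 points on each side of a knee")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  } else {
    best <- fit_at(knee)
    if (is.null(best)) stop("need at least 2 points on each side of the knee")
  }
  cf <- stats::coef(best$fit)
  list(slope_below = unname(cf["lo"]), slope_above = unname(cf["hi"]),
       knee = best$k, intercept = unname(cf["(Intercept)"]),
       fitted = unname(stats::fitted(best$fit)), rss = best$rss)
}

#' Per-group summaries with Bonferroni-corrected pairwise tests
#'
#' Mean and SD per group and variable, plus independent-samples Student
#' t-tests between every pair of groups for each variable, Bonferroni
#' adjusted.
#'
#' @param cohort a `cohort_table` (or any data.frame with a `group` column).
#' @param variables variable names to summarise (default: all numeric
#'   columns).
#' @param m Bonferroni family size (default: the number of pairwise tests
#'   performed).
#' @return list with `summary` (group x variable means/SDs) and `tests`
#'   (pairwise t statistics with raw and adjusted p).
#' @export
group_summary <- function(cohort, variables = NULL, m = NULL) {
  stopifnot("group" %in% names(cohort))
  if (is.null(variables))
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  groups <- unique(as.character(cohort$group))
  if (length(groups) < 2) stop("need at least two groups")
  if (any(table(cohort$group) < 2)) stop("every group needs >= 2 members")
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- cohort[cohort$group == g, variables, drop = FALSE]
    data.frame(group = g, variable = variables,
               n = nrow(sub),
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)),
               row.names = NULL)
  }))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- cohort[cohort$group == pr[1], v]
      b <- cohort[cohort$group == pr[2], v]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(variable = v, group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, row.names = NULL)
    }))
  }))
  tests$p_adj <- bonferroni_adjust(tests$p, m %||% nrow(tests))
  list(summary = summ, tests = tests)
}
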