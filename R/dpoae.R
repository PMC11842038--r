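# DPOAE growth functions and bootstrapped threshold extraction.
#
# The distortion-component level L_DC grows monotonically (or saturates) with
# the primary level L2.  The threshold TH_DP is the L2 at which a
# monotonicity-constrained cubic, fitted to resampled L_DC points, reaches a
# fixed criterion level (-25 dB SPL), extrapolation below the lowest measured
# level permitted.  The median over bootstrap draws is reported.

#' Scissors-paradigm primary level rule
#'
#' `L1 = 0.4 * L2 + 39` (dB SPL).
#'
#' @param L2 primary level(s) L2, dB SPL.
#' @return primary level(s) L1, dB SPL.
#' @export
scissors_l1 <- function(L2) 0.4 * L2 + 39

#' DPOAE growth function container
#'
#' @param L2 strictly increasing primary levels, dB SPL.
#' @param Ldc_mean mean distortion-component levels, dB SPL.
#' @param Ldc_sd per-point standard deviations, dB.
#' @param f2 probe frequency, Hz.
#' @param ratio f2/f1 primary ratio.
#' @return object of class `dp_growth`.
#' @export
dp_growth <- function(L2, Ldc_mean, Ldc_sd, f2 = 4000, ratio = 1.2) {
  if (length(L2) < 4) stop("a growth function needs at least 4 points")
  if (any(diff(L2) <= 0)) stop("L2 must be strictly increasing")
  if (length(Ldc_mean) != length(L2) || length(Ldc_sd) != length(L2))
    stop("L2, Ldc_mean and Ldc_sd must have equal length")
  if (any(Ldc_sd < 0)) stop("Ldc_sd must be non-negative")
  structure(list(L2 = L2, Ldc_mean = Ldc_mean, Ldc_sd = Ldc_sd,
                 f2 = f2, ratio = ratio),
            class = "dp_growth")
}

#' @export
print.dp_growth <- function(x, ...) {
  cat(sprintf("DPOAE growth function at f2 = %g Hz (f2/f1 = %g), %d points\n",
              x$f2, x$ratio, length(x$L2)))
  print(data.frame(L2_dB = x$L2, Ldc_dB = x$Ldc_mean, Ldc_sd_dB = x$Ldc_sd),
        row.names = FALSE)
  invisible(x)
}

#' Distortion-component level by least-squares-fit filtering
#'
#' Estimates the amplitude of the component at `target_freq` by fitting
#' `a*cos + b*sin` in the least-squares sense over consecutive windows of
#' width `1/bandwidth` seconds (a sharp LSF filter of the stated bandwidth),
#' averaging the window amplitudes, and expressing the result in dB SPL
#' re 20 uPa RMS.
#'
#' @param pressure recorded pressure, Pa.
#' @param fs sampling rate, Hz.
#' @param target_freq component frequency, Hz.
#' @param bandwidth filter bandwidth, Hz (default 2).
#' @return component level, dB SPL.
#' @export
lsf_component_level <- function(pressure, fs, target_freq, bandwidth = 2) {
  if (target_freq >= fs / 2) stop("target frequency above Nyquist")
  nw <- round(fs / bandwidth)
  if (length(pressure) < nw)
    stop("record shorter than one filter window (1/bandwidth s)")
  n_win <- floor(length(pressure) / nw)
  amps <- vapply(seq_len(n_win), function(i) {
    x <- pressure[((i - 1) * nw + 1):(i * nw)]
    t <- (seq_len(nw) - 1) / fs
    C <- cos(2 * pi * target_freq * t)
    S <- sin(2 * pi * target_freq * t)
    # closed-form least squares for [C S] regressors
    M <- rbind(c(sum(C * C), sum(C * S)), c(sum(C * S), sum(S * S)))
    v <- c(sum(C * x), sum(S * x))
    ab <- solve(M, v)
    sqrt(sum(ab^2))
  }, numeric(1))
  amp <- mean(amps)
  20 * log10((amp / sqrt(2)) / 20e-6)
}

#' Endpoint elimination to enforce monotone growth
#'
#' Iteratively removes the outermost point at whichever end participates in a
#' decreasing adjacent pair until the retained L_DC sequence is
#' non-decreasing. Interior points are never removed: a dip that endpoint
#' removal cannot fix, or fewer than 3 surviving points, is a failure.
#'
#' @param L2 primary levels (increasing).
#' @param Ldc distortion-component levels.
#' @return list with `keep` (retained indices into the input) and `ok`
#'   (logical; `FALSE` flags an irrecoverably non-monotone draw).
#' @export
enforce_monotonicity <- function(L2, Ldc) {
  stopifnot(length(L2) == length(Ldc), length(L2) >= 4)
  keep <- seq_along(Ldc)
  repeat {
    y <- Ldc[keep]
    dec <- which(diff(y) < 0)
    if (length(dec) == 0) return(list(keep = keep, ok = TRUE))
    if (length(keep) <= 3) return(list(keep = keep, ok = FALSE))
    if (dec[1] == 1) {                      # first pair decreasing
      keep <- keep[-1]
    } else if (dec[length(dec)] == length(y) - 1) {  # last pair decreasing
      keep <- keep[-length(keep)]
    } else {
      return(list(keep = keep, ok = FALSE)) # interior dip: forbidden
    }
  }
}

# least-squares polynomial fit in a centered variable, returned as raw
# coefficients c0..c3 in L2; centering keeps the normal equations
# well-conditioned over typical 30-60 dB level ranges
fit_poly_raw <- function(x, y, degree) {
  xc <- mean(x)
  X <- outer(x - xc, 0:degree, `^`)
  cc <- qr.solve(X, y)
  # expand sum cc_j (x - xc)^j into powers of x
  out <- numeric(degree + 1)
  for (j in 0:degree) {
    for (i in 0:j) {
      out[i + 1] <- out[i + 1] + cc[j + 1] * choose(j, i) * (-xc)^(j - i)
    }
  }
  c(out, rep(0, 3 - degree))
}

poly_eval <- function(coefs, x) {
  coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
}

is_nondecreasing_poly <- function(coefs, lo, hi, tol = 1e-9) {
  g <- seq(lo, hi, length.out = 201)
  d <- coefs[2] + 2 * coefs[3] * g + 3 * coefs[4] * g^2
  all(d >= -tol * max(1, max(abs(coefs))))
}

#' Monotonicity-constrained cubic fit to a growth function
#'
#' Least-squares cubic polynomial `Ldc(L2)` through the retained points,
#' accepted only when non-decreasing over the retained level range (the
#' "adapted cubic": an ordinary cubic with the monotonicity constraint
#' enforced by rejection). With exactly 3 retained points a quadratic is
#' fitted (a cubic would be underdetermined) and the remaining coefficient is
#' zero.
#'
#' @param L2 retained primary levels.
#' @param Ldc retained distortion-component levels.
#' @return list with `coefficients` (c0..c3 of the raw-polynomial in L2),
#'   `monotone` (logical), and `range` (retained L2 range). A non-monotone
#'   least-squares solution is returned with `monotone = FALSE` so callers can
#'   reject the draw.
#' @export
fit_adapted_cubic <- function(L2, Ldc) {
  stopifnot(length(L2) == length(Ldc), length(L2) >= 3)
  degree <- min(3, length(L2) - 1)
  coefs <- fit_poly_raw(L2, Ldc, degree)
  list(coefficients = coefs,
       monotone = is_nondecreasing_poly(coefs, min(L2), max(L2)),
       range = range(L2))
}

# L2 in [min(L2)-extrapolate, max(L2)] at which the growth branch reaches
# `criterion`: walking down from the top of the (monotone) fitted range, the
# first point where the curve drops below the criterion.  This ignores
# spurious re-crossings from the cubic's tail behaviour far below the
# measured range.  NA when the curve never reaches the criterion.
threshold_from_fit <- function(coefs, L2_range, criterion, extrapolate = 30) {
  lo <- L2_range[1] - extrapolate
  hi <- L2_range[2]
  g <- seq(lo, hi, length.out = 2001)
  v <- poly_eval(coefs, g) - criterion
  if (v[length(v)] < 0) return(NA_real_)   # never reaches the criterion
  below <- which(v < 0)
  if (length(below) == 0) {
    exact <- which(v == 0)
    if (length(exact)) return(g[min(exact)])
    return(NA_real_)                       # above criterion everywhere
  }
  i <- max(below)                          # first drop below, seen from above
  if (i == length(v)) return(NA_real_)
  stats::uniroot(function(x) poly_eval(coefs, x) - criterion,
                 c(g[i], g[i + 1]), tol = 1e-10)$root
}

#' Bootstrapped DPOAE threshold estimate
#'
#' Per bootstrap draw, L_DC points are resampled from per-point Gaussians
#' (truncated at +/- 1.96 SD, i.e. draws constrained to each point's 95%
#' confidence interval), monotone growth is enforced by endpoint elimination,
#' a monotonicity-constrained cubic is fitted, and the threshold is the
#' smallest L2 at which the (possibly extrapolated) fitted curve reaches the
#' criterion level. Draws whose fit fails any constraint are discarded and
#' counted. TH_DP is the median over valid draws; its SD is the SD over valid
#' draws.
#'
#' @param growth a [dp_growth()] object.
#' @param n_boot bootstrap draws (default 500).
#' @param criterion threshold criterion, dB SPL (default -25).
#' @param extrapolate furthest extrapolation below the lowest measured L2, dB
#'   (default 30); bounds runaway extrapolation of the cubic.
#' @param seed integer seed.
#' @return object of class `dpoae_fit` with `th_dp` (dB SPL), `sd`,
#'   `n_valid`, `n_boot`, `criterion`, per-draw thresholds, the cubic fitted
#'   to the mean points, and the input growth function. When no draw yields a
#'   threshold, `th_dp` is `NA` with a diagnostic count.
#' @export
dpoae_fit <- function(growth, n_boot = 500, criterion = -25,
                      extrapolate = 30, seed = 1) {
  stopifnot(inherits(growth, "dp_growth"), n_boot >= 1)
  set.seed(seed)
  k <- length(growth$L2)
  # truncated-normal draws via inverse CDF restricted to +/-1.96 SD
  plo <- stats::pnorm(-1.96); phi <- stats::pnorm(1.96)
  ths <- rep(NA_real_, n_boot)
  n_reject_mono <- 0L
  n_reject_fit <- 0L
  for (b in seq_len(n_boot)) {
    z <- stats::qnorm(stats::runif(k, plo, phi))
    ldc <- growth$Ldc_mean + z * growth$Ldc_sd
    mono <- enforce_monotonicity(growth$L2, ldc)
    if (!mono$ok) { n_reject_mono <- n_reject_mono + 1L; next }
    fit <- fit_adapted_cubic(growth$L2[mono$keep], ldc[mono$keep])
    if (!fit$monotone) { n_reject_fit <- n_reject_fit + 1L; next }
    ths[b] <- threshold_from_fit(fit$coefficients, fit$range, criterion,
                                 extrapolate)
  }
  valid <- ths[!is.na(ths)]
  mean_fit <- fit_adapted_cubic(growth$L2, growth$Ldc_mean)
  structure(list(th_dp = if (length(valid)) stats::median(valid) else NA_real_,
                 sd = if (length(valid) > 1) stats::sd(valid) else 0,
                 n_valid = length(valid),
                 n_boot = n_boot,
                 n_reject_monotonicity = n_reject_mono,
                 n_reject_fit = n_reject_fit,
                 criterion = criterion,
                 extrapolate = extrapolate,
                 thresholds = ths,
                 mean_fit = mean_fit,
                 growth = growth,
                 seed = seed),
            class = "dpoae_fit")
}

#' @export
print.dpoae_fit <- function(x, ...) {
  cat("Bootstrapped DPOAE threshold\n")
  if (is.na(x$th_dp)) {
    cat(sprintf("  no threshold: 0 of %d draws crossed %g dB SPL (%d monotonicity, %d fit rejections)\n",
                x$n_boot, x$criterion,
                x$n_reject_monotonicity, x$n_reject_fit))
  } else {
    cat(sprintf("  TH_DP = %.2f dB SPL (SD %.2f) at the %g dB SPL criterion\n",
                x$th_dp, x$sd, x$criterion))
    cat(sprintf("  %d of %d bootstrap draws valid\n", x$n_valid, x$n_boot))
  }
  invisible(x)
}

#' @export
summary.dpoae_fit <- function(object, ...) {
  out <- unclass(object)[c("th_dp", "sd", "n_valid", "n_boot",
                           "n_reject_monotonicity", "n_reject_fit",
                           "criterion")]
  out$threshold_quartiles <- stats::quantile(object$thresholds, na.rm = TRUE)
  class(out) <- "summary.dpoae_fit"
  out
}

#' @export
print.summary.dpoae_fit <- function(x, ...) {
  cat(sprintf("TH_DP = %.2f dB SPL (SD %.2f), criterion %g dB SPL\n",
              x$th_dp, x$sd, x$criterion))
  cat(sprintf("valid draws: %d/%d (rejected: %d monotonicity, %d fit)\n",
              x$n_valid, x$n_boot, x$n_reject_monotonicity, x$n_reject_fit))
  cat("threshold quartiles (dB SPL):\n")
  print(round(x$threshold_quartiles, 2))
  invisible(x)
}

#' @export
coef.dpoae_fit <- function(object, ...) {
  stats::setNames(object$mean_fit$coefficients, c("c0", "c1", "c2", "c3"))
}

#' Predicted distortion-component level from the mean-point cubic
#'
#' @param object a `dpoae_fit`.
#' @param newdata optional numeric vector of L2 levels; defaults to the
#'   measured levels.
#' @param ... unused.
#' @export
predict.dpoae_fit <- function(object, newdata = NULL, ...) {
  L2 <- newdata %||% object$growth$L2
  poly_eval(object$mean_fit$coefficients, L2)
}

#' @export
plot.dpoae_fit <- function(x, ...) {
  g <- x$growth
  lo <- if (is.na(x$th_dp)) min(g$L2) else min(x$th_dp, g$L2) - 2
  grid <- seq(lo, max(g$L2), length.out = 200)
  graphics::plot(g$L2, g$Ldc_mean, pch = 19,
                 xlim = range(grid), ylim = range(c(g$Ldc_mean, x$criterion)),
                 xlab = "L2 (dB SPL)", ylab = "L_DC (dB SPL)",
                 main = "DPOAE growth and bootstrapped threshold", ...)
  graphics::arrows(g$L2, g$Ldc_mean - g$Ldc_sd, g$L2, g$Ldc_mean + g$Ldc_sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(grid, poly_eval(x$mean_fit$coefficients, grid), col = "grey40")
  graphics::abline(h = x$criterion, lty = 3)
  if (!is.na(x$th_dp)) graphics::abline(v = x$th_dp, lty = 2, col = "red")
  invisible(x)
}

#' Winsorize low outlying thresholds at the Tukey fence
#'
#' Values below `Q1 - 1.5*IQR` of the sample are replaced by that fence
#' value, avoiding high-leverage points in downstream regressions.
#'
#' @param values numeric vector (length >= 4) of thresholds, dB SPL.
#' @return list with `values` (adjusted), `fence`, and `n_replaced`.
#' @export
winsorize_low_thresholds <- function(values) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  fence <- q[1] - 1.5 * (q[2] - q[1])
  low <- values < fence
  values[low] <- fence
  list(values = values, fence = fence, n_replaced = sum(low))
}
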