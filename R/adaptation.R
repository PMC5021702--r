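#' Continuous firing rate (cFR)
#'
#' Exponentially smoothed instantaneous firing rate, updated at every
#' spike:
#' \deqn{cFR(t) = d \cdot cFR(t - \Delta t) + (1 - d) / \Delta t,}
#' where \eqn{\Delta t} is the interval since the previous spike and
#' \eqn{d = e^{-\Delta t / \tau}} is the exponential decay term. The rate
#' at the first spike is initialised to 0 Hz. For a constant inter-spike
#' interval the recursion converges to exactly \eqn{1/\Delta t}.
#'
#' @param spike_times Strictly increasing spike times in seconds.
#' @param tau Decay constant in seconds (default 0.1).
#' @return A data.frame of class `cfr_series` with columns `time_s`, `cfr_hz`
#'   and `d` (the per-spike decay term; `NA` for the first spike).
#' @export
continuous_firing_rate <- function(spike_times, tau = 0.1) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  n <- length(spike_times)
  if (n == 0)
    return(structure(data.frame(time_s = numeric(0), cfr_hz = numeric(0),
                                d = numeric(0)),
                     class = c("cfr_series", "data.frame"), tau = tau))
  dt <- diff(spike_times)
  if (any(dt <= 0)) stop("spike_times must be strictly increasing")
  cfr <- numeric(n)
  d <- c(NA_real_, exp(-dt / tau))
  cfr[1] <- 0
  for (i in seq_len(n - 1L)) {
    cfr[i + 1L] <- d[i + 1L] * cfr[i] + (1 - d[i + 1L]) / dt[i]
  }
  structure(data.frame(time_s = spike_times, cfr_hz = cfr, d = d),
            class = c("cfr_series", "data.frame"), tau = tau)
}

# AR (percent) from exponential-fit parameters: the percent change of the
# feature between its zero-rate baseline (y_c + y_inf) and its high-rate
# asymptote (y_inf, for b < 0).
adaptation_rate <- function(y_c, y_inf) {
  if (abs(y_inf + y_c) < 1e-9) return(NA_real_)
  (y_inf / (y_inf + y_c) - 1) * 100
}

#' Fit the exponential spike-shape adaptation model
#'
#' Fits \eqn{g(x) = y_c e^{b x} + y_\infty} to per-spike feature values
#' against the continuous firing rate by least squares, and derives the
#' adaptation rate
#' \deqn{AR = \left(\frac{y_\infty}{y_\infty + y_c} - 1\right) \times 100\%.}
#' A reduction of the feature at high rates (e.g. spike amplitude shrinking
#' during bursts) gives negative AR; a growth (spike widening) gives
#' positive AR. Amplitudes should be passed as magnitudes (`abs()`) so the
#' sign convention holds.
#'
#' The nonlinear fit uses `minpack.lm::nlsLM` with 5 starting values of
#' `b` spread geometrically over the range scaled to the observed cFR
#' span, `y_inf` initialised at the high-rate feature mean; the best-RSS
#' converged start wins. Two identifiability guards apply. First, `b` is
#' bounded so the exponential decays at least twofold across twice the
#' observed cFR range: for slower decay the asymptote `y_inf` (and hence
#' AR) would be pure extrapolation, and near `b = 0` the model is
#' collinear with its own intercept. Second, the exponential must beat
#' the constant model `g(x) = mean(y)` in an F-test at p < 0.01;
#' otherwise the feature is reported as rate-independent (`y_c = 0`,
#' AR = 0). If no start converges the result is flagged missing.
#'
#' @param feature Per-spike feature values (same length as `cfr`).
#' @param cfr Per-spike continuous firing rate, Hz.
#' @param feature_name Label stored in the result.
#' @param exclude_first Drop the first (cFR = 0, uninitialised) spike from
#'   the fit. Default TRUE.
#' @param bins If not `NULL`, average the feature within this many
#'   equal-count cFR bins before fitting instead of fitting per-spike
#'   scatter.
#' @return Object of class `adaptation_fit` with elements `y_c`, `b`,
#'   `y_inf`, `ar_percent`, `rss`, `n`, `feature_name`, `converged`, and the
#'   data used. Methods: `print`, `coef`, `predict`, `residuals`, `plot`.
#' @export
fit_adaptation <- function(feature, cfr, feature_name = "feature",
                           exclude_first = TRUE, bins = NULL) {
  if (inherits(cfr, "cfr_series")) cfr <- cfr$cfr_hz
  if (length(feature) != length(cfr))
    stop("feature and cfr must have equal length")
  ok <- is.finite(feature) & is.finite(cfr)
  if (exclude_first && length(ok) > 0) ok[1] <- FALSE
  x <- cfr[ok]; y <- feature[ok]
  if (length(x) < 10) stop("need at least 10 (cfr, feature) pairs")
  if (max(x) < 2 * max(min(x), 1e-12))
    warning("cFR range spans less than a factor of 2; fit may be ill-posed")

  if (!is.null(bins)) {
    q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    g <- cut(x, q, include.lowest = TRUE)
    y <- tapply(y, g, mean); x <- tapply(x, g, mean)
    keep <- is.finite(x) & is.finite(y)
    x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  }

  xr <- max(x) - min(x)
  if (xr <= 0) stop("cfr values are constant; cannot fit")
  low <- y[x <= stats::quantile(x, 0.2)]
  y_inf0 <- mean(y[x >= stats::quantile(x, 0.8)])
  y_c0 <- mean(low) - y_inf0
  b_hi <- -log(2) / (2 * xr)      # at least twofold decay over 2x range
  b_lo <- -100 / xr

  nobs <- length(x)
  rss0 <- sum((y - mean(y))^2)    # constant (rate-independent) model
  constant_fit <- function(p_vs_constant) {
    out <- list(y_c = 0, b = 0, y_inf = mean(y), ar_percent = 0,
                rss = rss0, n = nobs, feature_name = feature_name,
                converged = TRUE, p_vs_constant = p_vs_constant,
                data = data.frame(cfr_hz = x, feature = y))
    class(out) <- "adaptation_fit"
    out
  }

  best <- NULL
  for (b0 in c(-30, -10, -3, -1, -0.4) / xr) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y_c * exp(b * x) + y_inf,
                        start = list(y_c = y_c0, b = max(min(b0, b_hi), b_lo),
                                     y_inf = y_inf0),
                        lower = c(-Inf, b_lo, -Inf),
                        upper = c(Inf, b_hi, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    # fall back to Nelder-Mead on the same objective (b kept in bounds)
    obj <- function(p) {
      if (p[2] < b_lo || p[2] > b_hi) return(Inf)
      sum((y - (p[1] * exp(p[2] * x) + p[3]))^2)
    }
    op <- tryCatch(stats::optim(c(y_c0, -3 / xr, y_inf0), obj),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value)) {
      out <- list(y_c = NA_real_, b = NA_real_, y_inf = NA_real_,
                  ar_percent = NA_real_, rss = NA_real_, n = nobs,
                  feature_name = feature_name, converged = FALSE,
                  p_vs_constant = NA_real_,
                  data = data.frame(cfr_hz = x, feature = y))
      class(out) <- "adaptation_fit"
      return(out)
    }
    pars <- c(y_c = op$par[1], b = op$par[2], y_inf = op$par[3])
    rss <- op$value
  } else {
    pars <- stats::coef(best$fit)
    rss <- best$rss
  }

  # does rate dependence explain significantly more than a constant?
  if (rss0 <= 0 || rss >= rss0) return(constant_fit(1))
  fstat <- ((rss0 - rss) / 2) / (rss / (nobs - 3))
  p_const <- stats::pf(fstat, 2, nobs - 3, lower.tail = FALSE)
  if (!is.finite(p_const) || p_const >= 0.01) return(constant_fit(p_const))

  out <- list(y_c = unname(pars["y_c"]), b = unname(pars["b"]),
              y_inf = unname(pars["y_inf"]),
              ar_percent = adaptation_rate(unname(pars["y_c"]),
                                           unname(pars["y_inf"])),
              rss = rss, n = nobs, feature_name = feature_name,
              converged = TRUE, p_vs_constant = p_const,
              data = data.frame(cfr_hz = x, feature = y))
  class(out) <- "adaptation_fit"
  out
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("Spike-shape adaptation fit: %s (n = %d spikes)\n",
              x$feature_name, x$n))
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  g(x) = y_c * exp(b x) + y_inf\n"))
  cat(sprintf("  y_c = %.4g   b = %.4g /Hz   y_inf = %.4g   (RSS %.4g)\n",
              x$y_c, x$b, x$y_inf, x$rss))
  cat(sprintf("  adaptation rate AR = %.2f%%\n", x$ar_percent))
  invisible(x)
}

#' @export
coef.adaptation_fit <- function(object, ...) {
  c(y_c = object$y_c, b = object$b, y_inf = object$y_inf)
}

#' @export
predict.adaptation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$cfr_hz
       else if (is.data.frame(newdata)) newdata$cfr_hz
       else newdata
  object$y_c * exp(object$b * x) + object$y_inf
}

#' @export
residuals.adaptation_fit <- function(object, ...) {
  object$data$feature - predict(object)
}

#' @export
plot.adaptation_fit <- function(x, ...) {
  plot(x$data$cfr_hz, x$data$feature, pch = 16, cex = 0.5,
       col = "grey40", xlab = "cFR (Hz)", ylab = x$feature_name, ...)
  xs <- seq(min(x$data$cfr_hz), max(x$data$cfr_hz), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  graphics::title(sprintf("%s vs cFR, AR = %.1f%%", x$feature_name,
                          x$ar_percent))
  invisible(x)
}

#' Compare adaptation rates between groups
#'
#' Pairwise two-tailed Mann-Whitney (Wilcoxon rank-sum) tests between the
#' AR distributions of template-type groups, plus boxplot summaries
#' (median, quartiles, whiskers at 1.5 x IQR).
#'
#' @param ar_values Numeric vector of adaptation rates (percent).
#' @param groups Factor/character vector of group labels, same length.
#' @param min_n Minimum group size for inclusion (default 3); smaller
#'   groups are skipped with a warning.
#' @return List with `tests` (data.frame: group_a, group_b, n_a, n_b, U,
#'   p_two_tailed) and `summaries` (per-group median, q1, q3, whiskers, n).
#' @export
compare_groups <- function(ar_values, groups, min_n = 3) {
  ok <- is.finite(ar_values) & !is.na(groups)
  ar_values <- ar_values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_n]
  if (length(keep) < length(sizes))
    warning("skipping undersized groups: ",
            paste(setdiff(names(sizes), keep), collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 groups with >= ", min_n,
                             " values each")
  summaries <- do.call(rbind, lapply(keep, function(g) {
    v <- ar_values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  pairs <- utils::combn(sort(keep), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- ar_values[groups == pairs[1, j]]
    b <- ar_values[groups == pairs[2, j]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               n_a = length(a), n_b = length(b),
               U = unname(wt$statistic), p_two_tailed = wt$p.value)
  }))
  list(tests = tests, summaries = summaries)
}
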