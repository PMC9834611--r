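# Noncompartmental analysis: linear-log trapezoidal AUC and terminal
# half-life by log-linear regression.

#' Concentration-time series
#'
#' Light container for a single concentration-time profile.
#'
#' @param times Sampling times in h, strictly increasing.
#' @param concentrations Concentrations in nM, non-negative, same length.
#' @param tissue Tissue label.
#' @param source Subject or provenance label.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(times, concentrations, tissue = "blood",
                                 source = "sim") {
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 tissue = tissue, source = source),
            class = "concentration_series")
}

as_series <- function(x) {
  if (inherits(x, "concentration_series")) return(x)
  if (inherits(x, "pbpk_simulation")) return(sim_series(x, "blood"))
  stop("expected a concentration_series", call. = FALSE)
}

# Interpolate concentration at time t, consistent with the linear-log
# trapezoidal rule: log interpolation on strictly declining positive
# segments, linear otherwise.
interp_linlog <- function(times, conc, t) {
  vapply(t, function(ti) {
    if (ti <= times[1]) return(conc[1])
    if (ti >= times[length(times)]) return(conc[length(conc)])
    i <- findInterval(ti, times)
    t1 <- times[i]; t2 <- times[i + 1]
    c1 <- conc[i]; c2 <- conc[i + 1]
    if (ti == t1) return(c1)
    w <- (ti - t1) / (t2 - t1)
    if (c1 > c2 && c2 > 0) {
      c1 * (c2 / c1)^w
    } else {
      c1 + w * (c2 - c1)
    }
  }, numeric(1))
}

#' Area under the curve by the linear-log trapezoidal method
#'
#' Per segment, the linear trapezoid `(C1 + C2)/2 * dt` is used when the
#' concentration is rising, flat, or touches zero at either end; the log
#' trapezoid `(C1 - C2) * dt / ln(C1/C2)` is used on strictly declining
#' positive segments. Endpoints `t0`/`t1` falling inside a segment are
#' interpolated consistently with the same rule, so the AUC is additive
#' over adjacent intervals.
#'
#' @param series A [concentration_series()] (or a `pbpk_simulation`, whose
#'   blood profile is used).
#' @param t0,t1 Integration limits in h; default the full series range.
#' @return AUC in nM*h.
#' @export
auc_linlog <- function(series, t0 = NULL, t1 = NULL) {
  s <- as_series(series)
  times <- s$times; conc <- s$concentrations
  if (length(times) < 2) stop("need at least 2 points for AUC", call. = FALSE)
  t0 <- t0 %||% times[1]
  t1 <- t1 %||% times[length(times)]
  if (t1 <= t0) stop("require t1 > t0", call. = FALSE)
  if (t0 < times[1] || t1 > times[length(times)])
    stop("[t0, t1] must lie within the sampled time range", call. = FALSE)

  keep <- times > t0 & times < t1
  tt <- c(t0, times[keep], t1)
  cc <- c(interp_linlog(times, conc, t0), conc[keep],
          interp_linlog(times, conc, t1))

  c1 <- cc[-length(cc)]; c2 <- cc[-1]
  dt <- diff(tt)
  loggy <- c1 > c2 & c2 > 0
  seg <- ifelse(loggy,
                (c1 - c2) * dt / log(ifelse(loggy, c1 / c2, 2)),
                (c1 + c2) / 2 * dt)
  sum(seg)
}

#' Terminal half-life by log-linear regression
#'
#' Fits ordinary least squares of `ln C` against time over a terminal
#' window of positive concentrations after the observed maximum, and
#' reports `t1/2 = ln 2 / (-slope)`. The result is flagged undefined (with
#' a reason, not an error) when fewer than `min_points` usable points exist
#' or when the fitted slope is non-negative, i.e. the terminal elimination
#' phase was not achieved — as happens for a still-accumulating tissue.
#'
#' @param series A [concentration_series()] (or `pbpk_simulation`).
#' @param min_points Minimum (and, for `window = "last_k"`, exact) number
#'   of terminal points used; default 3.
#' @param window Terminal-window rule: `"last_k"` (default) uses the last
#'   `min_points` points; `"best_r2"` scans window sizes from `min_points`
#'   to all points after the maximum and keeps the best-r-squared fit;
#'   `"fraction"` uses all points in the final `fraction` share of the
#'   sampled interval.
#' @param fraction Share of the time range used when `window = "fraction"`.
#' @return An object of class `nca_halflife`: list with `t_half` (h, `NA`
#'   if undefined), `slope`, `r2`, `n_points`, `interval` and `reason`.
#' @export
terminal_half_life <- function(series, min_points = 3,
                               window = c("last_k", "best_r2", "fraction"),
                               fraction = 0.25) {
  s <- as_series(series)
  window <- match.arg(window)
  times <- s$times; conc <- s$concentrations

  undefined <- function(reason, n = 0) {
    structure(list(t_half = NA_real_, slope = NA_real_, r2 = NA_real_,
                   n_points = n, interval = c(NA_real_, NA_real_),
                   reason = reason),
              class = "nca_halflife")
  }
  i_max <- which.max(conc)
  after <- seq_along(times) > i_max & conc > 0
  if (window == "fraction") {
    cutoff <- times[length(times)] - fraction * diff(range(times))
    after <- after & times >= cutoff
  }
  idx <- which(after)
  if (length(idx) < min_points)
    return(undefined("terminal phase not achieved: fewer than min_points usable points after Tmax",
                     length(idx)))

  fit_window <- function(ii) {
    fit <- stats::lm.fit(cbind(1, times[ii]), log(conc[ii]))
    slope <- fit$coefficients[[2]]
    ybar <- mean(log(conc[ii]))
    ss_tot <- sum((log(conc[ii]) - ybar)^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
    list(slope = slope, r2 = r2, ii = ii)
  }

  best <- if (window == "last_k") {
    fit_window(utils::tail(idx, min_points))
  } else if (window == "fraction") {
    fit_window(idx)
  } else {
    cands <- lapply(min_points:length(idx),
                    function(k) fit_window(utils::tail(idx, k)))
    r2s <- vapply(cands, function(x) x$r2 %||% NA_real_, numeric(1))
    cands[[which.max(replace(r2s, is.na(r2s), -Inf))]]
  }

  if (!is.finite(best$slope) || best$slope >= 0)
    return(undefined("terminal phase not achieved: non-negative terminal slope",
                     length(best$ii)))
  structure(list(t_half = log(2) / (-best$slope), slope = best$slope,
                 r2 = best$r2, n_points = length(best$ii),
                 interval = range(times[best$ii]),
                 reason = NA_character_),
            class = "nca_halflife")
}

#' AUC extrapolated to infinity
#'
#' Adds the terminal extrapolation `C_last / lambda_z` to the linear-log
#' trapezoidal AUC over the sampled range.
#'
#' @param series A [concentration_series()].
#' @param ... Passed to [terminal_half_life()].
#' @return AUC from 0 to infinity in nM*h, or `NA` when no terminal phase
#'   is identifiable.
#' @export
auc_inf <- function(series, ...) {
  s <- as_series(series)
  hl <- terminal_half_life(s, ...)
  if (!is.finite(hl$t_half)) return(NA_real_)
  lambda <- log(2) / hl$t_half
  auc_linlog(s) + s$concentrations[length(s$concentrations)] / lambda
}

#' Noncompartmental analysis of one series
#'
#' Convenience wrapper combining [auc_linlog()] and [terminal_half_life()].
#'
#' @param series A [concentration_series()] or `pbpk_simulation`.
#' @param t0,t1 AUC integration limits (defaults: full range).
#' @param ... Passed to [terminal_half_life()].
#' @return A one-row data.frame with tissue, interval, `auc_nM_h`,
#'   `t_half_h`, `n_terminal_points`, `regression_r2` and `reason`.
#' @export
nca <- function(series, t0 = NULL, t1 = NULL, ...) {
  s <- as_series(series)
  hl <- terminal_half_life(s, ...)
  data.frame(
    tissue = s$tissue,
    source = s$source,
    t0 = t0 %||% s$times[1],
    t1 = t1 %||% s$times[length(s$times)],
    auc_nM_h = auc_linlog(s, t0, t1),
    t_half_h = hl$t_half,
    n_terminal_points = hl$n_points,
    regression_r2 = hl$r2,
    reason = hl$reason,
    stringsAsFactors = FALSE
  )
}

#' @export
print.nca_halflife <- function(x, ...) {
  if (is.finite(x$t_half)) {
    cat(sprintf("<nca_halflife> t1/2 = %.4g h (n = %d, r^2 = %.4f, window %.3g-%.3g h)\n",
                x$t_half, x$n_points, x$r2, x$interval[1], x$interval[2]))
  } else {
    cat("<nca_halflife> undefined:", x$reason, "\n")
  }
  invisible(x)
}
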