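# Predictive-performance metrics: per-point prediction error and the
# MAPE% / MPE% / RMSPE% summaries.

#' Per-point prediction error
#'
#' `PE = 100 * (measured - predicted) / predicted`, in percent. Positive
#' values are underprediction by the model, negative overprediction.
#'
#' @param measured Measured concentrations (>= 0), vectorized.
#' @param predicted Predicted concentrations (> 0), vectorized.
#' @return Prediction errors in percent.
#' @export
prediction_error <- function(measured, predicted) {
  if (any(predicted <= 0)) {
    bad <- which(predicted <= 0)
    stop("predicted concentration must be positive (offending index ",
         bad[1], ")", call. = FALSE)
  }
  if (any(measured < 0))
    stop("measured concentrations must be non-negative", call. = FALSE)
  100 * (measured - predicted) / predicted
}

#' Summarize predictive performance
#'
#' MAPE% is the median of the absolute prediction errors (precision), MPE%
#' the median of the signed prediction errors (bias), and RMSPE% the root
#' mean square of the prediction errors (accuracy). Medians of even-length
#' sets are midpoints of the two central values.
#'
#' @param measured,predicted Paired concentration vectors, or alternatively
#'   supply precomputed errors via `pe`.
#' @param pe Optional vector of prediction errors in percent; overrides
#'   `measured`/`predicted`.
#' @return An object of class `performance_report`: list with `pe` (the
#'   per-point errors), `mape`, `mpe`, `rmspe` (percent) and `n`.
#' @export
summarize_performance <- function(measured = NULL, predicted = NULL, pe = NULL) {
  if (is.null(pe)) {
    if (is.null(measured) || is.null(predicted))
      stop("supply either pe or both measured and predicted", call. = FALSE)
    pe <- prediction_error(measured, predicted)
  }
  if (length(pe) < 1) stop("need at least one paired observation", call. = FALSE)
  structure(list(
    pe = pe,
    mape = stats::median(abs(pe)),
    mpe = stats::median(pe),
    rmspe = sqrt(mean(pe^2)),
    n = length(pe)
  ), class = "performance_report")
}

#' Pair observations with a simulated curve
#'
#' Matches observed records against a simulation by tissue, evaluating the
#' simulated profile at the observed times by linear interpolation.
#' Observed tissue labels `serum`/`plasma` map to the blood compartment and
#' `brain` to the brain tissue sub-compartment. Records below the lower
#' limit of quantification are excluded by default or substituted with
#' LLOQ/2.
#'
#' @param obs Data.frame with columns `tissue`, `time_h`, `conc_nM` and
#'   optionally a logical `censored`.
#' @param sim A `pbpk_simulation`.
#' @param lloq Lower limit of quantification in nM used to censor `obs`
#'   rows with `conc_nM < lloq` (in addition to any `censored` flag);
#'   `NULL` disables it.
#' @param lloq_policy `"exclude"` (default) drops censored records;
#'   `"half"` substitutes `lloq / 2` for them.
#' @return Data.frame of paired points: `tissue`, `time_h`, `c_measured`,
#'   `c_predicted`.
#' @export
pair_observations <- function(obs, sim, lloq = NULL,
                              lloq_policy = c("exclude", "half")) {
  stopifnot(inherits(sim, "pbpk_simulation"))
  lloq_policy <- match.arg(lloq_policy)
  need <- c("tissue", "time_h", "conc_nM")
  if (!all(need %in% names(obs)))
    stop("obs must have columns ", paste(need, collapse = ", "), call. = FALSE)

  censored <- if ("censored" %in% names(obs)) obs$censored else
    rep(FALSE, nrow(obs))
  if (!is.null(lloq)) censored <- censored | obs$conc_nM < lloq
  if (lloq_policy == "exclude") {
    obs <- obs[!censored, , drop = FALSE]
  } else {
    if (is.null(lloq))
      stop("lloq_policy = 'half' requires lloq", call. = FALSE)
    obs$conc_nM[censored] <- lloq / 2
  }
  if (!nrow(obs)) stop("no usable observations after LLOQ handling", call. = FALSE)

  pred <- numeric(nrow(obs))
  for (tis in unique(obs$tissue)) {
    col <- tissue_column(tis, sim)
    rows <- obs$tissue == tis
    pred[rows] <- stats::approx(sim$time_h, sim[[col]],
                                xout = obs$time_h[rows], rule = 2)$y
  }
  data.frame(tissue = obs$tissue, time_h = obs$time_h,
             c_measured = obs$conc_nM, c_predicted = pred,
             stringsAsFactors = FALSE)
}

# map observed tissue labels to simulation columns
tissue_column <- function(tissue, sim) {
  map <- c(serum = "blood", plasma = "blood", blood = "blood",
           brain = "brain_tissue")
  col <- if (tissue %in% names(map)) map[[tissue]] else tissue
  if (!col %in% names(sim))
    stop("no simulated compartment for observed tissue '", tissue, "'",
         call. = FALSE)
  col
}

#' Per-tissue performance of a simulation against observations
#'
#' Pairs observations with the simulation via [pair_observations()] and
#' returns one [summarize_performance()] row per group.
#'
#' @inheritParams pair_observations
#' @return Data.frame with one row per tissue: `group`, `n`, `mape`, `mpe`,
#'   `rmspe` (percent).
#' @export
performance_by_group <- function(obs, sim, lloq = NULL,
                                 lloq_policy = c("exclude", "half")) {
  pairs <- pair_observations(obs, sim, lloq = lloq,
                             lloq_policy = lloq_policy)
  out <- lapply(split(pairs, pairs$tissue), function(g) {
    rep <- summarize_performance(g$c_measured, g$c_predicted)
    data.frame(group = g$tissue[1], n = rep$n, mape = rep$mape,
               mpe = rep$mpe, rmspe = rep$rmspe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> n = %d: MAPE %.3g%%, MPE %.3g%%, RMSPE %.3g%%\n",
              x$n, x$mape, x$mpe, x$rmspe))
  invisible(x)
}
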