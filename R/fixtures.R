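# Synthetic observation generators: noisy tissue PK sampling designs and
# microsomal velocity datasets, so calibration, NCA and metrics can be
# exercised without external data.

#' Sampling schedule
#'
#' @param times Sampling times in h, strictly increasing.
#' @param replicates_per_time Replicates per time point (e.g. 3 animals per
#'   destructive time point).
#' @param design `"destructive"` (each replicate is an independent subject,
#'   as in terminal rodent sampling) or `"longitudinal"` (repeated sampling
#'   of the same subject).
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(times, replicates_per_time = 1,
                              design = c("destructive", "longitudinal")) {
  design <- match.arg(design)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (replicates_per_time < 1) stop("replicates_per_time must be >= 1", call. = FALSE)
  structure(list(times = times,
                 replicates_per_time = as.integer(replicates_per_time),
                 design = design),
            class = "sampling_schedule")
}

#' Shipped sampling schedules
#'
#' `"mouse"`: destructive sampling, 3 animals per time at 0.083, 0.5, 1, 2,
#' 4, 6 h. `"dog"`: the clinical serum schedule 5, 10, 15, 30, 45, 60, 90,
#' 120, 240, 360, 480, 720, 1440 min. `"human_sparse"`: a sparse clinical
#' design over 24 h.
#'
#' @param preset One of `"mouse"`, `"dog"`, `"human_sparse"`.
#' @return A [sampling_schedule()].
#' @export
default_schedule <- function(preset = c("mouse", "dog", "human_sparse")) {
  preset <- match.arg(preset)
  switch(preset,
    mouse = sampling_schedule(c(0.083, 0.5, 1, 2, 4, 6), 3, "destructive"),
    dog = sampling_schedule(
      c(5, 10, 15, 30, 45, 60, 90, 120, 240, 360, 480, 720, 1440) / 60,
      1, "longitudinal"),
    human_sparse = sampling_schedule(c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                                     1, "longitudinal"))
}

#' Noise model for synthetic observations
#'
#' @param kind `"lognormal"` (multiplicative, CV-parameterized) or
#'   `"proportional_additive"` (normal noise with SD
#'   `sqrt((cv*C)^2 + additive_sd^2)`, truncated at 0).
#' @param cv Coefficient of variation (fraction). Defaults to 0.15, typical
#'   bioanalytical tissue variability.
#' @param additive_floor Censoring limit in nM (LLOQ-like); observations
#'   below it are flagged `censored`, not dropped.
#' @param additive_sd Additive noise SD for the proportional+additive kind.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal", "proportional_additive"),
                        cv = 0.15, additive_floor = 0, additive_sd = 0) {
  kind <- match.arg(kind)
  if (cv < 0 || additive_floor < 0 || additive_sd < 0)
    stop("cv, additive_floor and additive_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv = cv, additive_floor = additive_floor,
                 additive_sd = additive_sd),
            class = "noise_model")
}

#' Generate synthetic noisy observations from a simulated truth
#'
#' Interpolates the simulated profile of each requested tissue at the
#' schedule times, applies the noise model, and flags (without dropping)
#' values below the censoring floor. For the lognormal kind the draws are
#' `C * exp(rnorm(0, sdlog))` with `sdlog = sqrt(log(1 + cv^2))`, so the
#' generating curve is the median and the CV is exact.
#'
#' @param sim A `pbpk_simulation` used as ground truth.
#' @param schedule A [sampling_schedule()]; times must lie within the
#'   simulated range.
#' @param noise A [noise_model()].
#' @param tissues Simulation compartments to observe (default `"blood"`).
#' @param seed Integer seed for reproducibility.
#' @return Data.frame with columns `tissue`, `time_h`, `replicate`,
#'   `conc_nM`, `censored`.
#' @export
generate_observations <- function(sim, schedule, noise = noise_model(),
                                  tissues = "blood", seed = 1L) {
  stopifnot(inherits(sim, "pbpk_simulation"),
            inherits(schedule, "sampling_schedule"),
            inherits(noise, "noise_model"))
  if (min(schedule$times) < min(sim$time_h) ||
      max(schedule$times) > max(sim$time_h))
    stop("schedule times fall outside the simulated time range", call. = FALSE)

  set.seed(seed)
  out <- do.call(rbind, lapply(tissues, function(tis) {
    col <- tissue_column(tis, sim)
    truth <- stats::approx(sim$time_h, sim[[col]], xout = schedule$times)$y
    do.call(rbind, lapply(seq_len(schedule$replicates_per_time), function(r) {
      y <- if (noise$kind == "lognormal") {
        if (noise$cv > 0) {
          sdlog <- sqrt(log(1 + noise$cv^2))
          truth * exp(stats::rnorm(length(truth), 0, sdlog))
        } else truth
      } else {
        sd <- sqrt((noise$cv * truth)^2 + noise$additive_sd^2)
        pmax(truth + stats::rnorm(length(truth), 0, sd), 0)
      }
      data.frame(tissue = tis, time_h = schedule$times, replicate = r,
                 conc_nM = y, censored = y < noise$additive_floor,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic microsomal velocity dataset
#'
#' Michaelis-Menten velocities `v = Vmax * S / (Km + S)` on a substrate
#' grid with optional lognormal noise, replicated (technical doublets by
#' default).
#'
#' @param vmax,km Generating Michaelis-Menten constants (velocity units and
#'   substrate units respectively).
#' @param substrate Substrate concentration grid.
#' @param replicates Draws per substrate level (default 2).
#' @param cv Lognormal CV of the noise (0 for exact curves).
#' @param seed Integer seed.
#' @return Data.frame with columns `substrate`, `replicate`, `velocity`,
#'   and attribute `saturating` (`FALSE` when the whole grid sits below
#'   Km/5, i.e. only `Vmax/Km` is identifiable from the design).
#' @export
generate_microsomal_dataset <- function(vmax, km, substrate, replicates = 2,
                                        cv = 0.05, seed = 1L) {
  if (vmax <= 0 || km <= 0) stop("vmax and km must be positive", call. = FALSE)
  if (any(substrate <= 0)) stop("substrate levels must be positive", call. = FALSE)
  set.seed(seed)
  truth <- vmax * substrate / (km + substrate)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    y <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      truth * exp(stats::rnorm(length(truth), 0, sdlog))
    } else truth
    data.frame(substrate = substrate, replicate = r, velocity = y)
  }))
  rownames(out) <- NULL
  attr(out, "saturating") <- max(substrate) >= km / 5
  out
}
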