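# Monte Carlo virtual populations: rank-correlated lognormal parameter
# sampling, batch simulation, envelope summaries and per-subject NCA.

#' Specify a Monte Carlo virtual population
#'
#' Varied parameters are drawn from lognormal distributions centred on the
#' base model values (medians), with the standard deviation of the
#' logarithms defaulting to 0.2 for parameters without a reported
#' variability. A rank correlation structure across parameters can be
#' imposed; the default identity matrix samples them independently.
#'
#' @param n_subjects Number of virtual subjects (default 100).
#' @param varied Either a character vector of dotted parameter paths (each
#'   varied with `sd_log_default` around its base value) or a named list
#'   mapping paths to lists with optional `median` and `sd_log` overrides.
#'   `NULL` selects the shipped default set: body weight, cardiac output,
#'   the optimized partition coefficients, metabolic Vmax/Km, ABCB1 Vmax
#'   and the barrier PSA.
#' @param sd_log_default Default standard deviation of log values (0.2).
#' @param rank_correlation Optional rank-correlation matrix over the varied
#'   parameters (symmetric, unit diagonal, positive semi-definite), in the
#'   order of `varied`. `NULL` means independence.
#' @param seed Integer seed making the draws reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 100, varied = NULL,
                            sd_log_default = 0.2, rank_correlation = NULL,
                            seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (sd_log_default < 0) stop("sd_log_default must be >= 0", call. = FALSE)
  if (is.null(varied))
    varied <- c("phys.body_weight", "phys.cardiac_output",
                "drug.PC.gut", "drug.PC.kidney", "drug.PC.liver",
                "drug.PC.brain", "drug.Vmax_met", "drug.Km_met",
                "drug.Vmax_ABCB1", "drug.PSA")
  if (is.character(varied))
    varied <- stats::setNames(rep(list(list()), length(varied)), varied)
  if (is.null(names(varied)) || any(!nzchar(names(varied))))
    stop("varied must be named by parameter path", call. = FALSE)
  p <- length(varied)
  if (!is.null(rank_correlation)) {
    rc <- rank_correlation
    if (!is.matrix(rc) || any(dim(rc) != p))
      stop("rank_correlation must be a ", p, "x", p, " matrix", call. = FALSE)
    if (max(abs(rc - t(rc))) > 1e-12 || max(abs(diag(rc) - 1)) > 1e-12)
      stop("rank_correlation must be symmetric with unit diagonal", call. = FALSE)
    ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("rank_correlation is not positive semi-definite; ",
           "consider projecting to the nearest PSD matrix ",
           "(e.g. Matrix::nearPD)", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), varied = varied,
                 sd_log_default = sd_log_default,
                 rank_correlation = rank_correlation,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a virtual population
#'
#' Draws `n_subjects` parameter sets. Each varied parameter is lognormal
#' with `meanlog = log(median)` (median defaulting to the base model value)
#' and `sdlog = sd_log`. Rank correlation is imposed by the Iman-Conover
#' rank-reordering method: each parameter's sample is reordered to match
#' the ranks of a correlated multivariate-normal reference, which fixes the
#' Spearman correlation without altering the marginals. Cardiac output is
#' resolved from the allometric relationship before sampling so that it can
#' be varied independently of body weight.
#'
#' @param spec A [population_spec()].
#' @param phys,drug Base model configuration.
#' @return An object of class `population_draws`: list with `subjects` (a
#'   list of `list(phys, drug)` per subject) and `draws` (data.frame of the
#'   sampled values, one column per varied parameter).
#' @export
sample_population <- function(spec, phys, drug) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(phys, "species_physiology"),
            inherits(drug, "drug_parameters"))
  if (is.null(phys$cardiac_output))
    phys$cardiac_output <- allometric_cardiac_output(
      phys$body_weight, phys$co_coefficient, phys$co_exponent)
  base <- list(phys = phys, drug = drug)

  paths <- names(spec$varied)
  p <- length(paths)
  n <- spec$n_subjects
  medians <- vapply(seq_len(p), function(i)
    spec$varied[[i]]$median %||% param_get(base, paths[i]), numeric(1))
  sdlogs <- vapply(seq_len(p), function(i)
    spec$varied[[i]]$sd_log %||% spec$sd_log_default, numeric(1))
  if (any(medians <= 0))
    stop("varied parameters must have positive medians (offending: ",
         paste(paths[medians <= 0], collapse = ", "), ")", call. = FALSE)

  set.seed(spec$seed)
  draws <- vapply(seq_len(p), function(i)
    stats::rlnorm(n, meanlog = log(medians[i]), sdlog = sdlogs[i]),
    numeric(n))
  draws <- matrix(draws, nrow = n, ncol = p,
                  dimnames = list(NULL, paths))

  if (!is.null(spec$rank_correlation) && n > 1) {
    # Iman-Conover: reorder each column to the ranks of correlated normals
    z <- matrix(stats::rnorm(n * p), n, p) %*%
      chol(spec$rank_correlation + diag(1e-12, p))
    for (j in seq_len(p))
      draws[, j] <- sort(draws[, j])[rank(z[, j], ties.method = "first")]
  }

  subjects <- lapply(seq_len(n), function(i) {
    config <- base
    for (j in seq_len(p))
      config <- param_set(config, paths[j], draws[i, j])
    config
  })
  structure(list(subjects = subjects,
                 draws = as.data.frame(draws),
                 base = base, spec = spec),
            class = "population_draws")
}

#' Simulate a virtual population
#'
#' Runs [simulate_iv_bolus()] for every subject on a common output grid and
#' summarizes the population as pointwise envelope statistics (min, max,
#' mean, SD on the arithmetic scale) per compartment, together with
#' per-subject NCA of a chosen compartment. Subjects whose solve fails are
#' flagged and excluded from the summaries.
#'
#' @param draws A [sample_population()] result.
#' @param dose A [dose_event()]. Per-kg and per-m^2 doses are resolved
#'   against each subject's own (sampled) body weight.
#' @param t_end,n_out Simulation window and grid, as in
#'   [simulate_iv_bolus()].
#' @param nca_compartment Compartment for the per-subject NCA (default
#'   `"blood"`).
#' @param halflife_args List of arguments passed to
#'   [terminal_half_life()] for the per-subject half-life.
#' @param keep_simulations Keep the individual `pbpk_simulation` objects
#'   (default `TRUE`; set `FALSE` to save memory for large populations).
#' @param ... Passed to [simulate_iv_bolus()].
#' @return An object of class `pbpk_population`: list with `envelope`
#'   (data.frame: `time_h`, `compartment`, `min`, `mean`, `sd`, `max`),
#'   `nca` (per-subject AUC over the window and terminal half-life),
#'   `n_failed`, and optionally `simulations`.
#' @export
run_population <- function(draws, dose, t_end, n_out = 121,
                           nca_compartment = "blood",
                           halflife_args = list(),
                           keep_simulations = TRUE, ...) {
  stopifnot(inherits(draws, "population_draws"))
  sims <- vector("list", length(draws$subjects))
  failed <- logical(length(sims))
  for (i in seq_along(sims)) {
    sims[[i]] <- tryCatch(
      simulate_iv_bolus(draws$subjects[[i]]$phys, draws$subjects[[i]]$drug,
                        dose, t_end = t_end, n_out = n_out, ...),
      error = function(e) {
        warning("subject ", i, " excluded: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    failed[i] <- is.null(sims[[i]])
  }
  ok <- which(!failed)
  if (!length(ok)) stop("all subjects failed to simulate", call. = FALSE)

  comps <- setdiff(names(sims[[ok[1]]]), "time_h")
  time_h <- sims[[ok[1]]]$time_h
  envelope <- do.call(rbind, lapply(comps, function(cc) {
    m <- vapply(sims[ok], function(s) s[[cc]], numeric(length(time_h)))
    m <- matrix(m, nrow = length(time_h))
    data.frame(time_h = time_h, compartment = cc,
               min = apply(m, 1, min), mean = rowMeans(m),
               sd = apply(m, 1, stats::sd), max = apply(m, 1, max),
               stringsAsFactors = FALSE)
  }))

  nca_tab <- do.call(rbind, lapply(ok, function(i) {
    s <- sim_series(sims[[i]], nca_compartment)
    hl <- do.call(terminal_half_life, c(list(s), halflife_args))
    data.frame(subject = i,
               auc_nM_h = auc_linlog(s),
               t_half_h = hl$t_half,
               stringsAsFactors = FALSE)
  }))

  structure(list(envelope = envelope, nca = nca_tab,
                 n_failed = sum(failed),
                 simulations = if (keep_simulations) sims[ok],
                 draws = draws),
            class = "pbpk_population")
}

#' @export
print.pbpk_population <- function(x, ...) {
  n <- nrow(x$nca)
  cat(sprintf("<pbpk_population> %d subjects (%d failed)\n", n, x$n_failed))
  cat(sprintf("  blood AUC over window: mean %.4g nM*h (SD %.3g)\n",
              mean(x$nca$auc_nM_h), stats::sd(x$nca$auc_nM_h)))
  th <- x$nca$t_half_h
  if (any(is.finite(th)))
    cat(sprintf("  terminal t1/2: mean %.4g h (%d subjects defined)\n",
                mean(th[is.finite(th)]), sum(is.finite(th))))
  invisible(x)
}
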