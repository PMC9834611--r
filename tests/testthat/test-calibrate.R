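test_that("noiseless Michaelis-Menten data are recovered exactly", {
  S <- c(1, 5, 10, 50, 100)
  v <- 100 * S / (10 + S)
  fit <- fit_michaelis_menten(S, v)
  expect_equal(fit$vmax, 100, tolerance = 1e-6)
  expect_equal(fit$km, 10, tolerance = 1e-6)
  # defining property: half-maximal velocity at S = Km
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  expect_true(fit$identifiable)
})

test_that("Vmax is precise over repeated noisy doublet designs", {
  dat <- lapply(1:200, function(i)
    generate_microsomal_dataset(100, 10, c(1, 2.5, 5, 10, 25, 50, 100),
                                replicates = 2, cv = 0.05, seed = i))
  vmax <- vapply(dat, function(d)
    fit_michaelis_menten(d$substrate, d$velocity)$vmax, numeric(1))
  expect_lt(stats::sd(vmax) / mean(vmax), 0.10)
  expect_equal(mean(vmax), 100, tolerance = 0.05)
})

test_that("a purely linear-range design is flagged poorly identified", {
  d <- generate_microsomal_dataset(100, 1000, c(0.1, 0.5, 1, 2),
                                   replicates = 2, cv = 0.05, seed = 2)
  expect_false(attr(d, "saturating"))
  fit <- fit_michaelis_menten(d$substrate, d$velocity)
  expect_false(fit$identifiable)
})

test_that("IVIVE scaling is linear in microsomal protein content", {
  expect_equal(scale_vmax_ivive(250, 0.5, 0), 0)
  one <- scale_vmax_ivive(250, 0.5, 46)
  expect_equal(scale_vmax_ivive(250, 0.5, 92), 2 * one)
  # mouse vs dog liver protein content at identical microsomal kinetics
  expect_equal(scale_vmax_ivive(250, 0.5, 55) / one, 55 / 46,
               tolerance = 1e-12)
  # unit chain: ng/ml/min at 0.5 mg/ml protein -> umol/L liver/h
  expect_equal(one, 250 * 60 * 46 / (0.5 * 811), tolerance = 1e-12)
})

test_that("a zero-parameter fit evaluates residuals and information criteria", {
  sim <- mouse_sim("mdr1a1b_knockout")
  obs <- generate_observations(sim, default_schedule("mouse"),
                               noise_model(cv = 0.05),
                               tissues = "kidney", seed = 5)
  phys <- default_physiology("mouse")
  ko <- apply_scenario(default_drug_parameters("mouse"), "mdr1a1b_knockout")
  f0 <- fit_model(obs[, c("tissue", "time_h", "conc_nM")], phys, ko,
                  dose_event(mg_per_kg = 2))
  expect_equal(f0$k, 0)
  expect_true(f0$converged)
  expect_gt(f0$residual_norm, 0)
  # adding a parameter that buys nothing is penalized more by BIC than AIC
  expect_equal(f0$bic, f0$aic, tolerance = 1e-12)
})

test_that("the kidney partition coefficient is recovered from noisy knockout data", {
  truth <- 3.73
  sim <- mouse_sim("mdr1a1b_knockout")
  obs <- generate_observations(sim, default_schedule("mouse"),
                               noise_model(cv = 0.05),
                               tissues = "kidney", seed = 17)
  phys <- default_physiology("mouse")
  ko <- apply_scenario(default_drug_parameters("mouse"), "mdr1a1b_knockout")
  start <- param_set(list(phys = phys, drug = ko), "drug.PC.kidney", 2.0)
  fit <- fit_model(obs[, c("tissue", "time_h", "conc_nM")], phys,
                   start$drug, dose_event(mg_per_kg = 2),
                   free = list("drug.PC.kidney" =
                                 list(init = 2.0, lower = 0.5, upper = 20)))
  expect_true(fit$converged)
  est <- fit$estimates[["drug.PC.kidney"]]
  expect_lt(abs(est - truth) / truth, 0.15)
  # the refitted model carries the estimate
  expect_equal(fit$drug$PC[["kidney"]], est)
})

test_that("free-parameter bounds are validated", {
  obs <- data.frame(tissue = "serum", time_h = 1:3, conc_nM = c(3, 2, 1))
  expect_error(
    fit_model(obs, default_physiology("mouse"),
              default_drug_parameters("mouse"), dose_event(mg_per_kg = 2),
              free = list("drug.PSA" = list(init = 1, lower = 2, upper = 1))),
    "lower < upper")
})
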