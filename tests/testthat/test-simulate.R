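test_that("a zero dose yields identically zero concentrations", {
  sim <- simulate_iv_bolus(default_physiology("mouse"),
                           default_drug_parameters("mouse"),
                           dose_event(mg = 0), t_end = 2, n_out = 21)
  expect_true(all(as.matrix(sim[setdiff(names(sim), "time_h")]) == 0))
})

test_that("the system is linear in dose far below every saturation constant", {
  phys <- default_physiology("mouse")
  drug <- default_drug_parameters("mouse")
  # doses chosen so every concentration stays far below the smallest Km
  # (6.41 nM) yet the state stays far above the solver's absolute tolerance
  s1 <- simulate_iv_bolus(phys, drug, dose_event(mg_per_kg = 1e-5), 6, 61,
                          atol = 1e-16)
  s2 <- simulate_iv_bolus(phys, drug, dose_event(mg_per_kg = 2e-5), 6, 61,
                          atol = 1e-16)
  for (col in c("blood", "kidney", "liver", "gut", "brain_tissue")) {
    ratio <- s2[[col]][-1] / s1[[col]][-1]
    ratio <- ratio[is.finite(ratio)]
    expect_true(all(abs(ratio - 2) < 0.02), label = paste("dose-linear", col))
  }
})

test_that("knockout changes brain exposure by an order of magnitude but not serum", {
  wt <- mouse_sim("wild_type")
  ko <- mouse_sim("mdr1a1b_knockout")
  serum_ratio <- auc_linlog(sim_series(ko)) / auc_linlog(sim_series(wt))
  expect_lt(abs(serum_ratio - 1), 0.1)
  brain_ratio <- auc_linlog(sim_series(ko, "brain_tissue")) /
    auc_linlog(sim_series(wt, "brain_tissue"))
  expect_gt(brain_ratio, 5)
  expect_lt(brain_ratio, 20)
})

test_that("AUC is insensitive to output-grid refinement", {
  phys <- default_physiology("mouse")
  drug <- default_drug_parameters("mouse")
  dose <- dose_event(mg_per_kg = 2)
  a1 <- auc_linlog(simulate_iv_bolus(phys, drug, dose, 6, 101))
  a2 <- auc_linlog(simulate_iv_bolus(phys, drug, dose, 6, 1001))
  expect_lt(abs(a1 - a2) / a2, 1e-3)
})

test_that("scenarios transform parameters as documented and never mutate their input", {
  dog <- default_drug_parameters("dog")
  expect_equal(apply_scenario(dog, "wild_type")$Vmax_met, dog$Vmax_met)

  ind <- apply_scenario(dog, "cyp3a_induction_2x")
  expect_equal(ind$Vmax_met, 2 * 189.6e3)
  expect_equal(dog$Vmax_met, 189.6e3) # original untouched

  ko <- apply_scenario(default_drug_parameters("mouse"), "mdr1a1b_knockout")
  expect_equal(ko$Vmax_ABCB1, 0)
  expect_equal(ko$Vmax_bil, 23.35)
  expect_equal(ko$Km_bil, 1.52e-5)
  expect_equal(ko$sf_bil, 1)

  cust <- apply_scenario(dog, "custom", multipliers = list(PSA = 0.5))
  expect_equal(cust$PSA, dog$PSA / 2)
  expect_error(apply_scenario(dog, "no_such_scenario"))
  expect_error(apply_scenario(dog, "custom"), "multipliers")
})

test_that("per-square-metre dosing converts through the canine BSA relation", {
  phys <- default_physiology("dog") # 25 kg
  drug <- default_drug_parameters("dog")
  d_m2 <- dose_event(mg_per_m2 = 2.5)
  expected_mg <- 2.5 * 0.101 * 25^(2 / 3)
  expect_equal(vblpbpk:::dose_nmol(d_m2, phys, drug),
               dose_mg_to_nmol(expected_mg), tolerance = 1e-12)
  expect_equal(dose_mg_to_nmol(0.05, 811), 61.652, tolerance = 1e-4)
})

test_that("drug parameters round-trip through their YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  drug <- apply_scenario(default_drug_parameters("mouse"), "mdr1a1b_knockout")
  write_drug_parameters(drug, path)
  back <- read_drug_parameters(path)
  for (field in c("BC", "PC", "Vmax_met", "Km_met", "Vmax_ABCB1", "Km_ABCB1",
                  "Vmax_bil", "Km_bil", "PSA", "GFR_fraction"))
    expect_equal(back[[field]], drug[[field]], tolerance = 1e-12,
                 label = field)
})
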