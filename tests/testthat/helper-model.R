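# Shared fixtures: reference mouse simulations reused across test files.
# Built once per test run; everything is generated in code.

.cache <- new.env(parent = emptyenv())

mouse_sim <- function(scenario = "wild_type", t_end = 6, n_out = 241) {
  key <- paste(scenario, t_end, n_out, sep = "_")
  if (is.null(.cache[[key]])) {
    phys <- default_physiology("mouse")
    drug <- apply_scenario(default_drug_parameters("mouse"), scenario)
    .cache[[key]] <- simulate_iv_bolus(phys, drug, dose_event(mg_per_kg = 2),
                                       t_end = t_end, n_out = n_out)
  }
  .cache[[key]]
}

# independent fixed-point oracle for the saturable-binding free
# concentration: x <- CT / (PC + BC / (KD + x)) iterated to convergence
free_conc_oracle <- function(CT, PC, BC, KD, tol = 1e-12, max_iter = 10000L) {
  vapply(CT, function(ct) {
    x <- ct / PC
    for (i in seq_len(max_iter)) {
      x_new <- ct / (PC + BC / (KD + x))
      if (abs(x_new - x) <= tol * max(x_new, 1e-300)) return(x_new)
      x <- x_new
    }
    x
  }, numeric(1))
}
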