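test_that("fractional physiology resolves to the expected absolute volumes", {
  human <- resolve_physiology(default_physiology("human"))
  expect_equal(human["liver", "volume_L"], 70 * 2.57 / 100, tolerance = 1e-12)

  mouse <- resolve_physiology(default_physiology("mouse"))
  v_brain <- 0.025 * 1.65 / 100
  expect_equal(mouse["brain_tissue", "volume_L"] + mouse["brain_blood", "volume_L"],
               v_brain, tolerance = 1e-12)
  expect_equal(mouse["brain_tissue", "volume_L"], 0.97 * v_brain, tolerance = 1e-12)
  expect_equal(mouse["brain_blood", "volume_L"], 1.2375e-5, tolerance = 1e-9)
})

test_that("resolution conserves volume and splits flow by fractions", {
  for (sp in c("mouse", "dog", "human")) {
    phys <- default_physiology(sp)
    comp <- resolve_physiology(phys)
    expect_lte(sum(comp$volume_L), phys$body_weight)
    co <- attr(comp, "cardiac_output")
    perf <- setdiff(rownames(comp), c("blood", "lung", "brain_tissue"))
    expect_lte(sum(comp[perf, "flow_Lh"]), co * (1 + 1e-9))
    # lung carve-out keeps total volume identical to the no-lung layout
    comp0 <- resolve_physiology(phys, include_lung = FALSE)
    expect_equal(sum(comp$volume_L), sum(comp0$volume_L), tolerance = 1e-12)
  }
})

test_that("volumes are linear in body weight while flows follow the allometry", {
  p1 <- default_physiology("mouse", body_weight = 0.025)
  p2 <- default_physiology("mouse", body_weight = 0.050)
  c1 <- resolve_physiology(p1)
  c2 <- resolve_physiology(p2)
  expect_equal(c2$volume_L, 2 * c1$volume_L, tolerance = 1e-12)
  expect_equal(c2$flow_Lh, 2^0.75 * c1$flow_Lh, tolerance = 1e-12)
})

test_that("allometric cardiac output behaves as a power law", {
  expect_equal(allometric_cardiac_output(1, coefficient = 7.3), 7.3)
  expect_equal(allometric_cardiac_output(0.5, coefficient = 10, exponent = 1), 5)
  cos <- allometric_cardiac_output(c(0.025, 10, 70))
  expect_true(all(diff(cos) > 0))
  # default mouse cardiac output in the physiologic range (L/h)
  expect_gt(cos[1], 0.5)
  expect_lt(cos[1], 2)
  expect_error(allometric_cardiac_output(-1), "positive")
})

test_that("invalid physiologies are rejected with informative errors", {
  tab <- default_physiology("mouse")
  wf <- tab$tissue_weight_fraction
  ff <- tab$tissue_flow_fraction
  expect_error(
    species_physiology("x", 0.025, 0.45, wf[-1], ff),
    "brain")
  expect_error(
    species_physiology("x", -1, 0.45, wf, ff),
    "body_weight")
  wf0 <- wf; wf0[["liver"]] <- 0
  expect_error(
    species_physiology("x", 0.025, 0.45, wf0, ff),
    "positive")
  wf_big <- wf; wf_big[["slowly_perfused"]] <- 99
  expect_error(
    species_physiology("x", 0.025, 0.45, wf_big, ff),
    "100%")
})

test_that("physiology round-trips through its YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  phys <- default_physiology("dog")
  write_physiology(phys, path)
  back <- read_physiology(path)
  expect_equal(resolve_physiology(back), resolve_physiology(phys),
               tolerance = 1e-12)
})

test_that("shipped species configuration files match the in-code defaults", {
  for (sp in c("mouse", "dog", "human")) {
    path <- system.file("extdata", paste0(sp, "_physiology.yaml"),
                        package = "vblpbpk")
    expect_true(nzchar(path))
    expect_equal(resolve_physiology(read_physiology(path)),
                 resolve_physiology(default_physiology(sp)),
                 tolerance = 1e-10)
  }
})
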