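test_that("percent change is plain arithmetic with a guarded control", {
  expect_equal(percent_change(200, 200), 0)
  expect_equal(percent_change(300, 200), 50)
  expect_error(percent_change(300, 0), "positive")
  expect_error(percent_change(300, -5), "positive")
})

test_that("the control PCS sits at the cap shoulder under pressure alone", {
  fit <- cached_control()
  half_core <- fit$mesh$meta$half_core_arc
  expect_gt(fit$pcs$pcs, 0)
  # arg-max angle at the shoulder (core-arc end), within a couple of elements
  expect_lt(abs(fit$pcs$theta - half_core),
            3 * fit$mesh$meta$elem_arc_deg)
  # and radially within the cap
  g <- fit$mesh$meta$geometry
  expect_lte(fit$pcs$r, g$core_inner_radius + 1e-9)
  expect_gte(fit$pcs$r, g$lumen_radius - 1e-9)
})

test_that("PCS scales exactly with pressure and vanishes without load", {
  fit <- cached_control()
  zero <- run_scenario(scenario("p0", pressure = 0))
  expect_lt(abs(zero$pcs$pcs), 1e-9)
  dbl <- run_scenario(scenario("p2", pressure = 2 * 14.6))
  expect_equal(dbl$pcs$pcs, 2 * fit$pcs$pcs, tolerance = 1e-10)
})

test_that("superposition: a direct solve equals the basis combination", {
  sw <- cached_expansion_sweep()
  d <- 200
  direct <- run_scenario(scenario(
    "d200", crystals = list(crystal_spec("shoulder", expansion_um = d))
  ))
  from_basis <- sw$data$pcs_kpa[sw$data$d_um == d]
  expect_equal(direct$pcs$pcs, from_basis, tolerance = 1e-8)
})

test_that("PCS is affine in expansion while the arg-max location holds", {
  sw <- expansion_sweep("shoulder", d_values = seq(300, 400, by = 25))
  expect_true(sw$argmax_constant)
  expect_lt(sw$max_residual, 1e-6)
  # two-point sweep: slope is the finite difference exactly
  sw2 <- expansion_sweep("shoulder", d_values = c(200, 400))
  expect_equal(sw2$slope,
               diff(sw2$data$pcs_kpa) / 200, tolerance = 1e-12)
})

test_that("the expansion slope is invariant to luminal pressure", {
  d_values <- seq(300, 400, by = 50)
  s1 <- expansion_sweep("shoulder", d_values = d_values, pressure = 14.6)
  s2 <- expansion_sweep("shoulder", d_values = d_values, pressure = 26.6)
  expect_true(s1$argmax_constant && s2$argmax_constant)
  expect_equal(s1$slope, s2$slope, tolerance = 1e-6)
})

test_that("the pressure sweep raises the baseline monotonically", {
  ps <- pressure_sweep("shoulder", d_um = 2)
  expect_true(all(diff(ps$data$baseline_kpa) > 0))
  # per-pressure expansion slope identical across pressures
  expect_lt(diff(range(ps$data$slope_kpa_per_um)), 1e-9)
  # control PCS doubles exactly with pressure (pure linearity)
  p1 <- ps$data$baseline_kpa[ps$data$P_kpa == 9.3]
  expect_equal(max(ps$data$baseline_kpa) / p1, 26.6 / 9.3,
               tolerance = 1e-9)
})

test_that("run_all reports the eight-scenario roster deterministically", {
  res <- cached_run_all()
  expect_equal(nrow(res), 8L)
  expect_equal(res$scenario[1], "control")
  expect_true(all(is.na(res$error)))
  expect_equal(res$pct_change[1], 0)
  res2 <- run_all(default_scenarios()[c("control", "shoulder")])
  expect_equal(res2$pcs_kpa[1], res$pcs_kpa[1], tolerance = 1e-12)
  expect_equal(res2$pcs_kpa[2], res$pcs_kpa[2], tolerance = 1e-12)
  # CSV output is byte-identical across reruns
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_all(default_scenarios()[c("control", "center")], out_dir = d1)
  run_all(default_scenarios()[c("control", "center")], out_dir = d2)
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  expect_true(file.exists(file.path(d1, "control.vtk")))
})

test_that("per-scenario failures are collected, not fatal", {
  good <- scenario("control")
  bad <- scenario("broken",
                  params = morphology_params(core_area = 18))
  expect_warning(res <- run_all(list(good, bad)), "failed")
  expect_equal(nrow(res), 2L)
  expect_true(is.na(res$pcs_kpa[2]))
  expect_match(res$error[2], "wall thickness")
  expect_false(is.na(res$pcs_kpa[1]))
})

test_that("sensitivity of a crystal-free scenario to crystal stiffness is nil", {
  sens <- sensitivity_sweep(default_scenarios()["control"],
                            factors = c(0.5, 1, 11))
  expect_equal(sens$max_deviation_pct, 0)
})

test_that("tidiers and plots expose the fitted results", {
  fit <- cached_control()
  td <- tidy(fit)
  expect_true(all(c("sigma_rr", "sigma_tt", "sigma_rt", "sigma_zz", "region")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$scenario, "control")
  expect_equal(gl$pcs_kpa, fit$pcs$pcs)
  sw <- cached_expansion_sweep()
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(sw)$slope_kpa_per_um, sw$slope)
})

test_that("yaml configs round-trip into scenarios", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "morphology:",
    "  cap_thickness: 0.1",
    "pressure: 12.0",
    "scenarios:",
    "  - name: one",
    "    crystals:",
    "      - location: shoulder",
    "        expansion_um: 5"
  ), path)
  cfg <- read_config(path)
  expect_equal(cfg$params$cap_thickness, 0.1)
  expect_length(cfg$scenarios, 1L)
  expect_equal(cfg$scenarios$one$pressure, 12.0)
  expect_equal(cfg$scenarios$one$crystals[[1]]$expansion_um, 5)
})
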