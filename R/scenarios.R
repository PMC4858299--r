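# Scenario orchestration: the crystal-placement roster, PCS extraction, and
# the expansion / pressure / stiffness sweeps.

#' Define a loading scenario
#'
#' @param name Scenario name, unique within a run.
#' @param params Plaque morphometrics ([morphology_params()]).
#' @param crystals List of [crystal_spec()] (possibly empty for the control).
#' @param pressure Luminal pressure, kPa (default 14.6, i.e. 110 mmHg).
#' @param materials Region materials (default [default_materials()]).
#' @return Object of class `capstress_scenario`.
#' @export
scenario <- function(name, params = morphology_params(), crystals = list(),
                     pressure = 14.6, materials = default_materials()) {
  if (inherits(crystals, "crystal_spec")) crystals <- list(crystals)
  stopifnot(is.character(name), length(name) == 1L, pressure >= 0)
  structure(
    list(name = name, params = params, crystals = crystals,
         pressure = pressure, materials = materials),
    class = "capstress_scenario"
  )
}

#' The eight-scenario roster
#'
#' Control, the three single-crystal placements, the three two-crystal pairs,
#' and the three-crystal case, in that fixed order. Every crystal carries the
#' same expansion (default 2 um, the value used for the location comparisons).
#'
#' @param expansion_um Expansion of every crystal, um.
#' @param params Morphometrics shared by all scenarios.
#' @param pressure Luminal pressure, kPa.
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function(expansion_um = 2, params = morphology_params(),
                              pressure = 14.6) {
  cs <- function(loc) crystal_spec(loc, expansion_um = expansion_um)
  combos <- list(
    control = list(),
    shoulder = list(cs("shoulder")),
    halfway = list(cs("halfway")),
    center = list(cs("center")),
    shoulder_halfway = list(cs("shoulder"), cs("halfway")),
    halfway_center = list(cs("halfway"), cs("center")),
    shoulder_center = list(cs("shoulder"), cs("center")),
    three_crystals = list(cs("shoulder"), cs("halfway"), cs("center"))
  )
  out <- lapply(names(combos), function(nm) {
    scenario(nm, params = params, crystals = combos[[nm]], pressure = pressure)
  })
  names(out) <- names(combos)
  out
}

# Nodes of the stress field eligible for the cap PCS search: plaque-region
# recovery points radially between lumen surface and core interface, angularly
# within the core arc plus one element margin.
cap_mask <- function(stress, mesh) {
  geom <- mesh$meta$geometry
  half_core <- mesh$meta$half_core_arc
  margin <- mesh$meta$elem_arc_deg %||% 0
  stress$region == "plaque" &
    stress$r <= geom$core_inner_radius + 1e-9 &
    stress$theta <= half_core + margin + 1e-9
}

#' Peak circumferential stress on the fibrous cap
#'
#' @param stress A `stress_field` from [recover_stress()].
#' @param mesh The `q8_mesh` the field was computed on (provides the cap
#'   search domain: plaque recovery points between lumen and core over the
#'   core arc plus one element margin).
#' @return List of class `pcs_result`: `pcs` (kPa), `r`, `theta`, `node`.
#' @export
peak_cap_stress <- function(stress, mesh) {
  cap <- stress[cap_mask(stress, mesh), , drop = FALSE]
  if (nrow(cap) == 0L) abort("no cap recovery points found.")
  i <- which.max(cap$sigma_tt)
  structure(
    list(pcs = cap$sigma_tt[i], r = cap$r[i], theta = cap$theta[i],
         node = cap$node[i]),
    class = "pcs_result"
  )
}

#' @export
print.pcs_result <- function(x, ...) {
  cat(sprintf("PCS = %.1f kPa at r = %.3f mm, theta = %.2f deg\n",
              x$pcs, x$r, x$theta))
  invisible(x)
}

#' Percent change of PCS relative to the control
#'
#' @param pcs PCS of the scenario, kPa.
#' @param control_pcs PCS of the crystal-free control, kPa (> 0).
#' @return 100 * (pcs - control_pcs) / control_pcs.
#' @export
percent_change <- function(pcs, control_pcs) {
  if (!is.numeric(control_pcs) || any(control_pcs <= 0)) {
    abort("control_pcs must be positive.")
  }
  100 * (pcs - control_pcs) / control_pcs
}

# Assemble and solve one scenario; returns the pieces needed by the sweeps.
scenario_system <- function(s, refinement = 1L) {
  mesh <- build_half_model(s$params, s$crystals, refinement)
  asm <- fem_assemble(mesh, s$materials)
  eigs <- lapply(s$crystals, function(spec) {
    load <- expansion_to_eigenstrain(spec, s$materials$crystal)
    list(elements = place_crystal(mesh, spec), eps_r = load$eps_r,
         eps_r_per_um = load$eps_r_per_um, spec = spec)
  })
  f_p <- pressure_load(mesh, s$pressure)
  f_e <- numeric(asm$ndof)
  for (eg in eigs) {
    f_e <- f_e + eigenstrain_load(mesh, eg$elements, eg$eps_r,
                                  s$materials$crystal)
  }
  list(mesh = mesh, asm = asm, eigs = eigs, f_p = f_p, f_e = f_e)
}

#' Run one scenario end to end
#'
#' Builds the mesh, assembles materials, applies luminal pressure and crystal
#' eigenstrain loads, solves the plane-strain system, recovers cylindrical
#' stresses and extracts the cap PCS.
#'
#' @param s A [scenario()].
#' @param refinement Mesh refinement multiplier.
#' @return Object of class `plaque_fit`: `scenario`, `mesh`, `solution`,
#'   `stress` (tibble), `pcs` (a `pcs_result`).
#' @examples
#' \donttest{
#' fit <- run_scenario(scenario("control"))
#' fit$pcs
#' }
#' @export
run_scenario <- function(s, refinement = 1L) {
  stopifnot(inherits(s, "capstress_scenario"))
  sys <- scenario_system(s, refinement)
  sol <- fem_solve(sys$asm, sys$f_p + sys$f_e)
  stress <- recover_stress(sol, s$materials, eigenstrains = sys$eigs)
  structure(
    list(scenario = s, mesh = sys$mesh, solution = sol, stress = stress,
         pcs = peak_cap_stress(stress, sys$mesh)),
    class = "plaque_fit"
  )
}

#' @export
print.plaque_fit <- function(x, ...) {
  cat(sprintf("<plaque_fit> scenario '%s' (%d crystals, P = %g kPa)\n",
              x$scenario$name, length(x$scenario$crystals),
              x$scenario$pressure))
  print(x$pcs)
  invisible(x)
}

# Max |theta distance| (deg) from a node to a crystal band's angular extent.
band_theta_range <- function(mesh, location) {
  band <- mesh$meta$crystal_bands[[location]]
  if (is.null(band)) abort(paste0("no crystal band at ", location))
  cent <- t(vapply(band, function(e) {
    colMeans(mesh$nodes[mesh$elements[e, 1:4], , drop = FALSE])
  }, numeric(2)))
  th <- atan2(cent[, 2], cent[, 1]) * 180 / pi
  range(th)
}

#' Sweep crystal expansion at one location
#'
#' Solves the pressure-only and unit-expansion eigenstrain states once, forms
#' every requested expansion by superposition (exact for the linear model),
#' extracts PCS per expansion, and fits a least-squares line. Reports whether
#' the PCS arg-max node stays put over the sweep, in which case PCS is exactly
#' affine in d.
#'
#' @param location Crystal location (`"shoulder"`, `"halfway"`, `"center"`).
#' @param d_values Expansion grid, um (default 0-400 in 21 steps).
#' @param pressure Luminal pressure, kPa.
#' @param params Morphometrics.
#' @param crystal Crystal dimensions ([crystal_spec()]; its `expansion_um` is
#'   ignored in favour of `d_values`).
#' @param materials Region materials.
#' @param refinement Mesh refinement multiplier.
#' @return Object of class `capstress_sweep` (kind `"expansion"`): `data`
#'   tibble (`d_um`, `pcs_kpa`, `argmax_node`, `r`, `theta`), `slope`
#'   (kPa/um), `intercept`, `max_residual` (relative), `argmax_constant`.
#' @export
expansion_sweep <- function(location = "shoulder",
                            d_values = seq(0, 400, length.out = 21),
                            pressure = 14.6, params = morphology_params(),
                            crystal = crystal_spec(location),
                            materials = default_materials(),
                            refinement = 1L) {
  stopifnot(length(d_values) >= 2L, length(unique(d_values)) >= 2L,
            all(d_values >= 0))
  s <- scenario("sweep", params = params,
                crystals = list(crystal_spec(location, crystal$length,
                                             crystal$thickness, 0)),
                pressure = pressure, materials = materials)
  sys <- scenario_system(s, refinement)
  eg <- sys$eigs[[1]]
  f_e1 <- eigenstrain_load(sys$mesh, eg$elements, eg$eps_r_per_um,
                           materials$crystal)
  sol_p <- fem_solve(sys$asm, sys$f_p)
  sol_e <- fem_solve(sys$asm, f_e1)
  st_p <- recover_stress(sol_p, materials)
  st_e <- recover_stress(sol_e, materials,
                         eigenstrains = list(list(elements = eg$elements,
                                                  eps_r = eg$eps_r_per_um)))
  mask <- cap_mask(st_p, sys$mesh)
  base <- st_p$sigma_tt[mask]
  gain <- st_e$sigma_tt[mask]
  cap_nodes <- st_p$node[mask]
  cap_r <- st_p$r[mask]
  cap_th <- st_p$theta[mask]
  rows <- lapply(d_values, function(d) {
    v <- base + d * gain
    i <- which.max(v)
    tibble::tibble(d_um = d, pcs_kpa = v[i], argmax_node = cap_nodes[i],
                   r = cap_r[i], theta = cap_th[i])
  })
  dat <- dplyr::bind_rows(rows)
  fit <- lm(pcs_kpa ~ d_um, data = dat)
  res <- max(abs(fit$residuals)) / max(abs(dat$pcs_kpa))
  structure(
    list(kind = "expansion", data = dat, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), max_residual = res,
         argmax_constant = length(unique(dat$argmax_node)) == 1L,
         location = location, pressure = pressure, mesh = sys$mesh),
    class = "capstress_sweep"
  )
}

#' Sweep luminal pressure with and without a crystal
#'
#' For each pressure, reports the PCS with the crystal at expansion `d_um`,
#' the crystal-free baseline PCS, the local PCS-versus-expansion slope (the
#' unit-expansion stress gain at the arg-max node), and whether the PCS
#' arg-max is collocated with the crystal band.
#'
#' @param location Crystal location.
#' @param d_um Crystal expansion, um.
#' @param P_values Pressure grid, kPa (default: 70-200 mmHg truncated to one
#'   decimal in kPa, as quoted clinically).
#' @inheritParams expansion_sweep
#' @return Object of class `capstress_sweep` (kind `"pressure"`): `data`
#'   tibble (`P_kpa`, `pcs_kpa`, `baseline_kpa`, `slope_kpa_per_um`,
#'   `collocated`), plus the least-squares slope of PCS vs P.
#' @export
pressure_sweep <- function(location = "shoulder", d_um = 2,
                           P_values = kpa_1dp(mmhg_to_kpa(
                             c(70, 90, 110, 130, 150, 170, 200))),
                           params = morphology_params(),
                           crystal = crystal_spec(location),
                           materials = default_materials(),
                           refinement = 1L) {
  stopifnot(length(P_values) >= 1L, all(P_values >= 0))
  s <- scenario("sweep", params = params,
                crystals = list(crystal_spec(location, crystal$length,
                                             crystal$thickness, 0)),
                pressure = 1, materials = materials)
  sys <- scenario_system(s, refinement) # f_p at unit pressure
  eg <- sys$eigs[[1]]
  f_e1 <- eigenstrain_load(sys$mesh, eg$elements, eg$eps_r_per_um,
                           materials$crystal)
  sol_p <- fem_solve(sys$asm, sys$f_p)
  sol_e <- fem_solve(sys$asm, f_e1)
  st_p <- recover_stress(sol_p, materials)
  st_e <- recover_stress(sol_e, materials,
                         eigenstrains = list(list(elements = eg$elements,
                                                  eps_r = eg$eps_r_per_um)))
  mask <- cap_mask(st_p, sys$mesh)
  base1 <- st_p$sigma_tt[mask] # per unit pressure
  gain <- st_e$sigma_tt[mask] # per um expansion
  cap_th <- st_p$theta[mask]
  band_th <- band_theta_range(sys$mesh, location)
  margin <- sys$mesh$meta$elem_arc_deg
  rows <- lapply(P_values, function(P) {
    v <- P * base1 + d_um * gain
    i <- which.max(v)
    tibble::tibble(
      P_kpa = P, pcs_kpa = v[i], baseline_kpa = max(P * base1),
      slope_kpa_per_um = gain[i],
      collocated = cap_th[i] >= band_th[1] - margin &
        cap_th[i] <= band_th[2] + margin
    )
  })
  dat <- dplyr::bind_rows(rows)
  fit <- if (nrow(dat) >= 2L) lm(pcs_kpa ~ P_kpa, data = dat) else NULL
  structure(
    list(kind = "pressure", data = dat,
         slope = if (is.null(fit)) NA_real_ else unname(coef(fit)[2]),
         intercept = if (is.null(fit)) NA_real_ else unname(coef(fit)[1]),
         location = location, d_um = d_um, mesh = sys$mesh),
    class = "capstress_sweep"
  )
}

#' Sensitivity of PCS to the crystal Young's modulus
#'
#' Re-solves each scenario with the crystal modulus scaled by each factor
#' (default 0.5 to 11, i.e. -50% to +1000% of 100 kPa) and reports the largest
#' relative PCS deviation from the unscaled case over all scenarios.
#'
#' @param scenarios List of [scenario()] (default the eight-scenario roster).
#' @param factors Multipliers on the crystal Young's modulus.
#' @param refinement Mesh refinement multiplier.
#' @return Object of class `capstress_sweep` (kind `"sensitivity"`):
#'   `max_deviation_pct` and a `data` tibble (`scenario`, `factor`,
#'   `pcs_kpa`, `deviation_pct`).
#' @export
sensitivity_sweep <- function(scenarios = default_scenarios(),
                              factors = c(0.5, 1, 2, 5, 11),
                              refinement = 1L) {
  stopifnot(all(factors > 0))
  if (!any(abs(factors - 1) < 1e-12)) factors <- sort(c(1, factors))
  rows <- list()
  for (s in scenarios) {
    sys <- scenario_system(s, refinement)
    has_crystal <- "crystal" %in% names(sys$asm$K_region)
    K_other <- Reduce(`+`, sys$asm$K_region[setdiff(names(sys$asm$K_region),
                                                    "crystal")])
    pcs_by_factor <- vapply(factors, function(fac) {
      if (!has_crystal && fac != 1) {
        return(NA_real_) # filled from the factor-1 value below
      }
      K <- if (has_crystal) K_other + fac * sys$asm$K_region$crystal else
        K_other
      asm <- structure(list(K = K, K_region = NULL, ndof = sys$asm$ndof,
                            mesh = sys$mesh), class = "fem_assembly")
      # eigenstrain force scales with the crystal modulus
      sol <- fem_solve(asm, sys$f_p + fac * sys$f_e)
      mats <- s$materials
      mats$crystal <- mat_iso(mats$crystal$E * fac, mats$crystal$nu)
      st <- recover_stress(sol, mats, eigenstrains = sys$eigs)
      peak_cap_stress(st, sys$mesh)$pcs
    }, numeric(1))
    pcs1 <- pcs_by_factor[which.min(abs(factors - 1))]
    pcs_by_factor[is.na(pcs_by_factor)] <- pcs1
    rows[[s$name]] <- tibble::tibble(
      scenario = s$name, factor = factors, pcs_kpa = pcs_by_factor,
      deviation_pct = 100 * abs(pcs_by_factor - pcs1) / pcs1
    )
  }
  dat <- dplyr::bind_rows(rows)
  structure(
    list(kind = "sensitivity", data = dat,
         max_deviation_pct = max(dat$deviation_pct)),
    class = "capstress_sweep"
  )
}

#' @export
print.capstress_sweep <- function(x, ...) {
  cat(sprintf("<capstress_sweep> kind = %s\n", x$kind))
  if (x$kind == "expansion") {
    cat(sprintf("  slope %.4g kPa/um, intercept %.4g kPa, argmax constant: %s\n",
                x$slope, x$intercept, x$argmax_constant))
  } else if (x$kind == "pressure") {
    cat(sprintf("  d = %g um, PCS-vs-P slope %.4g kPa/kPa\n", x$d_um, x$slope))
  } else {
    cat(sprintf("  max |PCS deviation| = %.3g%%\n", x$max_deviation_pct))
  }
  print(head(x$data, 8))
  invisible(x)
}

#' Run the full scenario roster
#'
#' Executes every scenario, extracts PCS and percent change versus the control
#' scenario (the scenario named `"control"`, else the first crystal-free one),
#' and optionally writes `results.csv` and per-scenario VTK fields.
#'
#' @param scenarios Named list of [scenario()] (default the eight-case roster).
#' @param refinement Mesh refinement multiplier.
#' @param out_dir Optional output directory for `results.csv` and VTK files.
#' @return Tibble: `scenario`, `pcs_kpa`, `pcs_r_mm`, `pcs_theta_deg`,
#'   `pct_change`, `error` (NA unless that scenario failed). Failures are
#'   collected, not propagated.
#' @export
run_all <- function(scenarios = default_scenarios(), refinement = 1L,
                    out_dir = NULL) {
  nms <- unname(vapply(scenarios, function(s) s$name, character(1)))
  if (anyDuplicated(nms)) abort("scenario names must be unique.")
  fits <- lapply(scenarios, function(s) {
    tryCatch(run_scenario(s, refinement), error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  ctrl_idx <- which(nms == "control")
  if (!length(ctrl_idx)) {
    ctrl_idx <- which(vapply(scenarios, function(s) length(s$crystals) == 0L,
                             logical(1)))[1]
  }
  ctrl_pcs <- if (length(ctrl_idx) && !failed[ctrl_idx[1]]) {
    fits[[ctrl_idx[1]]]$pcs$pcs
  } else {
    NA_real_
  }
  res <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    if (failed[i]) {
      tibble::tibble(scenario = nms[i], pcs_kpa = NA_real_,
                     pcs_r_mm = NA_real_, pcs_theta_deg = NA_real_,
                     pct_change = NA_real_,
                     error = conditionMessage(fits[[i]]))
    } else {
      p <- fits[[i]]$pcs
      tibble::tibble(
        scenario = nms[i], pcs_kpa = p$pcs, pcs_r_mm = p$r,
        pcs_theta_deg = p$theta,
        pct_change = if (is.na(ctrl_pcs)) NA_real_ else
          percent_change(p$pcs, ctrl_pcs),
        error = NA_character_
      )
    }
  }))
  if (any(failed)) {
    warn(paste0("scenario(s) failed: ",
                paste(nms[failed], collapse = ", ")))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    for (i in seq_along(fits)) {
      if (!failed[i]) {
        write_vtk(fits[[i]]$mesh, file.path(out_dir, paste0(nms[i], ".vtk")),
                  stress = fits[[i]]$stress,
                  displacement = fits[[i]]$solution)
      }
    }
  }
  res
}
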