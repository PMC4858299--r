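# Shared fixtures and memoised heavy computations (one FEM solve feeds many
# assertions across files; testthat sources helpers once per run).

.capstress_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.capstress_cache[[key]])) {
    .capstress_cache[[key]] <- force(expr)
  }
  .capstress_cache[[key]]
}

lame_case <- function() {
  list(a = 1, b = 2, E = 100, nu = 0.3, P = 14.6,
       mats = list(annulus = mat_iso(100, 0.3)))
}

lame_hoop_exact <- function(r, a = 1, b = 2, P = 14.6) {
  P * a^2 / (b^2 - a^2) * (1 + b^2 / r^2)
}

# Lame solutions at three refinements (benchmark + convergence)
cached_lame <- function() {
  cached("lame", {
    lc <- lame_case()
    lapply(1:3, function(ref) {
      mesh <- build_annulus_mesh(lc$a, lc$b, n_r = 8L * ref,
                                 n_theta = 24L * ref)
      sol <- fem_solve(fem_assemble(mesh, lc$mats),
                       pressure_load(mesh, lc$P))
      st <- recover_stress(sol, lc$mats)
      list(mesh = mesh, sol = sol, stress = st)
    })
  })
}

cached_run_all <- function() {
  cached("run_all", run_all())
}

cached_control <- function() {
  cached("control", run_scenario(scenario("control")))
}

cached_expansion_sweep <- function() {
  cached("exp_sweep", expansion_sweep("shoulder"))
}

cached_sensitivity <- function() {
  cached("sens", sensitivity_sweep())
}

# a distorted two-element Q8 patch with an interior shared edge
patch_mesh <- function() {
  nodes <- rbind(
    c(0, 0), c(1.1, 0.1), c(2, 0),      # bottom corners
    c(0, 1), c(0.9, 1.2), c(2.1, 1.1),  # top corners
    c(0.55, 0.03), c(1.5, 0.07),        # bottom midsides
    c(0.52, 1.12), c(1.55, 1.17),       # top midsides
    c(-0.02, 0.5), c(1.02, 0.63), c(2.07, 0.54) # vertical midsides
  )
  elements <- rbind(
    c(1L, 2L, 5L, 4L, 7L, 12L, 9L, 11L),
    c(2L, 3L, 6L, 5L, 8L, 13L, 10L, 12L)
  )
  edges <- tibble::tibble(group = character(), element = integer(),
                          n1 = integer(), nm = integer(), n2 = integer())
  q8_mesh(nodes, elements, rep("patch", 2L), edges, center = c(10, 10))
}

# micro-OCT cohort: simulate + measure n crystals, return error table in px
measure_cohort <- function(n, seed = 7L) {
  co <- sim_crystal_cohort(n, seed = seed)
  rows <- lapply(seq_len(n), function(i) {
    s <- simulate_bscan(sim_spec(co[i, ], seed = seed + 100L + i))
    roi <- c(max(1, co$row_top[i] - 30),
             min(1024, co$row_top[i] + co$opt_thickness_px[i] + 30),
             max(1, co$col_start[i] - 20), min(512, co$col_end[i] + 20))
    mm <- tryCatch(measure_crystal(detect_crystal(s$scan, roi), s$scan),
                   error = function(e) NULL)
    if (is.null(mm)) {
      return(tibble::tibble(crystal = i, failed = TRUE,
                            length_um = NA_real_, thickness_um = NA_real_,
                            err_len_px = NA_real_, err_th_px = NA_real_))
    }
    tibble::tibble(
      crystal = i, failed = FALSE,
      length_um = mm$length_um, thickness_um = mm$thickness_um,
      err_len_px = abs(mm$length_um - s$truth$length_um) / (872 / 512),
      err_th_px = abs(mm$thickness_um - s$truth$thickness_um) * 1.33 /
        (1400 / 1024)
    )
  })
  dplyr::bind_rows(rows)
}

cached_cohort100 <- function() {
  cached("cohort100", measure_cohort(100L, seed = 7L))
}
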