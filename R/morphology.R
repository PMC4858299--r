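#' Plaque cross-section morphometrics
#'
#' Bundle the morphometric parameters of the idealized atherosclerotic coronary
#' cross-section. Defaults are the population means reported for thin-cap
#' fibroatheromas: a 91 um fibrous cap, 5.77 mm^2 lumen, a necrotic core
#' subtending 84.65 degrees with area 2.22 mm^2, and 70.53% area stenosis.
#'
#' The lumen is circular, the necrotic core an annular sector abluminal of the
#' cap, and the plaque the remaining annulus between lumen and arterial wall.
#' `lumen_area`, `cap_thickness`, `core_arc` and `core_area` are primary;
#' `stenosis_severity` fixes the outer (EEM) radius unless `wall_thickness`
#' overrides it. The printed relative core metrics are reported back as
#' diagnostics by [derive_geometry()], not imposed as constraints.
#'
#' @param cap_thickness Fibrous cap thickness, mm. Observed range 0.025-0.370.
#' @param lumen_area Lumen area, mm^2.
#' @param core_arc Necrotic core arc angle, degrees.
#' @param core_area Necrotic core area, mm^2.
#' @param stenosis_severity Area stenosis fraction, 1 - lumen/EEM area.
#' @param wall_thickness Optional media+adventitia thickness outside the plaque
#'   bed, mm. When given it overrides `stenosis_severity` as the closure for the
#'   outer radius.
#' @return An object of class `morphology_params`.
#' @examples
#' p <- morphology_params()
#' derive_geometry(p)
#' @export
morphology_params <- function(cap_thickness = 0.091,
                              lumen_area = 5.77,
                              core_arc = 84.65,
                              core_area = 2.22,
                              stenosis_severity = 0.7053,
                              wall_thickness = NULL) {
  stopifnot(
    is.numeric(cap_thickness), length(cap_thickness) == 1L,
    is.numeric(lumen_area), is.numeric(core_arc), is.numeric(core_area)
  )
  if (cap_thickness <= 0 || lumen_area <= 0 || core_area <= 0) {
    abort("cap_thickness, lumen_area and core_area must all be positive.")
  }
  if (core_arc <= 0 || core_arc >= 360) {
    abort("core_arc must lie strictly between 0 and 360 degrees.")
  }
  if (stenosis_severity <= 0 || stenosis_severity >= 1) {
    abort("stenosis_severity must be a fraction strictly between 0 and 1.")
  }
  if (!is.null(wall_thickness) && wall_thickness <= 0) {
    abort("wall_thickness override must be positive.")
  }
  structure(
    list(
      cap_thickness = cap_thickness,
      lumen_area = lumen_area,
      core_arc = core_arc,
      core_area = core_area,
      stenosis_severity = stenosis_severity,
      wall_thickness = wall_thickness
    ),
    class = "morphology_params"
  )
}

#' @export
print.morphology_params <- function(x, ...) {
  cat("<morphology_params>\n")
  cat(sprintf("  cap thickness     %.3f mm\n", x$cap_thickness))
  cat(sprintf("  lumen area        %.2f mm^2\n", x$lumen_area))
  cat(sprintf("  core arc          %.2f deg\n", x$core_arc))
  cat(sprintf("  core area         %.2f mm^2\n", x$core_area))
  if (is.null(x$wall_thickness)) {
    cat(sprintf("  stenosis severity %.2f%%\n", 100 * x$stenosis_severity))
  } else {
    cat(sprintf("  wall thickness    %.3f mm (override)\n", x$wall_thickness))
  }
  invisible(x)
}

#' Derive the concentric radii of the idealized cross-section
#'
#' Solves the annular-sector geometry in closed form: the lumen radius from the
#' lumen area, the core inner radius as lumen radius + cap thickness, the core
#' outer radius so the sector of angle `core_arc` has exactly `core_area`, and
#' the outer (EEM) radius so the area stenosis matches `stenosis_severity`
#' (or, with a `wall_thickness` override, core outer radius + wall thickness).
#'
#' @param params A [morphology_params()] object.
#' @return An object of class `derived_geometry`: a list with `lumen_radius`,
#'   `core_inner_radius`, `core_outer_radius`, `vessel_outer_radius`,
#'   `reference_area` (all mm / mm^2) and a `diagnostics` tibble with the
#'   relative core area/thickness implied by the reconstruction.
#' @examples
#' derive_geometry(morphology_params())
#' @export
derive_geometry <- function(params) {
  stopifnot(inherits(params, "morphology_params"))
  r_lumen <- sqrt(params$lumen_area / pi)
  r_ci <- r_lumen + params$cap_thickness
  # annular sector: (arc/360) * pi * (r_co^2 - r_ci^2) = core_area
  r_co <- sqrt(r_ci^2 + params$core_area * 360 / (params$core_arc * pi))
  if (!is.finite(r_co) || r_co <= r_ci) {
    abort("core_area is unachievable for the given arc and radii.")
  }
  if (is.null(params$wall_thickness)) {
    r_out <- sqrt(params$lumen_area / (pi * (1 - params$stenosis_severity)))
    if (r_out <= r_co) {
      abort(paste0(
        "stenosis_severity implies a vessel outer radius (", signif(r_out, 5),
        " mm) inside the core outer radius (", signif(r_co, 5),
        " mm): non-positive wall thickness."
      ))
    }
  } else {
    r_out <- r_co + params$wall_thickness
  }
  ref_area <- pi * r_out^2
  plaque_bed_area <- pi * (r_co^2 - r_lumen^2)
  diagnostics <- tibble::tibble(
    metric = c(
      "area_stenosis", "relative_core_area", "relative_core_thickness",
      "wall_thickness_mm"
    ),
    value = c(
      1 - params$lumen_area / ref_area,
      params$core_area / plaque_bed_area,
      (r_co - r_ci) / (r_out - r_lumen),
      r_out - r_co
    )
  )
  structure(
    list(
      lumen_radius = r_lumen,
      core_inner_radius = r_ci,
      core_outer_radius = r_co,
      vessel_outer_radius = r_out,
      reference_area = ref_area,
      params = params,
      diagnostics = diagnostics
    ),
    class = "derived_geometry"
  )
}

#' @export
print.derived_geometry <- function(x, ...) {
  cat("<derived_geometry> (mm)\n")
  cat(sprintf(
    "  lumen %.4f | core inner %.4f | core outer %.4f | vessel outer %.4f\n",
    x$lumen_radius, x$core_inner_radius, x$core_outer_radius,
    x$vessel_outer_radius
  ))
  invisible(x)
}

#' Sample a plausible plaque morphology
#'
#' Draws a cap thickness uniformly over the observed 25-370 um range and
#' jitters the remaining primary morphometrics about their printed means by a
#' uniform multiplicative factor of +/- `jitter`. Draws that fail to close the
#' annular-sector geometry (non-positive wall thickness) are rejected and
#' resampled.
#'
#' @param seed Optional integer seed; fixed seed gives reproducible draws.
#' @param jitter Half-width of the relative jitter on lumen area, core arc and
#'   core area (default 0.10). `jitter = 0` returns the printed means with only
#'   the cap thickness random.
#' @param retries Rejection-sampling budget.
#' @return A [morphology_params()] object.
#' @export
sample_morphology <- function(seed = NULL, jitter = 0.10, retries = 100L) {
  stopifnot(jitter >= 0, jitter < 1)
  draw <- function() {
    cap <- runif(1, 0.025, 0.370)
    f <- function(mu) mu * (1 + runif(1, -jitter, jitter))
    morphology_params(
      cap_thickness = cap,
      lumen_area = f(5.77),
      core_arc = f(84.65),
      core_area = f(2.22)
    )
  }
  run <- function() {
    for (i in seq_len(retries)) {
      p <- draw()
      ok <- tryCatch(
        {
          derive_geometry(p)
          TRUE
        },
        error = function(e) FALSE
      )
      if (ok) {
        return(p)
      }
    }
    abort("sample_morphology: no feasible geometry within the retry budget.")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
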