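#' Specify a cholesterol crystal
#'
#' A thin plate-like crystal lying tangentially at the abluminal face of the
#' fibrous cap. Default dimensions are the micro-OCT cohort means (length
#' 269.1 um, thickness 3.0 um). Crystallization growth is expressed as an
#' expansion `expansion_um` of the total thickness.
#'
#' @param location One of `"shoulder"`, `"halfway"`, `"center"` — fractions
#'   1, 0.5, 0 of the half core arc measured from the cap center.
#' @param length Crystal length, mm.
#' @param thickness Crystal thickness, mm.
#' @param expansion_um Thickness-direction expansion d, um (>= 0).
#' @return An object of class `crystal_spec`.
#' @examples
#' crystal_spec("shoulder", expansion_um = 2)
#' @export
crystal_spec <- function(location = c("shoulder", "halfway", "center"),
                         length = 0.2691, thickness = 0.0030,
                         expansion_um = 2) {
  location <- match.arg(location)
  stopifnot(length > 0, thickness > 0, expansion_um >= 0)
  if (length <= thickness) abort("crystal length must exceed its thickness.")
  structure(
    list(location = location, length = length, thickness = thickness,
         expansion_um = expansion_um),
    class = "crystal_spec"
  )
}

#' @export
print.crystal_spec <- function(x, ...) {
  cat(sprintf("<crystal_spec> %s: %.1f um x %.1f um, expansion d = %g um\n",
              x$location, 1000 * x$length, 1000 * x$thickness, x$expansion_um))
  invisible(x)
}

#' Locate the mesh elements of a crystal
#'
#' Returns the element ids of the crystal band carved at `spec$location` when
#' the mesh was built; errors if the mesh has no band there.
#'
#' @param mesh A `q8_mesh` built by [build_half_model()] with this crystal.
#' @param spec A [crystal_spec()].
#' @return Integer vector of element ids (all tagged `crystal`).
#' @export
place_crystal <- function(mesh, spec) {
  stopifnot(inherits(mesh, "q8_mesh"), inherits(spec, "crystal_spec"))
  band <- mesh$meta$crystal_bands[[spec$location]]
  if (is.null(band) || length(band) == 0L) {
    abort(paste0("mesh has no crystal band at location '", spec$location,
                 "'; rebuild the mesh with this crystal."))
  }
  band
}

#' Convert crystal expansion to an eigenstrain load
#'
#' Crystal growth of `d` um in the thickness direction is modelled as a
#' stress-free eigenstrain of d / thickness along the local radial direction
#' (thermal-expansion analogy): free expansion reproduces exactly d of
#' thickness increase, and the surrounding tissue compliance sets the actual
#' displacement. The load composes linearly under superposition.
#'
#' @param spec A [crystal_spec()].
#' @param material Crystal material (default 100 kPa, nu 0.49).
#' @return Object of class `crystal_load`: `eps_r` (dimensionless),
#'   `eps_r_per_um` (eigenstrain per um of expansion), and the material.
#' @examples
#' expansion_to_eigenstrain(crystal_spec("shoulder", expansion_um = 2))$eps_r
#' @export
expansion_to_eigenstrain <- function(spec,
                                     material = default_materials()$crystal) {
  stopifnot(inherits(spec, "crystal_spec"), spec$thickness > 0)
  per_um <- 1e-3 / spec$thickness
  structure(
    list(eps_r = spec$expansion_um * per_um, eps_r_per_um = per_um,
         material = material),
    class = "crystal_load"
  )
}
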