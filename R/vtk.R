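#' Export a mesh (and optional fields) as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid of quadratic quadrilaterals
#' (cell type 23) with the region tag as cell data and, when supplied, nodal
#' stress components (kPa) and displacements (mm) as point data. Nodal
#' stresses that differ across regions at an interface are averaged for
#' export.
#'
#' @param mesh A `q8_mesh`.
#' @param file Output path.
#' @param stress Optional `stress_field` tibble from [recover_stress()].
#' @param displacement Optional `fem_solution` (or tibble from
#'   [displacement_field()]).
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, file, stress = NULL, displacement = NULL) {
  stopifnot(inherits(mesh, "q8_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("capstress plaque model")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS ", ne, " ", ne * 9L)
  writeLines(apply(mesh$elements - 1L, 1L, function(r) {
    paste(c(8L, r), collapse = " ")
  }), con)
  wl("CELL_TYPES ", ne)
  writeLines(rep("23", ne), con)
  wl("CELL_DATA ", ne)
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  regs <- sort(unique(mesh$region))
  writeLines(as.character(match(mesh$region, regs) - 1L), con)

  have_pt <- !is.null(stress) || !is.null(displacement)
  if (have_pt) wl("POINT_DATA ", n)
  if (!is.null(stress)) {
    for (comp in c("sigma_rr", "sigma_tt", "sigma_rt", "sigma_zz")) {
      v <- tapply(stress[[comp]], stress$node, mean)
      full <- numeric(n)
      full[as.integer(names(v))] <- v
      wl("SCALARS ", comp, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.10g", full), con)
    }
  }
  if (!is.null(displacement)) {
    u <- if (inherits(displacement, "fem_solution")) displacement$u else
      as.matrix(displacement[, c("ux", "uy")])
    wl("VECTORS displacement double")
    writeLines(sprintf("%.10g %.10g 0", u[, 1], u[, 2]), con)
  }
  invisible(file)
}
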