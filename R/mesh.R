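# Structured meshes of 8-node serendipity quadrilaterals (Q8) on polar blocks.
# Node convention per element: corners 1-4 counterclockwise, then midsides
# 5 (1-2), 6 (2-3), 7 (3-4), 8 (4-1); local xi runs radially, eta tangentially.

#' Low-level Q8 mesh constructor
#'
#' @param nodes Numeric matrix n x 2 of (x, y) coordinates, mm.
#' @param elements Integer matrix n_el x 8 of node indices (corners then
#'   midsides, counterclockwise).
#' @param region Character vector of region tags per element.
#' @param edges Tibble of boundary edges: columns `group`, `element`, and
#'   `n1`, `nm`, `n2` (the three nodes along the quadratic edge).
#' @param center Coordinates of the lumen center used for cylindrical frames.
#' @param meta Optional list of provenance (geometry, crystal bands, ...).
#' @return An object of class `q8_mesh`.
#' @export
q8_mesh <- function(nodes, elements, region, edges, center = c(0, 0),
                    meta = list()) {
  nodes <- as.matrix(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (nrow(elements) == 0L || nrow(nodes) == 0L) {
    abort("empty mesh: no nodes or no elements.")
  }
  stopifnot(ncol(nodes) == 2L, ncol(elements) == 8L,
            length(region) == nrow(elements))
  structure(
    list(
      nodes = nodes, elements = elements, region = as.character(region),
      edges = edges, center = as.numeric(center), meta = meta
    ),
    class = "q8_mesh"
  )
}

#' @export
print.q8_mesh <- function(x, ...) {
  cat(sprintf(
    "<q8_mesh> %d nodes, %d elements (%s)\n",
    nrow(x$nodes), nrow(x$elements),
    paste(sprintf("%s: %d", names(table(x$region)), table(x$region)),
          collapse = ", ")
  ))
  invisible(x)
}

# Build a structured Q8 grid on the tensor product of radial break lines and
# angular break lines (degrees). Serendipity lattice: nodes on a (2nr+1) x
# (2nt+1) grid with both-odd entries absent.
q8_grid_polar <- function(r_breaks, theta_breaks_deg, center = c(0, 0)) {
  nr <- length(r_breaks) - 1L
  nt <- length(theta_breaks_deg) - 1L
  stopifnot(nr >= 1L, nt >= 1L, !is.unsorted(r_breaks),
            !is.unsorted(theta_breaks_deg))
  rline <- numeric(2L * nr + 1L)
  rline[seq(1L, 2L * nr + 1L, by = 2L)] <- r_breaks
  rline[seq(2L, 2L * nr, by = 2L)] <- (r_breaks[-1] + r_breaks[-(nr + 1L)]) / 2
  tline <- numeric(2L * nt + 1L)
  tline[seq(1L, 2L * nt + 1L, by = 2L)] <- theta_breaks_deg
  tline[seq(2L, 2L * nt, by = 2L)] <-
    (theta_breaks_deg[-1] + theta_breaks_deg[-(nt + 1L)]) / 2

  # serendipity lattice: drop the nodes where both 0-based indices are odd
  present <- !(outer((seq_len(2L * nr + 1L) - 1L) %% 2L == 1L,
                     (seq_len(2L * nt + 1L) - 1L) %% 2L == 1L, `&`))
  id <- matrix(NA_integer_, 2L * nr + 1L, 2L * nt + 1L)
  id[present] <- seq_len(sum(present))

  th <- rep(tline, each = 2L * nr + 1L)[as.vector(present)]
  rr <- rep(rline, times = 2L * nt + 1L)[as.vector(present)]
  rad <- th * pi / 180
  nodes <- cbind(center[1] + rr * cos(rad), center[2] + rr * sin(rad))

  elems <- matrix(0L, nr * nt, 8L)
  e <- 0L
  for (j in seq_len(nt)) {
    b0 <- 2L * (j - 1L) + 1L
    for (i in seq_len(nr)) {
      a0 <- 2L * (i - 1L) + 1L
      e <- e + 1L
      elems[e, ] <- c(
        id[a0, b0], id[a0 + 2L, b0], id[a0 + 2L, b0 + 2L], id[a0, b0 + 2L],
        id[a0 + 1L, b0], id[a0 + 2L, b0 + 1L], id[a0 + 1L, b0 + 2L],
        id[a0, b0 + 1L]
      )
    }
  }
  list(
    nodes = nodes, elements = elems, nr = nr, nt = nt, id = id,
    r_breaks = r_breaks, theta_breaks = theta_breaks_deg,
    elem_index = function(i, j) (j - 1L) * nr + i
  )
}

# Edge tibble rows for a structured polar grid.
polar_edge_groups <- function(grid) {
  nr <- grid$nr
  nt <- grid$nt
  el <- grid$elements
  idx <- grid$elem_index
  rows <- list()
  add <- function(group, element, n1, nm, n2) {
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(group = group, element = element, n1 = n1, nm = nm, n2 = n2)
  }
  for (j in seq_len(nt)) { # inner (lumen) and outer boundaries
    e <- idx(1L, j)
    add("lumen_surface", e, el[e, 1L], el[e, 8L], el[e, 4L])
    e <- idx(nr, j)
    add("outer_boundary", e, el[e, 2L], el[e, 6L], el[e, 3L])
  }
  for (i in seq_len(nr)) { # the two symmetry edges (theta = 0 and theta = 180)
    e <- idx(i, 1L)
    add("symmetry_line", e, el[e, 1L], el[e, 5L], el[e, 2L])
    e <- idx(i, nt)
    add("symmetry_line", e, el[e, 4L], el[e, 7L], el[e, 3L])
  }
  dplyr::bind_rows(rows)
}

subdivide <- function(a, b, n) seq(a, b, length.out = n + 1L)

#' Build the half cross-section plaque mesh
#'
#' Constructs the structured half-annulus mesh (180 degrees about the symmetry
#' axis through the cap center) with graded radial layers: fibrous cap between
#' lumen and core interface, necrotic core sector over half the core arc,
#' plaque annulus, and arterial wall outside the plaque bed. Each requested
#' crystal becomes a band of elements one element thick (the crystal thickness)
#' at the abluminal face of the cap, tagged `crystal`.
#'
#' Crystal location angles are fractions of the half core arc measured from the
#' cap center on the symmetry axis: `center` = 0, `halfway` = 0.5,
#' `shoulder` = 1 (the core-arc end). A `center` crystal straddles the symmetry
#' axis, so the half model carries half its length.
#'
#' @param params A [morphology_params()] object.
#' @param crystals List of [crystal_spec()] objects at distinct locations. All
#'   must share one thickness (one slot layer is carved in the cap).
#' @param refinement Positive integer mesh-density multiplier. The default
#'   yields roughly 1200 elements for the crystal-free model.
#' @return A `q8_mesh` with region tags in `artery`, `plaque`, `core`,
#'   `crystal`, boundary edge groups `lumen_surface`, `symmetry_line`,
#'   `outer_boundary`, and `meta` carrying the derived geometry and the element
#'   ids of each crystal band.
#' @examples
#' m <- build_half_model(morphology_params())
#' m
#' @export
build_half_model <- function(params = morphology_params(), crystals = list(),
                             refinement = 1L) {
  stopifnot(inherits(params, "morphology_params"))
  refinement <- as.integer(refinement)
  if (is.na(refinement) || refinement < 1L) {
    abort("refinement must be a positive integer.")
  }
  if (inherits(crystals, "crystal_spec")) crystals <- list(crystals)
  geom <- derive_geometry(params)
  half_core <- params$core_arc / 2

  slot_t <- 0
  if (length(crystals) > 0L) {
    locs <- vapply(crystals, function(s) s$location, character(1))
    if (anyDuplicated(locs)) abort("crystal locations must be distinct.")
    ths <- vapply(crystals, function(s) s$thickness, numeric(1))
    if (diff(range(ths)) > 1e-12) {
      abort("all crystals must share one thickness (a single slot layer).")
    }
    slot_t <- ths[1]
    if (slot_t >= params$cap_thickness / 2) {
      abort("crystal thicker than the cap layer budget (cap_thickness / 2).")
    }
  }

  # radial break lines: cap (2*ref layers) [+ crystal slot], core annulus
  # (6*ref), wall (3*ref)
  r_cap <- subdivide(geom$lumen_radius, geom$core_inner_radius - slot_t,
                     2L * refinement)
  r_breaks <- r_cap
  if (slot_t > 0) r_breaks <- c(r_breaks, geom$core_inner_radius)
  r_breaks <- c(
    r_breaks,
    subdivide(geom$core_inner_radius, geom$core_outer_radius,
              6L * refinement)[-1],
    subdivide(geom$core_outer_radius, geom$vessel_outer_radius,
              3L * refinement)[-1]
  )
  # angular break lines: the core half-arc and the remainder, widths ~1.7 deg
  t_breaks <- c(
    subdivide(0, half_core, 25L * refinement),
    subdivide(half_core, 180, 83L * refinement)[-1]
  )

  grid <- q8_grid_polar(r_breaks, t_breaks)
  edges <- polar_edge_groups(grid)

  # region tags from element centroids in (r, theta)
  rc <- (r_breaks[-1] + r_breaks[-length(r_breaks)]) / 2
  tc <- (t_breaks[-1] + t_breaks[-length(t_breaks)]) / 2
  cent_r <- rep(rc, times = grid$nt)
  cent_t <- rep(tc, each = grid$nr)
  region <- ifelse(
    cent_r > geom$core_outer_radius, "artery",
    ifelse(cent_r > geom$core_inner_radius & cent_t < half_core,
           "core", "plaque")
  )

  crystal_bands <- list()
  if (slot_t > 0) {
    slot_row <- 2L * refinement + 1L # the thin layer just under the interface
    w_deg <- half_core / (25L * refinement) # element arc width in the core block
    r_slot <- geom$core_inner_radius - slot_t / 2
    w_len <- r_slot * w_deg * pi / 180
    for (s in crystals) {
      frac <- c(center = 0, halfway = 0.5, shoulder = 1)[[s$location]]
      theta_c <- frac * half_core
      if (s$location == "center") {
        n_band <- ceiling((s$length / 2) / w_len)
        jset <- seq_len(n_band)
      } else {
        n_band <- ceiling(s$length / w_len)
        j_mid <- which.min(abs(tc - theta_c))
        jset <- seq(j_mid - (n_band %/% 2L), length.out = n_band)
        jset <- jset[jset >= 1L & jset <= grid$nt]
      }
      ids <- grid$elem_index(slot_row, jset)
      if (any(region[ids] == "crystal")) {
        abort("overlapping crystal bands at the requested locations.")
      }
      region[ids] <- "crystal"
      crystal_bands[[s$location]] <- ids
    }
  }

  q8_mesh(
    grid$nodes, grid$elements, region, edges,
    center = c(0, 0),
    meta = list(
      geometry = geom, params = params, crystals = crystals,
      refinement = refinement, crystal_bands = crystal_bands,
      half_core_arc = half_core, slot_thickness = slot_t,
      elem_arc_deg = half_core / (25L * refinement),
      target_areas = c(
        total = pi * (geom$vessel_outer_radius^2 - geom$lumen_radius^2) / 2,
        core = params$core_area / 2
      )
    )
  )
}

#' Build a plain half-annulus benchmark mesh
#'
#' A single-material half annulus (inner radius `a`, outer radius `b`) used for
#' closed-form validation against the thick-walled-cylinder (Lame) solution.
#'
#' @param a,b Inner and outer radii, mm.
#' @param n_r,n_theta Element counts radially and over the 180 degree span.
#' @param region Region tag applied to every element.
#' @return A `q8_mesh`.
#' @export
build_annulus_mesh <- function(a, b, n_r = 8L, n_theta = 24L,
                               region = "annulus") {
  stopifnot(a > 0, b > a)
  grid <- q8_grid_polar(subdivide(a, b, n_r), subdivide(0, 180, n_theta))
  q8_mesh(grid$nodes, grid$elements, rep(region, n_r * n_theta),
          polar_edge_groups(grid),
          meta = list(target_areas = c(total = pi * (b^2 - a^2) / 2)))
}

#' Mesh quality and invariant diagnostics
#'
#' Checks every element Jacobian at the 3x3 quadrature points, integrates
#' region areas against their targets, and verifies edge conformity (shared
#' corner pairs must share the midside node).
#'
#' @param mesh A `q8_mesh`.
#' @param error If `TRUE` (default), violations raise a structured error
#'   listing offending elements; otherwise the report is returned with
#'   `ok = FALSE`.
#' @param area_tol Relative tolerance on region areas with known targets.
#' @return A list of class `mesh_diagnostics`: `ok`, `min_jacobian`,
#'   `bad_elements`, `areas` (tibble of integrated region areas and relative
#'   errors), `nonconforming_edges`.
#' @export
validate_mesh <- function(mesh, error = TRUE, area_tol = 0.02) {
  stopifnot(inherits(mesh, "q8_mesh"))
  gp <- gauss_2d(3L)
  n_el <- nrow(mesh$elements)
  min_j <- Inf
  bad <- integer(0)
  areas <- numeric(n_el)
  for (e in seq_len(n_el)) {
    xy <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    dets <- vapply(seq_len(nrow(gp$pts)), function(q) {
      dN <- q8_shape(gp$pts[q, 1], gp$pts[q, 2])$dN
      det(crossprod(dN, xy))
    }, numeric(1))
    min_j <- min(min_j, dets)
    if (any(dets <= 0)) bad <- c(bad, e)
    areas[e] <- sum(dets * gp$w)
  }
  area_tbl <- tibble::tibble(
    region = names(split(areas, mesh$region)),
    area = vapply(split(areas, mesh$region), sum, numeric(1))
  )
  targets <- mesh$meta$target_areas
  area_tbl$target <- NA_real_
  area_tbl$rel_error <- NA_real_
  if (!is.null(targets)) {
    tot <- sum(areas)
    rows <- list()
    if ("total" %in% names(targets)) {
      rows$total <- c(tot, targets[["total"]])
    }
    if ("core" %in% names(targets) && "core" %in% area_tbl$region) {
      # the crystal slot carves a sliver out of the core annulus target
      rows$core <- c(area_tbl$area[area_tbl$region == "core"],
                     targets[["core"]])
    }
    extra <- tibble::tibble(
      region = names(rows),
      area = vapply(rows, `[`, numeric(1), 1L),
      target = vapply(rows, `[`, numeric(1), 2L)
    )
    extra$rel_error <- abs(extra$area - extra$target) / extra$target
    area_tbl <- dplyr::bind_rows(
      dplyr::filter(extra, .data$region == "total"),
      dplyr::mutate(area_tbl[area_tbl$region != "total", ],
                    target = NULL, rel_error = NULL),
    )
    if ("core" %in% names(rows)) {
      area_tbl$target[area_tbl$region == "core"] <- rows$core[2]
      area_tbl$rel_error[area_tbl$region == "core"] <-
        abs(rows$core[1] - rows$core[2]) / rows$core[2]
    }
  }

  # conformity: group edges by sorted corner pair, midside must agree
  el <- mesh$elements
  c1 <- el[, c(1L, 2L, 3L, 4L)]
  c2 <- el[, c(2L, 3L, 4L, 1L)]
  mid <- el[, c(5L, 6L, 7L, 8L)]
  key <- paste(pmin(c1, c2), pmax(c1, c2))
  nonconf <- unique(key[duplicated(key) | duplicated(key, fromLast = TRUE)])
  bad_edges <- character(0)
  if (length(nonconf)) {
    mids_by_key <- split(as.vector(mid), key)
    bad_edges <- names(Filter(function(m) length(unique(m)) > 1L, mids_by_key))
  }

  core_err <- area_tbl$rel_error[area_tbl$region == "core"]
  ok <- length(bad) == 0L && length(bad_edges) == 0L &&
    (!length(core_err) || is.na(core_err) || core_err <= area_tol)
  out <- structure(
    list(ok = ok, min_jacobian = min_j, bad_elements = bad,
         areas = area_tbl, nonconforming_edges = bad_edges),
    class = "mesh_diagnostics"
  )
  if (!ok && error) {
    abort(c(
      "mesh validation failed",
      if (length(bad)) paste0("non-positive Jacobian in elements: ",
                              paste(head(bad, 10L), collapse = ", ")),
      if (length(bad_edges)) paste0(length(bad_edges), " non-conforming edges"),
      if (length(core_err) && !is.na(core_err) && core_err > area_tol) {
        sprintf("core area error %.2f%% exceeds %.2f%%",
                100 * core_err, 100 * area_tol)
      }
    ))
  }
  out
}

#' @export
print.mesh_diagnostics <- function(x, ...) {
  cat(sprintf("<mesh_diagnostics> ok = %s, min Jacobian = %.3g\n",
              x$ok, x$min_jacobian))
  print(x$areas)
  invisible(x)
}

#' Integrated mesh area
#' @param mesh A `q8_mesh`.
#' @param region Optional region tag to restrict to.
#' @return Area in mm^2 by Gauss integration.
#' @export
mesh_area <- function(mesh, region = NULL) {
  gp <- gauss_2d(3L)
  keep <- if (is.null(region)) seq_len(nrow(mesh$elements)) else
    which(mesh$region == region)
  sum(vapply(keep, function(e) {
    xy <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    sum(vapply(seq_len(nrow(gp$pts)), function(q) {
      dN <- q8_shape(gp$pts[q, 1], gp$pts[q, 2])$dN
      det(crossprod(dN, xy))
    }, numeric(1)) * gp$w)
  }, numeric(1)))
}
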