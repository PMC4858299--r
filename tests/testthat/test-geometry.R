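test_that("derived radii follow the closed-form annular-sector geometry", {
  g <- derive_geometry(morphology_params())
  expect_equal(g$lumen_radius, sqrt(5.77 / pi), tolerance = 1e-12)
  expect_equal(g$lumen_radius, 1.3553, tolerance = 1e-4)
  expect_equal(g$core_inner_radius, g$lumen_radius + 0.091, tolerance = 1e-12)
  # sector area inversion: (arc/360) pi (r_o^2 - r_i^2) = core area
  expect_equal((84.65 / 360) * pi *
                 (g$core_outer_radius^2 - g$core_inner_radius^2),
               2.22, tolerance = 1e-12)
  # stenosis closure of the outer radius
  expect_equal(1 - 5.77 / (pi * g$vessel_outer_radius^2), 0.7053,
               tolerance = 1e-12)
  expect_true(g$lumen_radius < g$core_inner_radius &&
                g$core_inner_radius < g$core_outer_radius &&
                g$core_outer_radius < g$vessel_outer_radius)

  # unit circle (wall override keeps the small vessel feasible)
  g1 <- derive_geometry(morphology_params(lumen_area = pi, core_area = 0.5,
                                          wall_thickness = 0.3))
  expect_equal(g1$lumen_radius, 1, tolerance = 1e-12)

  # wall-thickness override replaces the stenosis closure
  g2 <- derive_geometry(morphology_params(wall_thickness = 0.5))
  expect_equal(g2$vessel_outer_radius, g2$core_outer_radius + 0.5,
               tolerance = 1e-12)
})

test_that("infeasible morphometrics are rejected", {
  expect_error(morphology_params(cap_thickness = -1), "positive")
  expect_error(morphology_params(core_arc = 400), "between 0 and 360")
  expect_error(morphology_params(stenosis_severity = 1.2), "fraction")
  # a huge core arc-area combination that swallows the vessel wall
  expect_error(
    derive_geometry(morphology_params(core_area = 18, core_arc = 84.65)),
    "non-positive wall thickness"
  )
})

test_that("the default half model meshes near the reported element count", {
  mesh <- build_half_model(morphology_params())
  expect_s3_class(mesh, "q8_mesh")
  n_el <- nrow(mesh$elements)
  expect_gt(n_el, 1224 * 0.9)
  expect_lt(n_el, 1224 * 1.1)
  expect_false("crystal" %in% mesh$region)
  diag <- validate_mesh(mesh)
  expect_true(diag$ok)
  expect_gt(diag$min_jacobian, 0)
  core_err <- diag$areas$rel_error[diag$areas$region == "core"]
  expect_lt(core_err, 0.02)
})

test_that("meshed areas and symmetry nodes respect the geometry", {
  mesh <- build_half_model(morphology_params())
  g <- mesh$meta$geometry
  half_area <- pi * (g$vessel_outer_radius^2 - g$lumen_radius^2) / 2
  expect_equal(mesh_area(mesh), half_area, tolerance = 0.005)
  expect_equal(mesh_area(mesh, "core"), 2.22 / 2, tolerance = 0.02)
  sym <- mesh$edges[mesh$edges$group == "symmetry_line", ]
  sym_nodes <- unique(c(sym$n1, sym$nm, sym$n2))
  expect_lt(max(abs(mesh$nodes[sym_nodes, 2])), 1e-12)
})

test_that("refinement increases element count and never degrades areas", {
  m1 <- build_half_model(morphology_params(), refinement = 1)
  m2 <- build_half_model(morphology_params(), refinement = 2)
  expect_gt(nrow(m2$elements), nrow(m1$elements))
  err <- function(m) abs(mesh_area(m, "core") - 2.22 / 2) / (2.22 / 2)
  expect_lte(err(m2), err(m1) + 1e-12)
})

test_that("crystal bands are carved where requested", {
  spec <- crystal_spec("shoulder")
  mesh <- build_half_model(morphology_params(), list(spec))
  band <- mesh$meta$crystal_bands$shoulder
  expect_true(all(mesh$region[band] == "crystal"))
  # centroid angle at the half core arc (the shoulder), within one element
  cent <- t(sapply(band, function(e) {
    colMeans(mesh$nodes[mesh$elements[e, 1:4], ])
  }))
  th <- atan2(cent[, 2], cent[, 1]) * 180 / pi
  expect_equal(mean(th), 84.65 / 2, tolerance = mesh$meta$elem_arc_deg / 42)
  # tangential extent = crystal length within one element width
  r_band <- mean(sqrt(rowSums(cent^2)))
  extent <- diff(range(th)) * pi / 180 * r_band +
    mesh$meta$elem_arc_deg * pi / 180 * r_band
  w_elem <- mesh$meta$elem_arc_deg * pi / 180 * r_band
  expect_lt(abs(extent - 0.2691), w_elem)
})

test_that("invalid crystal requests fail loudly", {
  p <- morphology_params()
  expect_error(
    build_half_model(p, list(crystal_spec("shoulder"),
                             crystal_spec("shoulder"))),
    "distinct"
  )
  expect_error(
    build_half_model(p, list(crystal_spec("shoulder", thickness = 0.09))),
    "budget"
  )
})

test_that("validate_mesh flags inverted elements and empty meshes", {
  mesh <- build_annulus_mesh(1, 2, n_r = 2, n_theta = 4)
  bad <- mesh
  bad$elements[1, ] <- bad$elements[1, c(4L, 3L, 2L, 1L, 7L, 6L, 5L, 8L)]
  expect_error(validate_mesh(bad), "Jacobian")
  rep <- validate_mesh(bad, error = FALSE)
  expect_false(rep$ok)
  expect_true(1L %in% rep$bad_elements)
  expect_error(q8_mesh(matrix(numeric(0), 0, 2),
                       matrix(integer(0), 0, 8), character(0),
                       tibble::tibble()), "empty mesh")
})

test_that("sampled morphologies stay in the printed ranges and mesh cleanly", {
  draws <- lapply(1:50, function(i) sample_morphology(seed = i))
  caps <- vapply(draws, function(p) p$cap_thickness, numeric(1))
  expect_true(all(caps >= 0.025 & caps <= 0.370))
  areas <- vapply(draws, function(p) p$lumen_area, numeric(1))
  expect_true(all(abs(areas / 5.77 - 1) <= 0.10 + 1e-12))
  # reproducible under a fixed seed
  expect_identical(sample_morphology(seed = 42), sample_morphology(seed = 42))
  # zero jitter pins everything but the cap at the printed means
  p0 <- sample_morphology(seed = 1, jitter = 0)
  expect_equal(p0$lumen_area, 5.77)
  expect_equal(p0$core_arc, 84.65)
  expect_equal(p0$core_area, 2.22)
  # every sampled morphology builds a valid mesh
  for (i in c(3, 17, 31)) {
    d <- validate_mesh(build_half_model(draws[[i]]), error = FALSE)
    expect_true(d$ok)
  }
})
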