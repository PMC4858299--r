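test_that("element stiffness is symmetric with a rigid-body null space", {
  xy <- rbind(c(0, 0), c(2.2, 0.1), c(2, 2), c(-0.1, 1.9),
              c(1.1, 0.02), c(2.1, 1.05), c(0.95, 1.97), c(-0.05, 0.95))
  D <- plane_strain_D(mat_transiso(50, 1000, nu_rtheta = 0.01,
                                   nu_thetaz = 0.27, G_rtheta = 500))$D
  K <- element_stiffness(xy, D, center = c(5, 5))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  for (u in list(rep(c(1, 0), 8), rep(c(0, 1), 8),
                 as.vector(t(cbind(-xy[, 2], xy[, 1]))))) {
    expect_lt(max(abs(K %*% u)) / max(abs(K)), 1e-9)
  }
  bad <- xy
  bad[2, ] <- xy[4, ] # collapse the element
  expect_error(element_stiffness(bad, D), "Jacobian")
})

test_that("a distorted Q8 patch reproduces a constant-strain state exactly", {
  mesh <- patch_mesh()
  mats <- list(patch = mat_iso(100, 0.3))
  exx <- 0.01; eyy <- -0.004; gxy <- 0.006
  ufun <- function(x, y) cbind(exx * x + gxy * y, eyy * y)
  interior <- 12L
  boundary <- setdiff(seq_len(nrow(mesh$nodes)), interior)
  ub <- ufun(mesh$nodes[boundary, 1], mesh$nodes[boundary, 2])
  constraints <- tibble::tibble(
    node = rep(boundary, each = 2L),
    dof = rep(c(1L, 2L), length(boundary)),
    value = as.vector(t(ub))
  )
  sol <- fem_solve(fem_assemble(mesh, mats), numeric(26), constraints)
  u_exact <- ufun(mesh$nodes[, 1], mesh$nodes[, 2])
  expect_lt(max(abs(sol$u - u_exact)), 1e-9)
  # recovered stresses equal D eps everywhere, expressed cylindrically
  D <- plane_strain_D(mats$patch)$D
  sig <- as.vector(D %*% c(exx, eyy, gxy))
  st <- recover_stress(sol, mats)
  phi <- atan2(st$y - mesh$center[2], st$x - mesh$center[1])
  c2 <- cos(phi)^2; s2 <- sin(phi)^2; cs <- cos(phi) * sin(phi)
  exp_rr <- c2 * sig[1] + s2 * sig[2] + 2 * cs * sig[3]
  exp_tt <- s2 * sig[1] + c2 * sig[2] - 2 * cs * sig[3]
  exp_rt <- -cs * sig[1] + cs * sig[2] + (c2 - s2) * sig[3]
  scale <- max(abs(sig))
  expect_lt(max(abs(st$sigma_rr - exp_rr)) / scale, 1e-9)
  expect_lt(max(abs(st$sigma_tt - exp_tt)) / scale, 1e-9)
  expect_lt(max(abs(st$sigma_rt - exp_rt)) / scale, 1e-9)
})

test_that("consistent pressure loads integrate the boundary correctly", {
  # closed circular boundary: zero resultant
  grid <- capstress:::q8_grid_polar(c(1, 1.5), seq(0, 360, length.out = 25))
  full <- q8_mesh(grid$nodes, grid$elements, rep("annulus", 24L),
                  capstress:::polar_edge_groups(grid))
  f <- pressure_load(full, 10)
  net <- c(sum(f[seq(1, length(f), 2)]), sum(f[seq(2, length(f), 2)]))
  expect_lt(max(abs(net)), 1e-9 * sum(abs(f)))
  # half circle of radius a: resultant 2 a P along the symmetry axis normal
  mesh <- build_annulus_mesh(1, 2, n_r = 2, n_theta = 16)
  fh <- pressure_load(mesh, 14.6)
  expect_equal(sum(fh[seq(2, length(fh), 2)]), 2 * 1 * 14.6,
               tolerance = 1e-9)
  expect_lt(abs(sum(fh[seq(1, length(fh), 2)])), 1e-9 * 2 * 14.6)
  expect_identical(pressure_load(mesh, 0), numeric(2L * nrow(mesh$nodes)))
})

test_that("eigenstrain loads are linear and reproduce free expansion", {
  mesh <- build_half_model(morphology_params(),
                           list(crystal_spec("shoulder")))
  band <- mesh$meta$crystal_bands$shoulder
  cr <- default_materials()$crystal
  expect_identical(eigenstrain_load(mesh, band, 0, cr),
                   numeric(2L * nrow(mesh$nodes)))
  f1 <- eigenstrain_load(mesh, band, 0.5, cr)
  f2 <- eigenstrain_load(mesh, band, 1.0, cr)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)

  # single unconstrained element under dilatational eigenstrain: stress-free
  # state with strain equal to the eigenstrain
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                 c(0.5, 0), c(1, 0.5), c(0.5, 1), c(0, 0.5))
  el <- matrix(1:8, 1, 8)
  edges <- tibble::tibble(group = character(), element = integer(),
                          n1 = integer(), nm = integer(), n2 = integer())
  m1 <- q8_mesh(nodes, el, "patch", edges)
  mats <- list(patch = mat_iso(100, 0.3))
  e0 <- 0.02
  fe <- eigenstrain_load(m1, 1L, c(e0, e0, 0), mats$patch)
  constraints <- tibble::tibble(node = c(1L, 1L, 2L), dof = c(1L, 2L, 2L),
                               value = 0)
  sol <- fem_solve(fem_assemble(m1, mats), fe, constraints)
  expect_equal(sol$u, e0 * nodes, tolerance = 1e-8)
  st <- recover_stress(sol, mats,
                       eigenstrains = list(list(elements = 1L,
                                                eps_r = c(e0, e0, 0))))
  expect_lt(max(abs(c(st$sigma_rr, st$sigma_tt, st$sigma_rt))), 1e-8 * 100)
})

test_that("the pressurized annulus matches the thick-walled-cylinder form", {
  lame <- cached_lame()
  lc <- lame_case()
  st <- lame[[1]]$stress
  inner <- st[abs(st$r - lc$a) < 1e-9, ]
  expect_equal(mean(inner$sigma_tt), lame_hoop_exact(lc$a),
               tolerance = 0.01)
  # hoop profile within 1% across radii
  prof <- dplyr::summarise(dplyr::group_by(st, r = round(.data$r, 9)),
                           stt = mean(.data$sigma_tt), .groups = "drop")
  expect_lt(max(abs(prof$stt - lame_hoop_exact(prof$r)) /
                  lame_hoop_exact(prof$r)), 0.01)
  # radial stress hits -P at the loaded face
  expect_equal(mean(inner$sigma_rr), -lc$P, tolerance = 0.01 * lc$P)
})

test_that("Lame benchmark error decreases monotonically under refinement", {
  lame <- cached_lame()
  lc <- lame_case()
  errs <- vapply(lame, function(l) {
    inner <- l$stress[abs(l$stress$r - lc$a) < 1e-9, ]
    abs(mean(inner$sigma_tt) - lame_hoop_exact(lc$a)) / lame_hoop_exact(lc$a)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1], 0.01)
})

test_that("solutions are linear in the load and at equilibrium", {
  lame <- cached_lame()
  lc <- lame_case()
  mesh <- lame[[1]]$mesh
  asm <- fem_assemble(mesh, lc$mats)
  sol0 <- fem_solve(asm, numeric(2L * nrow(mesh$nodes)))
  expect_equal(max(abs(sol0$u)), 0)
  sol1 <- lame[[1]]$sol
  sol2 <- fem_solve(asm, pressure_load(mesh, 2 * lc$P))
  expect_equal(sol2$u, 2 * sol1$u, tolerance = 1e-12)
  expect_lt(sol1$residual, 1e-10)
  expect_lt(max(equilibrium_imbalance(sol1)), 1e-8)
  # the rigid-mode anchor carries no load
  anchor <- sol1$constraints[sol1$constraints$dof == 1L, ]
  expect_lt(abs(anchor$reaction), 1e-8 * sqrt(sum(sol1$f^2)))
})

test_that("stress recovery annihilates rigid motions, keeps hydrostatics", {
  mesh <- build_annulus_mesh(1, 2, n_r = 2, n_theta = 8)
  mats <- list(annulus = mat_iso(100, 0.3))
  rigid <- cbind(0.3 - 0.01 * mesh$nodes[, 2],
                 -0.7 + 0.01 * mesh$nodes[, 1])
  sol_r <- structure(list(u = rigid, mesh = mesh), class = "fem_solution")
  st <- recover_stress(sol_r, mats)
  expect_lt(max(abs(c(st$sigma_rr, st$sigma_tt, st$sigma_rt, st$sigma_zz))),
            1e-9)
  hydro <- 0.005 * mesh$nodes
  sol_h <- structure(list(u = hydro, mesh = mesh), class = "fem_solution")
  sth <- recover_stress(sol_h, mats)
  expect_equal(sth$sigma_rr, sth$sigma_tt, tolerance = 1e-8)
  expect_lt(max(abs(sth$sigma_rt)) / max(abs(sth$sigma_rr)), 1e-8)
})

test_that("unconstrained systems are reported as singular", {
  mesh <- build_annulus_mesh(1, 2, n_r = 2, n_theta = 8)
  mats <- list(annulus = mat_iso(100, 0.3))
  f <- pressure_load(mesh, 1)
  none <- tibble::tibble(node = integer(), dof = integer(), value = numeric())
  expect_error(fem_solve(fem_assemble(mesh, mats), f, constraints = none),
               "singular|indefinite")
})
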