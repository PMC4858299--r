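# Plane-strain FEM on Q8 serendipity quadrilaterals: shape functions, element
# stiffness with polar material axes, consistent loads, direct sparse solve,
# and stress recovery in cylindrical components.

# Shape functions and parametric derivatives at (xi, eta).
q8_shape <- function(xi, eta) {
  xs <- c(-1, 1, 1, -1, 0, 1, 0, -1)
  es <- c(-1, -1, 1, 1, -1, 0, 1, 0)
  N <- numeric(8)
  dN <- matrix(0, 8, 2)
  for (a in 1:4) {
    N[a] <- (1 + xi * xs[a]) * (1 + eta * es[a]) * (xi * xs[a] + eta * es[a] - 1) / 4
    dN[a, 1] <- xs[a] * (1 + eta * es[a]) * (2 * xi * xs[a] + eta * es[a]) / 4
    dN[a, 2] <- es[a] * (1 + xi * xs[a]) * (2 * eta * es[a] + xi * xs[a]) / 4
  }
  for (a in c(5L, 7L)) { # midsides with xs = 0
    N[a] <- (1 - xi^2) * (1 + eta * es[a]) / 2
    dN[a, 1] <- -xi * (1 + eta * es[a])
    dN[a, 2] <- (1 - xi^2) * es[a] / 2
  }
  for (a in c(6L, 8L)) { # midsides with es = 0
    N[a] <- (1 + xi * xs[a]) * (1 - eta^2) / 2
    dN[a, 1] <- (1 - eta^2) * xs[a] / 2
    dN[a, 2] <- -eta * (1 + xi * xs[a])
  }
  list(N = N, dN = dN)
}

gauss_1d <- function(n) {
  if (n == 2L) {
    list(x = c(-1, 1) / sqrt(3), w = c(1, 1))
  } else if (n == 3L) {
    list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
  } else {
    abort("only 2- and 3-point Gauss rules are provided.")
  }
}

gauss_2d <- function(n) {
  g <- gauss_1d(n)
  pts <- as.matrix(expand.grid(xi = g$x, eta = g$x))
  w <- as.vector(outer(g$w, g$w))
  list(pts = pts, w = w)
}

# Cached shape data at the quadrature points of an n-point rule.
shape_cache <- function(n) {
  gp <- gauss_2d(n)
  sh <- lapply(seq_len(nrow(gp$pts)),
               function(q) q8_shape(gp$pts[q, 1], gp$pts[q, 2]))
  list(gp = gp, sh = sh)
}

the_cache <- new.env(parent = emptyenv())
get_shape_cache <- function(n) {
  key <- paste0("g", n)
  if (is.null(the_cache[[key]])) the_cache[[key]] <- shape_cache(n)
  the_cache[[key]]
}

# B matrix (3 x 16) and Jacobian determinant at one quadrature point.
bmat_at <- function(sh, xy) {
  J <- crossprod(sh$dN, xy) # 2x2: rows d/dxi, d/deta; cols x, y
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (detJ <= 0) abort("singular or inverted element Jacobian.")
  dNxy <- sh$dN %*% t(solve(J)) # 8x2 cartesian derivatives
  B <- matrix(0, 3, 16)
  ix <- seq(1, 15, by = 2)
  iy <- seq(2, 16, by = 2)
  B[1, ix] <- dNxy[, 1]
  B[2, iy] <- dNxy[, 2]
  B[3, ix] <- dNxy[, 2]
  B[3, iy] <- dNxy[, 1]
  list(B = B, detJ = detJ, N = sh$N)
}

#' Element stiffness matrix of a Q8 plane-strain element
#'
#' 3x3 Gauss quadrature of B' D B. When `center` is given, the material matrix
#' `D_local` is interpreted in the cylindrical (r, theta) frame about that
#' point and rotated to Cartesian axes at every quadrature point; with
#' `center = NULL` the matrix is used as a constant Cartesian matrix.
#'
#' @param coords 8 x 2 node coordinates (corners then midsides).
#' @param D_local 3 x 3 plane-strain constitutive matrix, kPa.
#' @param center Lumen center for the polar frame, or `NULL`.
#' @return 16 x 16 symmetric stiffness block (dof order u1x, u1y, ..., u8y).
#' @export
element_stiffness <- function(coords, D_local, center = c(0, 0)) {
  sc <- get_shape_cache(3L)
  K <- matrix(0, 16, 16)
  for (q in seq_along(sc$sh)) {
    bd <- bmat_at(sc$sh[[q]], coords)
    D <- if (is.null(center)) D_local else {
      p <- crossprod(sc$sh[[q]]$N, coords)
      rotate_D(D_local, atan2(p[2] - center[2], p[1] - center[1]))
    }
    K <- K + crossprod(bd$B, D %*% bd$B) * (bd$detJ * sc$gp$w[q])
  }
  (K + t(K)) / 2
}

#' Assemble the global stiffness matrix
#'
#' @param mesh A `q8_mesh`.
#' @param materials Named list of `capstress_material`, one entry per region
#'   tag present in the mesh.
#' @return A list of class `fem_assembly`: `K` (sparse symmetric), `K_region`
#'   (per-region sparse parts summing to `K`), `ndof`, and the mesh.
#' @export
fem_assemble <- function(mesh, materials) {
  stopifnot(inherits(mesh, "q8_mesh"))
  missing <- setdiff(unique(mesh$region), names(materials))
  if (length(missing)) {
    abort(paste0("no material given for region(s): ",
                 paste(missing, collapse = ", ")))
  }
  ndof <- 2L * nrow(mesh$nodes)
  K_region <- list()
  for (reg in unique(mesh$region)) {
    Dl <- plane_strain_D(materials[[reg]])$D
    els <- which(mesh$region == reg)
    nE <- length(els)
    ii <- integer(256L * nE)
    jj <- integer(256L * nE)
    xx <- numeric(256L * nE)
    pos <- 0L
    for (e in els) {
      en <- mesh$elements[e, ]
      dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
      Ke <- element_stiffness(mesh$nodes[en, , drop = FALSE], Dl,
                              center = mesh$center)
      idx <- pos + seq_len(256L)
      ii[idx] <- rep(dofs, times = 16L)
      jj[idx] <- rep(dofs, each = 16L)
      xx[idx] <- as.vector(Ke)
      pos <- pos + 256L
    }
    K_region[[reg]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                            dims = c(ndof, ndof))
  }
  K <- Reduce(`+`, K_region)
  structure(list(K = K, K_region = K_region, ndof = ndof, mesh = mesh),
            class = "fem_assembly")
}

#' Consistent nodal loads for constant normal pressure on the lumen surface
#'
#' Work-equivalent loads on quadratic boundary edges, applied on the
#' undeformed configuration (linear analysis). The traction points away from
#' the lumen center (internal pressure pushing the wall outward).
#'
#' @param mesh A `q8_mesh`.
#' @param P Pressure, kPa.
#' @param group Edge group to load (default `"lumen_surface"`).
#' @return Global force vector (length 2 x n_nodes), mN/mm.
#' @export
pressure_load <- function(mesh, P, group = "lumen_surface") {
  f <- numeric(2L * nrow(mesh$nodes))
  if (P == 0) return(f)
  edges <- mesh$edges[mesh$edges$group == group, , drop = FALSE]
  if (nrow(edges) == 0L) abort(paste0("no edges in group ", group))
  g <- gauss_1d(3L)
  for (k in seq_len(nrow(edges))) {
    nd <- c(edges$n1[k], edges$nm[k], edges$n2[k])
    xy <- mesh$nodes[nd, , drop = FALSE]
    for (q in seq_along(g$x)) {
      xi <- g$x[q]
      N <- c(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2)
      dN <- c(xi - 0.5, -2 * xi, xi + 0.5)
      tangent <- crossprod(dN, xy) # 1x2
      len <- sqrt(sum(tangent^2))
      if (len < 1e-14) abort("degenerate pressure edge.")
      normal <- c(tangent[2], -tangent[1]) / len
      mid <- crossprod(N, xy)
      if (sum(normal * (mid - mesh$center)) < 0) normal <- -normal
      tr <- P * normal
      dofs <- as.vector(rbind(2L * nd - 1L, 2L * nd))
      f[dofs] <- f[dofs] + as.vector(t(outer(N, tr))) * len * g$w[q]
    }
  }
  f
}

#' Equivalent nodal forces of a stress-free eigenstrain
#'
#' Integrates B' D epsilon* over the listed elements. The eigenstrain is a
#' normal strain of magnitude `eps_r` along the local radial (crystal
#' thickness) direction, rotated to Cartesian axes at each quadrature point.
#'
#' @param mesh A `q8_mesh`.
#' @param elements Element ids carrying the eigenstrain.
#' @param eps_r Radial eigenstrain (dimensionless), or a length-3 local strain
#'   vector (eps_r, eps_theta, gamma_rtheta) in engineering notation.
#' @param material The material of those elements (sets D in B' D epsilon*).
#' @return Global force vector.
#' @export
eigenstrain_load <- function(mesh, elements, eps_r, material) {
  f <- numeric(2L * nrow(mesh$nodes))
  eps_loc <- if (length(eps_r) == 1L) c(eps_r, 0, 0) else as.numeric(eps_r)
  stopifnot(length(eps_loc) == 3L, all(is.finite(eps_loc)))
  if (all(eps_loc == 0) || length(elements) == 0L) return(f)
  Dl <- plane_strain_D(material)$D
  sc <- get_shape_cache(3L)
  for (e in elements) {
    en <- mesh$elements[e, ]
    xy <- mesh$nodes[en, , drop = FALSE]
    dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
    fe <- numeric(16)
    for (q in seq_along(sc$sh)) {
      bd <- bmat_at(sc$sh[[q]], xy)
      p <- crossprod(sc$sh[[q]]$N, xy)
      phi <- atan2(p[2] - mesh$center[2], p[1] - mesh$center[1])
      # sigma* in global axes: rotate_D(D)*T^-1... equivalently t(T) D eps_loc
      sig <- crossprod(strain_rotation(phi), Dl %*% eps_loc)
      fe <- fe + crossprod(bd$B, sig) * (bd$detJ * sc$gp$w[q])
    }
    f[dofs] <- f[dofs] + fe
  }
  f
}

#' Symmetry-line constraints of the half model
#'
#' Zero displacement normal to the symmetry axis (u_y = 0) on every
#' symmetry-line node, plus a single u_x anchor that removes the remaining
#' rigid translation along the axis; all admissible loads on the half model
#' have zero axial resultant, so the anchor reaction is zero.
#'
#' @param mesh A `q8_mesh` with a `symmetry_line` edge group.
#' @return Tibble with columns `node`, `dof` (1 = x, 2 = y), `value`.
#' @export
symmetry_constraints <- function(mesh) {
  ed <- mesh$edges[mesh$edges$group == "symmetry_line", , drop = FALSE]
  nodes <- sort(unique(c(ed$n1, ed$nm, ed$n2)))
  if (length(nodes) == 0L) abort("mesh has no symmetry_line edge group.")
  out <- tibble::tibble(node = nodes, dof = 2L, value = 0)
  r <- sqrt(rowSums((mesh$nodes - matrix(mesh$center, nrow(mesh$nodes), 2,
                                         byrow = TRUE))^2))
  anchor <- which.min(abs(r - max(r)) + abs(mesh$nodes[, 1])) # top outer node
  dplyr::bind_rows(out, tibble::tibble(node = anchor, dof = 1L, value = 0))
}

#' Solve the constrained linear system
#'
#' Direct sparse Cholesky solve of the symmetric positive-definite reduced
#' system; supports non-homogeneous prescribed displacements.
#'
#' @param assembly A `fem_assembly` (or a `q8_mesh` plus `materials`).
#' @param f Global load vector.
#' @param constraints Tibble (`node`, `dof`, `value`); defaults to the
#'   half-model symmetry constraints.
#' @param materials Materials list, used only when `assembly` is a mesh.
#' @return Object of class `fem_solution`: `u` (n x 2 displacements, mm),
#'   `reactions` (tibble at constrained dofs), `residual` (relative), and the
#'   inputs.
#' @export
fem_solve <- function(assembly, f, constraints = NULL, materials = NULL) {
  if (inherits(assembly, "q8_mesh")) {
    assembly <- fem_assemble(assembly, materials)
  }
  stopifnot(inherits(assembly, "fem_assembly"))
  mesh <- assembly$mesh
  K <- assembly$K
  ndof <- assembly$ndof
  if (is.null(constraints)) constraints <- symmetry_constraints(mesh)
  cdof <- 2L * (constraints$node - 1L) + constraints$dof
  if (anyDuplicated(cdof)) {
    dup <- duplicated(cdof)
    constraints <- constraints[!dup, , drop = FALSE]
    cdof <- cdof[!dup]
  }
  cval <- constraints$value
  free <- setdiff(seq_len(ndof), cdof)
  u <- numeric(ndof)
  u[cdof] <- cval
  rhs <- f[free] - as.vector(K[free, cdof, drop = FALSE] %*% cval)
  Kff <- K[free, free]
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                  rhs, system = "A"),
    error = function(e) {
      abort(c("stiffness matrix is singular or indefinite after constraints",
              "check that all rigid-body modes are constrained",
              conditionMessage(e)))
    }
  )
  u[free] <- as.vector(sol)
  res <- as.vector(Kff %*% u[free]) - rhs
  fn <- sqrt(sum(f^2))
  residual <- sqrt(sum(res^2)) / max(fn, 1e-30)
  if (!all(is.finite(u)) || (fn > 0 && residual > 1e-6)) {
    abort(c(
      "stiffness matrix is singular or indefinite after constraints",
      sprintf("relative residual %.3g; an unconstrained rigid-body mode is the usual cause", residual)
    ))
  }
  reactions <- as.vector(K[cdof, , drop = FALSE] %*% u) - f[cdof]
  structure(
    list(
      u = matrix(u, ncol = 2, byrow = TRUE),
      mesh = mesh,
      constraints = dplyr::mutate(constraints, reaction = reactions),
      residual = residual,
      f = f
    ),
    class = "fem_solution"
  )
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("<fem_solution> %d nodes, max |u| = %.4g mm, residual = %.2g\n",
              nrow(x$u), max(abs(x$u)), x$residual))
  invisible(x)
}

#' Recover cylindrical stresses at the mesh nodes
#'
#' Stresses are sampled at the 3x3 Gauss points of each element, extrapolated
#' to the element nodes by the standard quadratic Gauss-point extrapolation,
#' and averaged over
#' the elements sharing a node within each region separately, so material
#' interfaces are not smeared. Components are cylindrical about the lumen
#' center; sigma_zz comes from the plane-strain condensation row. Crystal
#' eigenstrains, when present in `eigenstrains`, are subtracted before the
#' constitutive evaluation.
#'
#' @param sol A `fem_solution`.
#' @param materials Named list of materials per region.
#' @param eigenstrains Optional list of `list(elements =, eps_r =)` entries
#'   describing stress-free strains applied in the solve.
#' @return A tibble of class `stress_field`: node, x, y, r (mm), theta (deg),
#'   region, sigma_rr, sigma_tt, sigma_rt, sigma_zz (kPa).
#' @export
recover_stress <- function(sol, materials, eigenstrains = list()) {
  stopifnot(inherits(sol, "fem_solution"))
  mesh <- sol$mesh
  Dloc <- lapply(materials, plane_strain_D)
  eps_by_el <- matrix(0, nrow(mesh$elements), 3L)
  for (eg in eigenstrains) {
    ev <- if (length(eg$eps_r) == 1L) c(eg$eps_r, 0, 0) else
      as.numeric(eg$eps_r)
    eps_by_el[eg$elements, ] <- eps_by_el[eg$elements, , drop = FALSE] +
      matrix(ev, length(eg$elements), 3L, byrow = TRUE)
  }
  sc <- get_shape_cache(3L)
  # biquadratic extrapolation from the 3x3 Gauss points to the 8 nodes: in the
  # coordinate u = xi / sqrt(3/5) the Gauss points sit at -1, 0, 1
  lag <- function(t) c(t * (t - 1) / 2, 1 - t^2, t * (t + 1) / 2)
  scale <- sqrt(5 / 3)
  xs <- c(-1, 1, 1, -1, 0, 1, 0, -1)
  es <- c(-1, -1, 1, 1, -1, 0, 1, 0)
  Ext <- matrix(0, 8, 9)
  for (a in 1:8) {
    lx <- lag(xs[a] * scale)
    le <- lag(es[a] * scale)
    # gauss_2d(3): xi varies fastest, order (-g,0,g) x (-g,0,g)
    Ext[a, ] <- as.vector(outer(lx, le))
  }
  n_nodes <- nrow(mesh$nodes)
  # accumulate per (node, region)
  sums <- list()
  for (reg in unique(mesh$region)) {
    sums[[reg]] <- list(s = matrix(0, n_nodes, 4L), n = integer(n_nodes))
  }
  uvec <- as.vector(t(sol$u))
  for (e in seq_len(nrow(mesh$elements))) {
    en <- mesh$elements[e, ]
    xy <- mesh$nodes[en, , drop = FALSE]
    reg <- mesh$region[e]
    dl <- Dloc[[reg]]
    dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
    ue <- uvec[dofs]
    sg <- matrix(0, 9L, 4L) # gauss pts x (srr, stt, srt, szz)
    for (q in 1:9) {
      bd <- bmat_at(sc$sh[[q]], xy)
      p <- crossprod(sc$sh[[q]]$N, xy)
      phi <- atan2(p[2] - mesh$center[2], p[1] - mesh$center[1])
      eps_glob <- as.vector(bd$B %*% ue)
      eps_loc <- as.vector(strain_rotation(phi) %*% eps_glob)
      eps_loc <- eps_loc - eps_by_el[e, ]
      sig_loc <- as.vector(dl$D %*% eps_loc)
      # carry Cartesian components to the nodes; rotate there (a constant
      # Cartesian stress state then extrapolates exactly)
      sig_cart <- as.vector(crossprod(strain_rotation(phi), sig_loc))
      sg[q, ] <- c(sig_cart, sum(dl$zz * eps_loc))
    }
    vals <- Ext %*% sg # 8 x 4 nodal extrapolation, Cartesian + zz
    sums[[reg]]$s[en, ] <- sums[[reg]]$s[en, ] + vals
    sums[[reg]]$n[en] <- sums[[reg]]$n[en] + 1L
  }
  out <- list()
  dx <- mesh$nodes[, 1] - mesh$center[1]
  dy <- mesh$nodes[, 2] - mesh$center[2]
  r_all <- sqrt(dx^2 + dy^2)
  th_all <- atan2(dy, dx) * 180 / pi
  phi_all <- atan2(dy, dx)
  for (reg in names(sums)) {
    nn <- sums[[reg]]$n
    sel <- which(nn > 0L)
    sm <- sums[[reg]]$s[sel, , drop = FALSE] / nn[sel]
    cc <- cos(phi_all[sel])
    ss <- sin(phi_all[sel])
    out[[reg]] <- tibble::tibble(
      node = sel, x = mesh$nodes[sel, 1], y = mesh$nodes[sel, 2],
      r = r_all[sel], theta = th_all[sel], region = reg,
      sigma_rr = cc^2 * sm[, 1] + ss^2 * sm[, 2] + 2 * cc * ss * sm[, 3],
      sigma_tt = ss^2 * sm[, 1] + cc^2 * sm[, 2] - 2 * cc * ss * sm[, 3],
      sigma_rt = -cc * ss * sm[, 1] + cc * ss * sm[, 2] +
        (cc^2 - ss^2) * sm[, 3],
      sigma_zz = sm[, 4]
    )
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$node, .data$region)
  class(res) <- c("stress_field", class(res))
  res
}

#' Displacements as a tibble
#' @param sol A `fem_solution`.
#' @return Tibble: node, x, y, ux, uy (mm).
#' @export
displacement_field <- function(sol) {
  stopifnot(inherits(sol, "fem_solution"))
  tibble::tibble(
    node = seq_len(nrow(sol$u)),
    x = sol$mesh$nodes[, 1], y = sol$mesh$nodes[, 2],
    ux = sol$u[, 1], uy = sol$u[, 2]
  )
}

#' Check global equilibrium of a solved model
#'
#' @param sol A `fem_solution`.
#' @return Relative imbalance: |sum(applied) + sum(reactions)| / |applied|,
#'   per component, as a named numeric vector.
#' @export
equilibrium_imbalance <- function(sol) {
  fx <- sum(sol$f[seq(1, length(sol$f), by = 2)])
  fy <- sum(sol$f[seq(2, length(sol$f), by = 2)])
  rx <- sum(sol$constraints$reaction[sol$constraints$dof == 1L])
  ry <- sum(sol$constraints$reaction[sol$constraints$dof == 2L])
  # reactions R satisfy K u = f + R at constrained dofs, so global balance is
  # sum(f) + sum(R) = 0 component-wise
  scale <- max(sqrt(sum(sol$f^2)), 1e-30)
  c(x = abs(fx + rx), y = abs(fy + ry)) / scale
}
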