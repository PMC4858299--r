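#' Tissue material models
#'
#' `mat_transiso()` defines a transversely isotropic (polar-orthotropic) linear
#' elastic solid whose plane of isotropy is the circumferential-axial plane
#' (E_theta = E_z), the constitutive model used for artery and fibrous plaque.
#' `mat_iso()` defines an isotropic solid (necrotic core, cholesterol crystal).
#'
#' The unlisted constants of the orthotropic compliance are fixed by symmetry:
#' nu_theta_r = nu_r_theta * E_theta / E_r, nu_rz = nu_r_theta, and
#' nu_z_theta = nu_theta_z.
#'
#' @param E_r,E_theta,E_z Young's moduli in the radial, circumferential and
#'   axial directions, kPa. `E_z` defaults to `E_theta`.
#' @param nu_rtheta,nu_thetaz Poisson ratios in the r-theta and theta-z planes.
#' @param G_rtheta Shear modulus in the r-theta plane, kPa.
#' @return An object of class `capstress_material`.
#' @examples
#' mat_transiso(50, 1000, nu_rtheta = 0.01, nu_thetaz = 0.27, G_rtheta = 500)
#' mat_iso(1, 0.49) # the necrotic core
#' @export
mat_transiso <- function(E_r, E_theta, E_z = E_theta, nu_rtheta, nu_thetaz,
                         G_rtheta) {
  stopifnot(E_r > 0, E_theta > 0, E_z > 0, G_rtheta > 0)
  structure(
    list(kind = "transversely_isotropic", E_r = E_r, E_theta = E_theta,
         E_z = E_z, nu_rtheta = nu_rtheta, nu_thetaz = nu_thetaz,
         G_rtheta = G_rtheta),
    class = "capstress_material"
  )
}

#' @rdname mat_transiso
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @export
mat_iso <- function(E, nu) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  structure(list(kind = "isotropic", E = E, nu = nu),
            class = "capstress_material")
}

#' @export
print.capstress_material <- function(x, ...) {
  if (x$kind == "isotropic") {
    cat(sprintf("<material> isotropic: E = %g kPa, nu = %g\n", x$E, x$nu))
  } else {
    cat(sprintf(
      "<material> transversely isotropic: E_r = %g, E_theta = %g, E_z = %g kPa, nu_rtheta = %g, nu_thetaz = %g, G_rtheta = %g kPa\n",
      x$E_r, x$E_theta, x$E_z, x$nu_rtheta, x$nu_thetaz, x$G_rtheta
    ))
  }
  invisible(x)
}

#' Reference material set for the plaque model
#'
#' Artery and fibrous plaque are transversely isotropic (plaque: E_r 50,
#' E_theta = E_z 1000, nu_rtheta 0.01, nu_thetaz 0.27, G_rtheta 500 kPa;
#' artery: one order of magnitude softer with the same ratios); the necrotic
#' core is soft and nearly incompressible (E 1 kPa, nu 0.49) and the
#' cholesterol crystal is modelled as 100 kPa, nu 0.49.
#'
#' @param crystal_factor Multiplier on the crystal Young's modulus (used by
#'   the stiffness sensitivity sweep).
#' @return Named list of `capstress_material` for regions `artery`, `plaque`,
#'   `core`, `crystal`.
#' @export
default_materials <- function(crystal_factor = 1) {
  stopifnot(crystal_factor > 0)
  list(
    plaque = mat_transiso(50, 1000, nu_rtheta = 0.01, nu_thetaz = 0.27,
                          G_rtheta = 500),
    artery = mat_transiso(10, 100, nu_rtheta = 0.01, nu_thetaz = 0.27,
                          G_rtheta = 50),
    core = mat_iso(1, 0.49),
    crystal = mat_iso(100 * crystal_factor, 0.49)
  )
}

#' Plane-strain constitutive matrix in the local (r, theta) frame
#'
#' Builds the 3x3 orthotropic normal compliance with axes (r, theta, z),
#' enforces the symmetry relations, inverts it, and statically condenses with
#' epsilon_z = 0 to the in-plane matrix relating engineering strains
#' (eps_rr, eps_tt, gamma_rt) to stresses (sigma_rr, sigma_tt, sigma_rt).
#' Also returns the row recovering sigma_zz from the in-plane strains.
#'
#' @param material A `capstress_material`.
#' @return List with `D` (3x3, kPa), `zz` (length-3 row for sigma_zz), and the
#'   normal stiffness `C` (3x3).
#' @export
plane_strain_D <- function(material) {
  stopifnot(inherits(material, "capstress_material"))
  if (material$kind == "isotropic") {
    E_r <- E_t <- E_z <- material$E
    nu_rt <- nu_tz <- nu_rz <- material$nu
    G <- material$E / (2 * (1 + material$nu))
  } else {
    E_r <- material$E_r
    E_t <- material$E_theta
    E_z <- material$E_z
    nu_rt <- material$nu_rtheta
    nu_tz <- material$nu_thetaz
    nu_rz <- material$nu_rtheta
    G <- material$G_rtheta
  }
  # compliance S[i,j]: eps_i = S[i,j] sigma_j, order (r, theta, z); symmetry
  # S[j,i] = -nu_ij / E_i
  S <- matrix(c(
    1 / E_r, -nu_rt / E_r, -nu_rz / E_r,
    -nu_rt / E_r, 1 / E_t, -nu_tz / E_t,
    -nu_rz / E_r, -nu_tz / E_t, 1 / E_z
  ), 3, 3, byrow = TRUE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort("material compliance is not positive definite.")
  }
  C <- solve(S)
  D <- matrix(0, 3, 3)
  D[1:2, 1:2] <- C[1:2, 1:2]
  D[3, 3] <- G
  list(D = D, zz = c(C[3, 1], C[3, 2], 0), C = C)
}

# Rotate a local (r, theta) plane constitutive matrix to the Cartesian frame.
# T_eps maps global engineering strain to local; D_glob = t(T) D_loc T.
strain_rotation <- function(phi) {
  c <- cos(phi)
  s <- sin(phi)
  matrix(c(
    c^2, s^2, c * s,
    s^2, c^2, -c * s,
    -2 * c * s, 2 * c * s, c^2 - s^2
  ), 3, 3, byrow = TRUE)
}

rotate_D <- function(D, phi) {
  Tm <- strain_rotation(phi)
  crossprod(Tm, D %*% Tm)
}
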