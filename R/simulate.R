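# Synthetic micro-OCT B-scans with known crystal ground truth, so the
# morphometry stage is testable without any deposited images.

#' Specify a synthetic B-scan
#'
#' Each crystal is rendered as two bright horizontal ridges (top and bottom
#' surface reflections) separated by its optical thickness in pixels, the
#' image is convolved with the Gaussian point-spread function (axial 1.3 um,
#' lateral 2.5 um FWHM by default), and fully developed multiplicative speckle
#' (unit-mean exponential intensity noise) is blended in by `speckle_contrast`.
#'
#' @param crystals Tibble/data frame with columns `row_top` (px),
#'   `col_start`, `col_end` (px), `opt_thickness_px` (optical surface
#'   separation, px), `reflectivity` (ridge intensity above background).
#' @param n_rows,n_cols Image size in pixels (default 1024 x 512).
#' @param background Background intensity level.
#' @param speckle_contrast Speckle blend in `[0, 1]`; 0 is noise-free.
#' @param psf_axial_um,psf_lateral_um PSF FWHM, um.
#' @param lateral_pitch,axial_pitch,refractive_index Calibration as in
#'   [bscan()].
#' @param seed Integer seed; a fixed seed gives identical images.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(crystals, n_rows = 1024L, n_cols = 512L, background = 1,
                     speckle_contrast = 0.5, psf_axial_um = 1.3,
                     psf_lateral_um = 2.5, lateral_pitch = 872 / 512,
                     axial_pitch = 1400 / 1024, refractive_index = 1.33,
                     seed = 1L) {
  crystals <- tibble::as_tibble(crystals)
  need <- c("row_top", "col_start", "col_end", "opt_thickness_px",
            "reflectivity")
  if (!all(need %in% names(crystals))) {
    abort(paste0("crystals needs columns: ", paste(need, collapse = ", ")))
  }
  if (speckle_contrast < 0 || speckle_contrast > 1) {
    abort("speckle_contrast must lie in [0, 1].")
  }
  bad <- crystals$row_top < 1 |
    crystals$row_top + crystals$opt_thickness_px > n_rows |
    crystals$col_start < 1 | crystals$col_end > n_cols |
    crystals$col_start > crystals$col_end | crystals$opt_thickness_px < 1
  if (any(bad)) abort("crystal(s) out of image bounds.")
  structure(
    list(crystals = crystals, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), background = background,
         speckle_contrast = speckle_contrast, psf_axial_um = psf_axial_um,
         psf_lateral_um = psf_lateral_um, lateral_pitch = lateral_pitch,
         axial_pitch = axial_pitch, refractive_index = refractive_index,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Render a synthetic B-scan with ground truth
#'
#' @param spec A [sim_spec()].
#' @return List of class `sim_bscan`: `scan` (a [bscan()]) and `truth`, a
#'   tibble with the exact physical geometry of each crystal (`length_um`,
#'   `thickness_um` = optical separation * axial pitch / n, plus the pixel
#'   footprint).
#' @examples
#' sim <- simulate_bscan(sim_spec(
#'   tibble::tibble(row_top = 200, col_start = 100, col_end = 258,
#'                  opt_thickness_px = 3, reflectivity = 10),
#'   speckle_contrast = 0
#' ))
#' sim$truth
#' @export
simulate_bscan <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  render <- function() {
    img <- matrix(spec$background, spec$n_rows, spec$n_cols)
    for (i in seq_len(nrow(spec$crystals))) {
      cr <- spec$crystals[i, ]
      cols <- cr$col_start:cr$col_end
      img[cr$row_top, cols] <- img[cr$row_top, cols] + cr$reflectivity
      bot <- cr$row_top + cr$opt_thickness_px
      img[bot, cols] <- img[bot, cols] + cr$reflectivity
    }
    img <- blur_axial(img, (spec$psf_axial_um / 2.355) / spec$axial_pitch)
    img <- blur_lateral(img, (spec$psf_lateral_um / 2.355) / spec$lateral_pitch)
    cc <- spec$speckle_contrast
    if (cc > 0) {
      img <- img * (1 - cc + cc * matrix(rexp(length(img)), nrow(img)))
    }
    img
  }
  img <- withr::with_seed(spec$seed, render())
  truth <- tibble::tibble(
    crystal = seq_len(nrow(spec$crystals)),
    row_top = spec$crystals$row_top,
    col_start = spec$crystals$col_start,
    col_end = spec$crystals$col_end,
    opt_thickness_px = spec$crystals$opt_thickness_px,
    length_um = (spec$crystals$col_end - spec$crystals$col_start + 1) *
      spec$lateral_pitch,
    thickness_um = spec$crystals$opt_thickness_px * spec$axial_pitch /
      spec$refractive_index
  )
  structure(
    list(
      scan = bscan(img, spec$lateral_pitch, spec$axial_pitch,
                   spec$refractive_index),
      truth = truth, spec = spec
    ),
    class = "sim_bscan"
  )
}

#' Sample a cohort of crystal geometries
#'
#' Draws physical lengths from N(269.1, 80.16) um and thicknesses from
#' N(3.0, 0.33) um (the reported cohort statistics), converts them to pixel
#' footprints at the B-scan calibration (rounding to whole pixels, which
#' becomes the exact ground truth), and places each crystal at a random
#' position away from the image borders.
#'
#' @param n Number of crystals.
#' @param seed Integer seed.
#' @param mean_length_um,sd_length_um,mean_thickness_um,sd_thickness_um
#'   Cohort distribution parameters, um.
#' @param reflectivity Ridge intensity above background.
#' @param n_rows,n_cols,lateral_pitch,axial_pitch,refractive_index Frame
#'   geometry and calibration as in [sim_spec()].
#' @return Tibble with one crystal per row, ready to feed one at a time into
#'   [sim_spec()]/[simulate_bscan()].
#' @export
sim_crystal_cohort <- function(n = 20L, seed = 1L,
                               mean_length_um = 269.1, sd_length_um = 80.16,
                               mean_thickness_um = 3.0, sd_thickness_um = 0.33,
                               reflectivity = 10, n_rows = 1024L,
                               n_cols = 512L, lateral_pitch = 872 / 512,
                               axial_pitch = 1400 / 1024,
                               refractive_index = 1.33) {
  withr::with_seed(seed, {
    len_um <- pmax(rnorm(n, mean_length_um, sd_length_um), 20)
    th_um <- pmax(rnorm(n, mean_thickness_um, sd_thickness_um), 1)
    len_px <- pmax(round(len_um / lateral_pitch), 5L)
    len_px <- pmin(len_px, n_cols - 20L)
    opt_px <- pmax(round(th_um * refractive_index / axial_pitch), 2L)
    col_start <- vapply(len_px, function(L) {
      sample.int(n_cols - L - 10L, 1L) + 5L
    }, integer(1))
    row_top <- sample(seq(50L, n_rows - 60L), n, replace = TRUE)
    tibble::tibble(
      crystal = seq_len(n), row_top = row_top, col_start = col_start,
      col_end = col_start + len_px - 1L, opt_thickness_px = opt_px,
      reflectivity = reflectivity
    )
  })
}
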