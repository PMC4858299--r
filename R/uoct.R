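# Micro-OCT B-scan morphometry of thin plate-like cholesterol crystals: a
# crystal appears as a pair of bright specular ridges (top and bottom surface
# reflections); thickness is the optical ridge separation divided by the
# tissue refractive index, length the lateral extent of the ridge pair.

#' Construct a calibrated B-scan
#'
#' @param intensity Non-negative matrix, rows = depth (axial), cols = A-lines
#'   (lateral).
#' @param lateral_pitch Lateral pixel pitch, um/px. Default: 0.872 mm frame
#'   width over 512 A-lines.
#' @param axial_pitch Axial *optical* pixel pitch, um/px. Default: 1.4 mm
#'   frame depth over 1024 pixels.
#' @param refractive_index Tissue refractive index converting optical to
#'   physical axial distance (default 1.33).
#' @return Object of class `bscan`.
#' @export
bscan <- function(intensity, lateral_pitch = 872 / 512,
                  axial_pitch = 1400 / 1024, refractive_index = 1.33) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0) || any(!is.finite(intensity))) {
    abort("intensity must be finite and non-negative.")
  }
  stopifnot(lateral_pitch > 0, axial_pitch > 0, refractive_index >= 1)
  structure(
    list(intensity = intensity, lateral_pitch = lateral_pitch,
         axial_pitch = axial_pitch, refractive_index = refractive_index),
    class = "bscan"
  )
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf(
    "<bscan> %d x %d px (%.3f x %.3f mm optical), n = %g\n",
    nrow(x$intensity), ncol(x$intensity),
    nrow(x$intensity) * x$axial_pitch / 1000,
    ncol(x$intensity) * x$lateral_pitch / 1000, x$refractive_index
  ))
  invisible(x)
}

gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-h, h), sd = sigma_px)
  k / sum(k)
}

# Separable 1D convolution along matrix rows (axial direction), replicate
# padding, done as a sum of shifted matrices.
blur_axial <- function(mat, sigma_px) {
  k <- gauss_kernel(sigma_px)
  if (length(k) == 1L) return(mat)
  h <- (length(k) - 1L) / 2L
  nr <- nrow(mat)
  out <- matrix(0, nr, ncol(mat))
  for (s in seq_along(k)) {
    off <- s - h - 1L
    src <- pmin(pmax(seq_len(nr) + off, 1L), nr)
    out <- out + k[s] * mat[src, , drop = FALSE]
  }
  out
}

blur_lateral <- function(mat, sigma_px) {
  t(blur_axial(t(mat), sigma_px))
}

#' Trace the top and bottom surface reflections of a crystal
#'
#' The region of interest is smoothed axially at the point-spread-function
#' scale and laterally over a few A-lines (a matched filter: the crystal
#' ridges are laterally extended while speckle decorrelates beyond the PSF).
#' Per lateral column, the local maxima of the axial profile above an adaptive
#' threshold (ROI median + `k` * MAD) are found and the two strongest become
#' the top and bottom surface candidates, refined to subpixel by parabolic
#' interpolation. A second pass rejects columns whose ridge amplitude falls
#' below half the median candidate amplitude, which trims the blurred lateral
#' tails beyond the crystal ends. Columns with fewer than two qualifying peaks
#' (including columns where the two surfaces merge below the axial
#' resolution) are excluded.
#'
#' All criteria are relative, so the traces are invariant to global intensity
#' scaling of the B-scan.
#'
#' @param scan A [bscan()].
#' @param roi Pixel rectangle `c(row_min, row_max, col_min, col_max)`; default
#'   the whole image.
#' @param k MAD multiplier of the adaptive threshold (default 3).
#' @param smooth_um Axial smoothing scale, um (default 1.3, the axial
#'   resolution).
#' @param lateral_smooth_px Lateral matched-filter sigma, px (default 2).
#' @return Object of class `crystal_traces`: `top`, `bottom` (rows, indexed by
#'   column), `valid_cols`, `roi`.
#' @export
detect_crystal <- function(scan, roi = NULL, k = 3, smooth_um = 1.3,
                           lateral_smooth_px = 2) {
  stopifnot(inherits(scan, "bscan"))
  img <- scan$intensity
  if (is.null(roi)) roi <- c(1L, nrow(img), 1L, ncol(img))
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[2] > nrow(img) || roi[3] < 1L || roi[4] > ncol(img) ||
      roi[1] >= roi[2] || roi[3] > roi[4]) {
    abort("roi must be a valid pixel rectangle within the image.")
  }
  sub <- img[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  sigma_px <- (smooth_um / 2.355) / scan$axial_pitch
  sm <- blur_axial(sub, sigma_px)
  if (lateral_smooth_px > 0 && ncol(sm) > 1L) {
    sm <- blur_lateral(sm, lateral_smooth_px)
  }
  med <- median(sm)
  thr <- med + k * mad(sm)
  nr <- nrow(sm)
  peak <- sm > thr
  if (nr > 2L) {
    peak[2:(nr - 1), ] <- peak[2:(nr - 1), ] &
      sm[2:(nr - 1), ] > sm[1:(nr - 2), ] & sm[2:(nr - 1), ] >= sm[3:nr, ]
  }
  peak[c(1L, nr), ] <- FALSE
  refine <- function(j, i) {
    if (i <= 1L || i >= nr) return(as.numeric(i))
    y0 <- sm[i - 1L, j]; y1 <- sm[i, j]; y2 <- sm[i + 1L, j]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-30) return(as.numeric(i))
    i + 0.5 * (y0 - y2) / den
  }
  nc <- ncol(sm)
  top <- bottom <- amp <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    pk <- which(peak[, j])
    if (length(pk) < 2L) next
    ord <- sort(pk[order(sm[pk, j], decreasing = TRUE)][1:2])
    top[j] <- refine(j, ord[1])
    bottom[j] <- refine(j, ord[2])
    amp[j] <- min(sm[ord, j]) - med
  }
  cand <- which(!is.na(top) & bottom > top)
  if (length(cand) >= 5L) {
    ref_amp <- median(amp[cand])
    keep <- amp[cand] >= 0.5 * ref_amp
    valid <- cand[keep]
  } else {
    valid <- cand
  }
  if (length(valid) < 5L) {
    abort("no measurable crystal: fewer than 5 valid columns in the ROI.")
  }
  structure(
    list(top = top + roi[1] - 1L, bottom = bottom + roi[1] - 1L,
         valid_cols = valid + roi[3] - 1L, roi = roi, threshold = thr),
    class = "crystal_traces"
  )
}

#' Measure one crystal from its surface traces
#'
#' Length is the lateral extent of the valid columns times the lateral pitch
#' (lateral pixels are physical distances); thickness is the mean optical
#' separation of the two surfaces divided by the refractive index.
#'
#' @param traces A `crystal_traces` from [detect_crystal()].
#' @param scan The [bscan()] the traces came from.
#' @return One-row tibble of class `crystal_measurement`: `length_um`,
#'   `thickness_um`, `n_cols`, `col_start`, `col_end`, `row_top`, `row_bottom`.
#' @export
measure_crystal <- function(traces, scan) {
  stopifnot(inherits(traces, "crystal_traces"), inherits(scan, "bscan"))
  v <- traces$valid_cols
  sep_px <- traces$bottom[v - traces$roi[3] + 1L] -
    traces$top[v - traces$roi[3] + 1L]
  out <- tibble::tibble(
    length_um = (max(v) - min(v) + 1L) * scan$lateral_pitch,
    thickness_um = mean(sep_px) * scan$axial_pitch / scan$refractive_index,
    n_cols = length(v), col_start = min(v), col_end = max(v),
    row_top = mean(traces$top, na.rm = TRUE),
    row_bottom = mean(traces$bottom, na.rm = TRUE)
  )
  class(out) <- c("crystal_measurement", class(out))
  out
}

#' Summarize a cohort of crystal measurements
#'
#' @param measurements Tibble with `length_um` and `thickness_um` columns
#'   (rows from [measure_crystal()]), n >= 2.
#' @return Tibble with the arithmetic mean and sample (n-1) standard deviation
#'   of length and thickness.
#' @export
summarize_crystals <- function(measurements) {
  if (nrow(measurements) < 2L) {
    abort("at least 2 measurements are required for a cohort summary.")
  }
  tibble::tibble(
    n = nrow(measurements),
    mean_length_um = mean(measurements$length_um),
    sd_length_um = sd(measurements$length_um),
    mean_thickness_um = mean(measurements$thickness_um),
    sd_thickness_um = sd(measurements$thickness_um)
  )
}
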