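# Dimensionless, contrast-invariant edge-steepness metric evaluated on
# intensity profiles drawn perpendicular to metacarpal shaft edges.
#
# steepness = kappa * max|dI/ds| (per mm) * 1 mm / plateau contrast
#
# The plateau contrast is a robust (5th/95th percentile) range computed
# over the outer quarters of the profile, i.e. the two plateaus flanking
# the edge. Normalising by the plateaus rather than the full profile keeps
# the metric responsive to edge enhancement: unsharp-mask overshoot sits
# next to the edge and would otherwise inflate the denominator as fast as
# the gradient, capping the metric below the "too sharp" gate.
#
# kappa is fixed by a calibration anchor: a noise-free step edge blurred
# with a 0.6 mm Gaussian (typical film sharpness) scores 5.75, the middle
# of the 5-6.5 interval observed for film.

.sharpnessEnv <- new.env(parent = emptyenv())

.referenceProfile <- function(sigma_mm = 0.6, spacing_mm = 0.25,
                              half_len_mm = 4) {
  s <- seq(-half_len_mm, half_len_mm, by = spacing_mm)
  list(samples = stats::pnorm(s / sigma_mm), spacing = spacing_mm)
}

.rawSteepness <- function(samples, spacing_mm) {
  n <- length(samples)
  q <- function(v, p) unname(stats::quantile(v, p, names = FALSE, type = 7))
  k <- max(2L, floor(n / 4))
  plateau <- c(samples[seq_len(k)], samples[seq.int(n - k + 1L, n)])
  lo <- q(plateau, 0.05)
  hi <- q(plateau, 0.95)
  rng <- hi - lo
  scale <- max(abs(samples), 1e-12)
  if (!is.finite(rng) || rng <= 1e-8 * scale)
    stop("undefined edge: profile is flat within the intensity resolution")
  gmax <- max(abs(diff(samples))) / spacing_mm       # per mm
  gmax * 1 / rng                                     # x 1 mm width scale
}

#' Calibration constant of the sharpness metric
#'
#' The constant \eqn{\kappa} scaling the raw normalised gradient so that a
#' reference Gaussian-blurred step edge (\eqn{\sigma} = 0.6 mm, the middle
#' of the sharpness range typical of film radiographs) scores exactly
#' \code{target}. Computed once through the same code path as
#' \code{\link{profileSteepness}} and cached.
#'
#' @param sigma_ref_mm blur of the reference edge, mm.
#' @param target sharpness value assigned to the reference edge.
#' @return The calibration constant (dimensionless).
#' @export
sharpnessKappa <- function(sigma_ref_mm = 0.6, target = 5.75) {
  key <- sprintf("%.6g_%.6g", sigma_ref_mm, target)
  if (!is.null(.sharpnessEnv[[key]])) return(.sharpnessEnv[[key]])
  ref <- .referenceProfile(sigma_ref_mm)
  kappa <- target / .rawSteepness(ref$samples, ref$spacing)
  .sharpnessEnv[[key]] <- kappa
  kappa
}

#' Edge steepness of a single intensity profile
#'
#' Computes the dimensionless sharpness of one profile sampled
#' perpendicular to a bone edge: the maximum absolute finite-difference
#' gradient (per mm, times a 1 mm width scale) divided by the robust
#' plateau contrast, scaled by the calibration constant
#' \code{\link{sharpnessKappa}}. Invariant under any linear intensity map
#' \eqn{aI + b} (a > 0) and strictly decreasing in Gaussian blur.
#'
#' @param samples ordered intensity values along the profile (>= 8).
#' @param spacing_mm physical distance between consecutive samples, mm.
#' @param kappa calibration constant; default anchors a 0.6 mm blurred
#'   step at 5.75.
#' @return Dimensionless sharpness (>= 0).
#' @examples
#' s <- seq(-4, 4, by = 0.25)
#' profileSteepness(pnorm(s / 0.6), 0.25)   # 5.75 by calibration
#' @export
profileSteepness <- function(samples, spacing_mm, kappa = sharpnessKappa()) {
  samples <- as.numeric(samples)
  if (length(samples) < 8L) stop("a profile needs at least 8 samples")
  if (!is.finite(spacing_mm) || spacing_mm <= 0)
    stop("spacing_mm must be > 0")
  if (!all(is.finite(samples))) stop("profile samples must be finite")
  kappa * .rawSteepness(samples, spacing_mm)
}

# bilinear interpolation; x, y are 0-based pixel coordinates with pixel
# centres at integers; img is a matrix indexed [row = y + 1, col = x + 1]
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  v <- rep(NA_real_, length(x))
  if (any(ok)) {
    i00 <- cbind(y0[ok] + 1, x0[ok] + 1)
    i01 <- cbind(y0[ok] + 1, x1[ok] + 1)
    i10 <- cbind(y1[ok] + 1, x0[ok] + 1)
    i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
    v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00] +
      fx[ok] * (1 - fy[ok]) * img[i01] +
      (1 - fx[ok]) * fy[ok] * img[i10] +
      fx[ok] * fy[ok] * img[i11]
  }
  v
}

#' Sharpness of an image over metacarpal edge regions
#'
#' Samples intensity profiles perpendicular to the supplied edge segments
#' (by convention both shaft edges of metacarpals 2-4), scores each with
#' \code{\link{profileSteepness}}, discards profiles with an undefined
#' edge or samples outside the image, and returns the median — robust to
#' the occasional occluded edge.
#'
#' @param image numeric matrix (grayscale; rows = y, columns = x), or a
#'   path to a single-channel PNG/TIFF file.
#' @param edge_rois \code{data.frame} with columns \code{x0, y0, x1, y1}:
#'   segment endpoints in 0-based pixel coordinates running \emph{along}
#'   each edge.
#' @param pixel_spacing_mm physical pixel size, mm (default 0.1).
#' @param profile_length_mm total profile length across the edge (default
#'   8 mm).
#' @param step_mm sampling step along the profile (default 0.25 mm).
#' @param offsets fractional positions along each segment at which
#'   profiles are drawn.
#' @param kappa calibration constant, see \code{\link{sharpnessKappa}}.
#' @return \code{list(value = <dimensionless sharpness>,
#'   n_profiles_used = <count>)}.
#' @examples
#' sim <- simulateEdgeImage(blur_sigma_mm = 0.6, seed = 1)
#' imageSharpness(sim$image, sim$edge_rois)$value   # about 5.75
#' @export
imageSharpness <- function(image, edge_rois, pixel_spacing_mm = 0.1,
                           profile_length_mm = 8, step_mm = 0.25,
                           offsets = c(0.25, 0.5, 0.75),
                           kappa = sharpnessKappa()) {
  if (is.character(image)) image <- readGrayscaleImage(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix or a path to a PNG/TIFF file")
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(edge_rois)))
    stop("edge_rois must have columns x0, y0, x1, y1")
  if (!is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("pixel_spacing_mm must be > 0")

  half <- profile_length_mm / 2
  s_mm <- seq(-half, half, by = step_mm)
  vals <- numeric(0)
  for (i in seq_len(nrow(edge_rois))) {
    p0 <- c(edge_rois$x0[i], edge_rois$y0[i])
    p1 <- c(edge_rois$x1[i], edge_rois$y1[i])
    d <- p1 - p0
    len <- sqrt(sum(d^2))
    if (len == 0) next
    d <- d / len
    perp <- c(-d[2], d[1])
    for (t in offsets) {
      ctr <- p0 + t * (p1 - p0)
      px <- ctr[1] + perp[1] * s_mm / pixel_spacing_mm
      py <- ctr[2] + perp[2] * s_mm / pixel_spacing_mm
      prof <- .bilinear(image, px, py)
      if (anyNA(prof)) next                        # leaves the image
      v <- tryCatch(profileSteepness(prof, step_mm, kappa),
                    error = function(e) NA_real_)  # undefined edge
      if (is.finite(v)) vals <- c(vals, v)
    }
  }
  if (length(vals) < 2L)
    stop("insufficient usable edge profiles (need at least 2)")
  list(value = stats::median(vals), n_profiles_used = length(vals))
}

#' Read a grayscale PNG or TIFF image as a numeric matrix
#'
#' Single-channel 8- or 16-bit images; multi-channel input is averaged to
#' one channel. Values are returned on the [0, 1] scale used by the
#' readers — the sharpness metric is invariant to the scale.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric matrix, rows = y, columns = x.
#' @export
readGrayscaleImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a numeric matrix as a 16-bit grayscale PNG
#'
#' Intensities are clipped to [0, 1] and quantised to 16 bits.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGrayscaleImage <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}
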