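# Synthetic cohorts, bone sets and edge-test images with the statistical
# structure the accuracy evaluations assume: independent additive Gaussian
# method error, Gaussian single-rater error with a rare gross-error
# contamination (fat tails), per-bone scatter with occasional anomalous
# bones, and radiograph-like band images for the sharpness metric.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a study cohort of rated cases
#'
#' Draws \code{nCases} cases under the spec's error model: a true bone age
#' uniform over the sex's study range, an automated rating
#' \code{true + N(0, sigmaAuto)}, and \code{nRaters} manual ratings
#' \code{true + N(0, sigmaRater)}, each independently replaced with
#' probability \code{grossErrorRate} by \code{true + N(0, grossErrorSD)}
#' (the gross-error mixture that produces the fat tails seen in real
#' manual ratings). All ratings are truncated at 0 (no negative
#' maturity). Output is bitwise reproducible for a given spec.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param bones if \code{TRUE}, also simulate a 21-bone table per case
#'   (see \code{\link{simulateBoneSet}}) and return it as the
#'   \code{"bones"} attribute of the cohort.
#' @return A \code{data.frame} with columns \code{image_id}, \code{sex},
#'   \code{true_ba}, \code{auto_ba}, \code{rating_1..rating_k}.
#' @examples
#' coh <- simulateCohort(SimulationSpec(nCases = 5, seed = 42))
#' @export
simulateCohort <- function(spec, bones = FALSE) {
  validObject(spec)
  n <- spec@nCases
  k <- spec@nRaters
  .withSeed(spec@seed, {
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    rng <- ifelse(sex == "male",
                  spec@truthRangeMale[2] - spec@truthRangeMale[1],
                  spec@truthRangeFemale[2] - spec@truthRangeFemale[1])
    lo <- ifelse(sex == "male", spec@truthRangeMale[1],
                 spec@truthRangeFemale[1])
    true_ba <- lo + rng * stats::runif(n)
    auto_ba <- pmax(0, true_ba + stats::rnorm(n, 0, spec@sigmaAuto))
    ratings <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      r <- true_ba + stats::rnorm(n, 0, spec@sigmaRater)
      gross <- stats::runif(n) < spec@grossErrorRate
      if (any(gross))
        r[gross] <- true_ba[gross] +
          stats::rnorm(sum(gross), 0, spec@grossErrorSD)
      ratings[, j] <- pmax(0, r)
    }
    coh <- data.frame(image_id = sprintf("case_%05d", seq_len(n)),
                      sex = sex, true_ba = true_ba, auto_ba = auto_ba,
                      stringsAsFactors = FALSE)
    colnames(ratings) <- paste0("rating_", seq_len(k))
    coh <- cbind(coh, as.data.frame(ratings))
    if (bones) {
      bt <- do.call(rbind, lapply(seq_len(n), function(i) {
        b <- simulateBoneSet(true_ba[i], spec, .seeded = FALSE)
        cbind(image_id = coh$image_id[i], b)
      }))
      rownames(bt) <- NULL
      attr(coh, "bones") <- bt
    }
    coh
  })
}

#' Simulate the 21 tubular bones of one hand
#'
#' The 21 tubular bones mature under the same endocrine control, so each
#' bone's estimated age scatters around the case's true bone age:
#' \code{max(0, true_ba + N(0, boneSD))}. With probability
#' \code{anomalyRate} a bone is anomalous — appearance score drawn from
#' Uniform(0.7, 1) plus an extra age shift \code{N(0, 3 boneSD)} —
#' otherwise its appearance score is Uniform(0, 0.3).
#'
#' @param true_ba true bone age, years (>= 0).
#' @param spec a \linkS4class{SimulationSpec} (uses \code{boneSD},
#'   \code{anomalyRate} and, when seeding, \code{seed}).
#' @param .seeded set the spec seed before drawing (default). Internal
#'   callers that already manage the RNG pass \code{FALSE}.
#' @return A per-bone table as built by \code{\link{boneTable}}.
#' @examples
#' simulateBoneSet(10, SimulationSpec(boneSD = 0.3, seed = 1))
#' @export
simulateBoneSet <- function(true_ba, spec = SimulationSpec(), .seeded = TRUE) {
  stopifnot(is.finite(true_ba), true_ba >= 0)
  draw <- function() {
    ids <- boneRoster()
    n <- length(ids)
    age <- true_ba + stats::rnorm(n, 0, spec@boneSD)
    anom <- stats::runif(n) < spec@anomalyRate
    score <- stats::runif(n, 0, 0.3)
    if (any(anom)) {
      score[anom] <- stats::runif(sum(anom), 0.7, 1)
      age[anom] <- age[anom] + stats::rnorm(sum(anom), 0, 3 * spec@boneSD)
    }
    boneTable(ids, pmax(0, age), score)
  }
  if (.seeded) .withSeed(spec@seed, draw()) else draw()
}

#' Simulate a radiograph-like edge-test image
#'
#' Renders three vertical bright bands (metacarpal-like shafts) on a dark
#' background with Poisson-like noise, blurs with a Gaussian point-spread
#' of \code{blur_sigma_mm}, optionally applies an unsharp mask (gain
#' \code{enhance_gain}, radius \code{enhance_sigma_mm}) emulating modality
#' edge-enhancement post-processing, and finally a linear intensity map
#' \code{a I + b}. ROI segments running along both shaft edges of each
#' band are returned for \code{\link{imageSharpness}}.
#'
#' @param blur_sigma_mm Gaussian blur of the imaging chain, mm (>= 0).
#'   0.6 mm reproduces the calibration anchor (sharpness 5.75).
#' @param enhance_gain unsharp-mask gain (0 = no enhancement).
#' @param enhance_sigma_mm unsharp-mask radius, mm.
#' @param contrast_a,contrast_b linear intensity map applied last.
#' @param seed RNG seed for the noise.
#' @param pixel_spacing_mm pixel size, mm.
#' @param noise_sd relative amplitude of the Poisson-like noise.
#' @param height_px image height in pixels.
#' @return \code{list(image = <matrix>, edge_rois = <data.frame x0,y0,x1,y1>,
#'   pixel_spacing_mm = <mm>)}.
#' @examples
#' sim <- simulateEdgeImage(blur_sigma_mm = 0.6, seed = 1)
#' imageSharpness(sim$image, sim$edge_rois)$value
#' @export
simulateEdgeImage <- function(blur_sigma_mm = 0.6, enhance_gain = 0,
                              enhance_sigma_mm = 1.0, contrast_a = 1,
                              contrast_b = 0, seed = 1,
                              pixel_spacing_mm = 0.1, noise_sd = 0.004,
                              height_px = 240L) {
  stopifnot(blur_sigma_mm >= 0, enhance_gain >= 0, contrast_a > 0)
  sp <- pixel_spacing_mm
  band_w <- 12 / sp                       # 12 mm shafts
  gap_w <- 12 / sp
  margin <- 10 / sp
  width_px <- as.integer(round(2 * margin + 3 * band_w + 2 * gap_w))
  h <- as.integer(height_px)

  # band edges in 0-based x pixel coordinates
  lefts <- margin + (0:2) * (band_w + gap_w)
  rights <- lefts + band_w

  img <- matrix(0.2, h, width_px)
  xs <- seq_len(width_px) - 1          # 0-based column centres
  for (i in 1:3)
    img[, xs >= lefts[i] & xs < rights[i]] <- 0.7

  .withSeed(seed, {
    if (noise_sd > 0)
      img <- img + sqrt(img) * matrix(stats::rnorm(length(img), 0, noise_sd),
                                      h, width_px)
  })
  if (blur_sigma_mm > 0)
    img <- EBImage::gblur(img, sigma = blur_sigma_mm / sp)
  if (enhance_gain > 0) {
    low <- EBImage::gblur(img, sigma = enhance_sigma_mm / sp)
    img <- img + enhance_gain * (img - low)
  }
  img <- contrast_a * img + contrast_b

  y0 <- round(0.3 * h); y1 <- round(0.7 * h)
  edge_x <- as.numeric(rbind(lefts, rights)) - 0.5  # edge midway between cols
  rois <- data.frame(x0 = edge_x, y0 = y0, x1 = edge_x, y1 = y1)
  list(image = img, edge_rois = rois, pixel_spacing_mm = sp)
}
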