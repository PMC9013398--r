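# S4 containers for the self-validation cascade, the cohort simulator and
# the agreement-statistics toolkit.

.IMAGE_STATUSES <- c("accepted", "hand_not_found", "too_sharp", "too_blurred",
                     "no_radius_mature", "accepted_with_warning")
.REJECTION_REASONS <- c("none", "appearance", "deviation")
.DEVIATION_MODES <- c("loo_iterative", "grand_single")

#' Thresholds of the self-validation cascade
#'
#' Holds every tunable of the six-step cascade. The first two steps
#' validate individual bones (anomalous appearance; deviation from the
#' consensus bone age, with a threshold of 2.4 y above a consensus of 7 y,
#' falling linearly to 1.2 y at birth). The remaining gates validate the
#' whole image: at least 8 accepted bones, sharpness within (4, 13], and a
#' radius requirement for near-mature hands (short-bone mean above 17 y
#' for boys, 15 y for girls).
#'
#' @slot devThresholdHigh deviation threshold (years) at and above
#'   \code{rampEnd} consensus bone age; default 2.4.
#' @slot devThresholdBirth deviation threshold (years) at a consensus bone
#'   age of 0; default 1.2.
#' @slot rampEnd consensus bone age (years) where the ramp reaches its
#'   plateau; default 7.
#' @slot minBones minimum accepted-bone count, below which the image is
#'   rejected as \code{hand_not_found}; default 8.
#' @slot sharpMax sharpness above which the image is \code{too_sharp}
#'   (over-aggressive edge enhancement); default 13.
#' @slot sharpMin sharpness below which the image is \code{too_blurred};
#'   default 4.
#' @slot matureBAMale,matureBAFemale short-bone mean bone age (years)
#'   above which a rejected radius voids the analysis; defaults 17 and 15.
#' @slot appearanceThreshold appearance anomaly score in [0,1] above which
#'   a bone is rejected; default 0.5.
#' @slot bypassQualityGates if \code{TRUE}, the sharpness and radius gates
#'   downgrade to \code{accepted_with_warning} instead of rejecting; the
#'   minimum-bone gate is never bypassable. Default \code{FALSE}.
#' @slot deviationMode \code{"loo_iterative"} (iterative worst-first
#'   removal against the leave-one-out mean, the default) or
#'   \code{"grand_single"} (single pass against the grand mean).
#'
#' @seealso \code{\link{ValidationConfig}} for the constructor,
#'   \code{\link{runCascade}}.
#' @export
setClass("ValidationConfig",
  representation(
    devThresholdHigh = "numeric",
    devThresholdBirth = "numeric",
    rampEnd = "numeric",
    minBones = "integer",
    sharpMax = "numeric",
    sharpMin = "numeric",
    matureBAMale = "numeric",
    matureBAFemale = "numeric",
    appearanceThreshold = "numeric",
    bypassQualityGates = "logical",
    deviationMode = "character"
  ),
  prototype(
    devThresholdHigh = 2.4, devThresholdBirth = 1.2, rampEnd = 7,
    minBones = 8L, sharpMax = 13, sharpMin = 4,
    matureBAMale = 17, matureBAFemale = 15,
    appearanceThreshold = 0.5, bypassQualityGates = FALSE,
    deviationMode = "loo_iterative"
  )
)

setValidity("ValidationConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("devThresholdHigh", "devThresholdBirth", "rampEnd", "sharpMax",
              "sharpMin", "matureBAMale", "matureBAFemale",
              "appearanceThreshold"))
    if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(msg)) return(msg)
  if (object@devThresholdBirth > object@devThresholdHigh)
    msg <- c(msg, "devThresholdBirth must be <= devThresholdHigh")
  if (object@rampEnd <= 0) msg <- c(msg, "rampEnd must be > 0")
  if (object@sharpMin >= object@sharpMax)
    msg <- c(msg, "sharpMin must be < sharpMax")
  if (object@minBones < 1L) msg <- c(msg, "minBones must be >= 1")
  if (object@appearanceThreshold < 0 || object@appearanceThreshold > 1)
    msg <- c(msg, "appearanceThreshold must lie in [0, 1]")
  if (!object@deviationMode %in% .DEVIATION_MODES)
    msg <- c(msg, sprintf("deviationMode must be one of: %s",
                          paste(.DEVIATION_MODES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ValidationConfig
#'
#' @param devThresholdHigh,devThresholdBirth,rampEnd deviation-threshold
#'   ramp: \code{devThresholdBirth} years at a consensus of 0, rising
#'   linearly to \code{devThresholdHigh} years at \code{rampEnd}.
#' @param minBones minimum accepted-bone count (gate 1).
#' @param sharpMax,sharpMin sharpness gates 2 and 3.
#' @param matureBAMale,matureBAFemale maturity limits of the radius gate 4.
#' @param appearanceThreshold appearance-score cutoff of bone step A.
#' @param bypassQualityGates downgrade gates 2-4 to warnings.
#' @param deviationMode consensus strategy of bone step B; see
#'   \linkS4class{ValidationConfig}.
#' @return A \linkS4class{ValidationConfig}.
#' @examples
#' cfg <- ValidationConfig()
#' deviationThreshold(0, cfg)    # 1.2
#' deviationThreshold(12, cfg)   # 2.4
#' @export
ValidationConfig <- function(devThresholdHigh = 2.4, devThresholdBirth = 1.2,
                             rampEnd = 7, minBones = 8L, sharpMax = 13,
                             sharpMin = 4, matureBAMale = 17,
                             matureBAFemale = 15, appearanceThreshold = 0.5,
                             bypassQualityGates = FALSE,
                             deviationMode = c("loo_iterative", "grand_single")) {
  new("ValidationConfig",
      devThresholdHigh = as.numeric(devThresholdHigh),
      devThresholdBirth = as.numeric(devThresholdBirth),
      rampEnd = as.numeric(rampEnd),
      minBones = as.integer(minBones),
      sharpMax = as.numeric(sharpMax), sharpMin = as.numeric(sharpMin),
      matureBAMale = as.numeric(matureBAMale),
      matureBAFemale = as.numeric(matureBAFemale),
      appearanceThreshold = as.numeric(appearanceThreshold),
      bypassQualityGates = isTRUE(bypassQualityGates),
      deviationMode = match.arg(deviationMode))
}

setMethod("show", "ValidationConfig", function(object) {
  cat("ValidationConfig\n")
  cat(sprintf("  deviation ramp : %.2f y at birth -> %.2f y at %.1f y (%s)\n",
              object@devThresholdBirth, object@devThresholdHigh,
              object@rampEnd, object@deviationMode))
  cat(sprintf("  min bones      : %d\n", object@minBones))
  cat(sprintf("  sharpness gate : (%.1f, %.1f]\n", object@sharpMin, object@sharpMax))
  cat(sprintf("  mature BA      : %.1f y (male) / %.1f y (female)\n",
              object@matureBAMale, object@matureBAFemale))
  cat(sprintf("  appearance     : > %.2f rejects\n", object@appearanceThreshold))
  if (object@bypassQualityGates)
    cat("  quality gates 2-4 bypassed (warnings only)\n")
  invisible(object)
})

#' One analysed hand radiograph
#'
#' A case after (or before) the self-validation cascade: sex, the per-bone
#' table over the 21 tubular bones, the image sharpness, the gate status
#' and the final bone age (the mean over accepted tubular bones).
#'
#' @slot imageId case identifier.
#' @slot sex \code{"male"} or \code{"female"}.
#' @slot bones per-bone \code{data.frame}; see \code{\link{bones}}.
#' @slot sharpness dimensionless sharpness, or \code{NA} if not measured.
#' @slot status one of the six gate statuses.
#' @slot finalBoneAge years; present iff status is \code{accepted} or
#'   \code{accepted_with_warning}.
#' @export
setClass("ImageAssessment",
  representation(
    imageId = "character", sex = "character", bones = "data.frame",
    sharpness = "numeric", status = "character", finalBoneAge = "numeric"
  ),
  prototype(imageId = NA_character_, sex = "male",
            sharpness = NA_real_, status = "accepted",
            finalBoneAge = NA_real_)
)

setValidity("ImageAssessment", function(object) {
  msg <- character()
  if (length(object@sex) != 1L || !object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(object@status) != 1L || !object@status %in% .IMAGE_STATUSES)
    msg <- c(msg, sprintf("status must be one of: %s",
                          paste(.IMAGE_STATUSES, collapse = ", ")))
  b <- object@bones
  need <- c("bone_id", "bone_age", "appearance_score", "accepted",
            "rejection_reason")
  if (!all(need %in% names(b))) {
    msg <- c(msg, sprintf("bones must have columns: %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(b)) {
    if (anyDuplicated(b$bone_id))
      msg <- c(msg, "bone_id must be unique within an image")
    if (!all(b$bone_id %in% boneRoster()))
      msg <- c(msg, "unknown bone_id (not in the 21-bone tubular roster)")
    if (!all(is.finite(b$bone_age) & b$bone_age >= 0))
      msg <- c(msg, "bone_age must be finite and >= 0")
    if (!all(b$rejection_reason %in% .REJECTION_REASONS))
      msg <- c(msg, "invalid rejection_reason")
    if (!all((b$rejection_reason == "none") == b$accepted))
      msg <- c(msg, "rejection_reason must be 'none' iff accepted")
  }
  fba <- object@finalBoneAge
  has <- length(fba) == 1L && is.finite(fba)
  want <- object@status %in% c("accepted", "accepted_with_warning")
  if (length(object@status) == 1L && has != want)
    msg <- c(msg, "finalBoneAge must be present iff the image is accepted")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImageAssessment", function(object) {
  cat(sprintf("ImageAssessment '%s' (%s)\n", object@imageId, object@sex))
  cat(sprintf("  status   : %s\n", object@status))
  if (is.finite(object@finalBoneAge))
    cat(sprintf("  bone age : %.2f y (%.1f months)\n",
                object@finalBoneAge, 12 * object@finalBoneAge))
  cat(sprintf("  bones    : %d accepted of %d\n",
              sum(object@bones$accepted), nrow(object@bones)))
  if (is.finite(object@sharpness))
    cat(sprintf("  sharpness: %.2f\n", object@sharpness))
  rej <- object@bones[!object@bones$accepted, , drop = FALSE]
  if (nrow(rej))
    cat("  rejected :", paste(sprintf("%s(%s)", rej$bone_id,
                                      rej$rejection_reason), collapse = " "),
        "\n")
  invisible(object)
})

#' Generative parameters for a synthetic study cohort
#'
#' Describes the error model under which synthetic cases are drawn: a true
#' bone age from a uniform range per sex, an automated rating with
#' independent Gaussian method error, manual ratings with Gaussian
#' single-rater error contaminated by a rare gross-error component (fat
#' tails), and a per-bone scatter with occasional anomalous bones.
#'
#' @slot nCases number of cases.
#' @slot truthRangeMale,truthRangeFemale uniform true-bone-age range
#'   (years); defaults 0-17 and 0-15, the span such studies cover.
#' @slot sigmaAuto SD (years) of the automated method about truth;
#'   reference value 0.33.
#' @slot sigmaRater single-rater SD (years); reference values 0.52
#'   (Tuebingen-like) and 0.68 (RSNA-like).
#' @slot nRaters manual raters per case.
#' @slot boneSD per-bone scatter (years) about the case's true bone age.
#' @slot anomalyRate probability a bone is anomalous (high appearance
#'   score plus an extra age shift).
#' @slot grossErrorRate,grossErrorSD contamination mixture for manual
#'   ratings: with probability \code{grossErrorRate} a rating is redrawn
#'   with SD \code{grossErrorSD}.
#' @slot seed integer seed fixing every output exactly.
#' @export
setClass("SimulationSpec",
  representation(
    nCases = "integer", truthRangeMale = "numeric",
    truthRangeFemale = "numeric", sigmaAuto = "numeric",
    sigmaRater = "numeric", nRaters = "integer", boneSD = "numeric",
    anomalyRate = "numeric", grossErrorRate = "numeric",
    grossErrorSD = "numeric", seed = "integer"
  ),
  prototype(nCases = 100L, truthRangeMale = c(0, 17),
            truthRangeFemale = c(0, 15), sigmaAuto = 0.33,
            sigmaRater = 0.52, nRaters = 1L, boneSD = 0.5,
            anomalyRate = 0, grossErrorRate = 0.01, grossErrorSD = 1.5,
            seed = 1L)
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nCases < 1L) msg <- c(msg, "nCases must be >= 1")
  for (s in c("sigmaAuto", "sigmaRater", "boneSD", "grossErrorSD"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", s))
  for (s in c("anomalyRate", "grossErrorRate")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
  }
  for (s in c("truthRangeMale", "truthRangeFemale")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] < 0 || r[2] < r[1])
      msg <- c(msg, sprintf("'%s' must be c(lo, hi) with 0 <= lo <= hi", s))
  }
  if (object@nRaters < 1L) msg <- c(msg, "nRaters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' @param nCases,truthRangeMale,truthRangeFemale,sigmaAuto,sigmaRater,nRaters
#'   see \linkS4class{SimulationSpec}.
#' @param boneSD,anomalyRate,grossErrorRate,grossErrorSD,seed
#'   see \linkS4class{SimulationSpec}.
#' @return A \linkS4class{SimulationSpec}.
#' @examples
#' spec <- SimulationSpec(nCases = 200, sigmaAuto = 0.33, sigmaRater = 0.52,
#'                        seed = 7)
#' @export
SimulationSpec <- function(nCases = 100L, truthRangeMale = c(0, 17),
                           truthRangeFemale = c(0, 15), sigmaAuto = 0.33,
                           sigmaRater = 0.52, nRaters = 1L, boneSD = 0.5,
                           anomalyRate = 0, grossErrorRate = 0.01,
                           grossErrorSD = 1.5, seed = 1L) {
  new("SimulationSpec", nCases = as.integer(nCases),
      truthRangeMale = as.numeric(truthRangeMale),
      truthRangeFemale = as.numeric(truthRangeFemale),
      sigmaAuto = as.numeric(sigmaAuto), sigmaRater = as.numeric(sigmaRater),
      nRaters = as.integer(nRaters), boneSD = as.numeric(boneSD),
      anomalyRate = as.numeric(anomalyRate),
      grossErrorRate = as.numeric(grossErrorRate),
      grossErrorSD = as.numeric(grossErrorSD), seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d cases, seed %d\n", object@nCases, object@seed))
  cat(sprintf("  sigma_auto %.2f y, sigma_rater %.2f y x %d rater(s)\n",
              object@sigmaAuto, object@sigmaRater, object@nRaters))
  cat(sprintf("  bone SD %.2f y, anomaly rate %.2f, gross errors %.1f%% @ SD %.1f y\n",
              object@boneSD, object@anomalyRate, 100 * object@grossErrorRate,
              object@grossErrorSD))
  invisible(object)
})

#' Agreement report for a paired-rating table
#'
#' Accuracy of an automated rating against a manual reference: RMS error
#' (years), MAD (months), the reference's own error, the quadrature-
#' decomposed true accuracy, the implied single-rater variability, the
#' error variance as a fraction of the natural bone-age variance, and the
#' Bland-Altman bias and limits of agreement.
#'
#' @slot n number of paired cases.
#' @slot rms RMS of (auto - reference), years.
#' @slot madMonths mean absolute deviation, months.
#' @slot refError RMS error of the reference about truth, years.
#' @slot trueAccuracy \code{sqrt(rms^2 - refError^2)}, years.
#' @slot raterSD single-rater SD implied by the panel, years.
#' @slot varianceFraction \code{trueAccuracy} variance as percent of the
#'   natural 1 y^2 variance.
#' @slot bias,loa Bland-Altman mean difference and 95\% limits.
#' @slot table per-case \code{data.frame(mean, diff)}.
#' @export
setClass("AgreementReport",
  representation(n = "integer", rms = "numeric", madMonths = "numeric",
                 refError = "numeric", trueAccuracy = "numeric",
                 raterSD = "numeric", varianceFraction = "numeric",
                 bias = "numeric", loa = "numeric", table = "data.frame"),
  prototype(refError = NA_real_, trueAccuracy = NA_real_,
            raterSD = NA_real_, varianceFraction = NA_real_)
)

setValidity("AgreementReport", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (is.finite(object@rms) && is.finite(object@madMonths) &&
      object@madMonths / 12 > object@rms + 1e-9)
    msg <- c(msg, "MAD (in years) cannot exceed the RMS error")
  if (length(object@loa) != 2L) msg <- c(msg, "loa must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d)\n", object@n))
  cat(sprintf("  RMS error     : %.2f y\n", object@rms))
  cat(sprintf("  MAD           : %.1f months\n", object@madMonths))
  if (is.finite(object@refError)) {
    cat(sprintf("  reference err : %.2f y\n", object@refError))
    cat(sprintf("  true accuracy : %.2f y (%d%% of natural variance)\n",
                object@trueAccuracy, round(object@varianceFraction)))
  }
  if (is.finite(object@raterSD))
    cat(sprintf("  rater SD      : %.2f y\n", object@raterSD))
  cat(sprintf("  Bland-Altman  : bias %.2f y, LoA [%.2f, %.2f] y\n",
              object@bias, object@loa[1], object@loa[2]))
  invisible(object)
})

#' Disputed-case analysis
#'
#' Counts over the disputed cases (automated and manual ratings more than
#' \code{disputeThreshold} years apart, default 1.8): how often the
#' automated rating was closer to the rerating-panel reference, and how
#' many grave errors (more than \code{graveThreshold} years from the
#' reference, default 1.5) each method made.
#'
#' @slot disputeThreshold,graveThreshold years.
#' @slot nDisputed,nAutoCloser,nManualGrave,nAutoGrave counts.
#' @export
setClass("DisputedAnalysis",
  representation(disputeThreshold = "numeric", graveThreshold = "numeric",
                 nDisputed = "integer", nAutoCloser = "integer",
                 nManualGrave = "integer", nAutoGrave = "integer"))

setValidity("DisputedAnalysis", function(object) {
  msg <- character()
  if (object@nAutoCloser > object@nDisputed)
    msg <- c(msg, "nAutoCloser cannot exceed nDisputed")
  if (object@nManualGrave > object@nDisputed ||
      object@nAutoGrave > object@nDisputed)
    msg <- c(msg, "grave counts cannot exceed nDisputed")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DisputedAnalysis", function(object) {
  cat(sprintf("DisputedAnalysis (|auto - manual| > %.1f y)\n",
              object@disputeThreshold))
  cat(sprintf("  disputed cases : %d\n", object@nDisputed))
  if (object@nDisputed > 0)
    cat(sprintf("  auto closer    : %d (%.0f%%)\n", object@nAutoCloser,
                100 * object@nAutoCloser / object@nDisputed))
  cat(sprintf("  grave errors (> %.1f y): manual %d, auto %d\n",
              object@graveThreshold, object@nManualGrave, object@nAutoGrave))
  invisible(object)
})
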