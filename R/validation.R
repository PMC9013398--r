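# The six-step self-validation cascade: two per-bone steps (appearance,
# deviation from consensus) followed by four image-level gates (minimum
# bone count, too sharp, too blurred, no radius in a near-mature hand).

.BONE_ROSTER <- c(
  "radius", "ulna",
  paste0("mc", 1:5),           # metacarpals 1-5
  paste0("pp", 1:5),           # proximal phalanges 1-5
  paste0("mp", 2:5),           # middle phalanges 2-5 (digit 1 has none)
  paste0("dp", 1:5)            # distal phalanges 1-5
)

#' The fixed roster of 21 tubular bones
#'
#' The tubular bones of the hand and wrist carrying an epiphysis: radius,
#' ulna, metacarpals 1-5, proximal phalanges 1-5, middle phalanges 2-5 and
#' distal phalanges 1-5. Every per-bone table must use these identifiers;
#' tie-breaks in the cascade follow this order.
#'
#' @return Character vector of the 21 bone identifiers, in roster order.
#' @examples
#' boneRoster()
#' @export
boneRoster <- function() .BONE_ROSTER

# short bones of the maturity gate: everything except the two long bones
.shortBones <- function() setdiff(.BONE_ROSTER, c("radius", "ulna"))

#' Build a per-bone assessment table
#'
#' Convenience constructor for the per-bone table consumed by the cascade.
#' All bones start accepted with rejection reason \code{"none"}.
#'
#' @param bone_id identifiers from \code{\link{boneRoster}}.
#' @param bone_age estimated bone ages in years (finite, >= 0).
#' @param appearance_score anomaly scores in [0, 1]; higher means more
#'   anomalous. Default 0 (unremarkable appearance).
#' @return A \code{data.frame} in canonical roster order.
#' @examples
#' boneTable(boneRoster(), bone_age = rep(10, 21))
#' @export
boneTable <- function(bone_id, bone_age, appearance_score = 0) {
  stopifnot(length(bone_id) == length(bone_age))
  if (!all(bone_id %in% .BONE_ROSTER))
    stop("unknown bone_id: ", paste(setdiff(bone_id, .BONE_ROSTER), collapse = ", "))
  if (anyDuplicated(bone_id))
    stop("duplicate bone_id in bone table")
  if (!all(is.finite(bone_age) & bone_age >= 0))
    stop("bone_age must be finite and >= 0")
  appearance_score <- rep_len(appearance_score, length(bone_id))
  b <- data.frame(bone_id = as.character(bone_id),
                  bone_age = as.numeric(bone_age),
                  appearance_score = as.numeric(appearance_score),
                  accepted = TRUE,
                  rejection_reason = "none",
                  stringsAsFactors = FALSE)
  .canonicalBoneOrder(b)
}

.canonicalBoneOrder <- function(b) {
  b <- b[order(match(b$bone_id, .BONE_ROSTER)), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Deviation threshold as a function of consensus bone age
#'
#' The per-bone deviation cutoff of validation step B: 2.4 y at and above
#' a consensus bone age of 7 y, decreasing linearly to 1.2 y at birth
#' (defaults). Continuous, piecewise linear and non-decreasing.
#'
#' @param consensus_ba consensus bone age in years (vectorised, >= 0).
#' @param config a \linkS4class{ValidationConfig}.
#' @return Threshold(s) in years.
#' @examples
#' cfg <- ValidationConfig()
#' deviationThreshold(c(0, 3.5, 7, 12), cfg)  # 1.2 1.8 2.4 2.4
#' @export
deviationThreshold <- function(consensus_ba, config = ValidationConfig()) {
  if (!length(consensus_ba) || !all(is.finite(consensus_ba)) ||
      any(consensus_ba < 0))
    stop("consensus_ba must be finite and >= 0")
  hi <- config@devThresholdHigh
  lo <- config@devThresholdBirth
  ifelse(consensus_ba >= config@rampEnd, hi,
         lo + (hi - lo) * consensus_ba / config@rampEnd)
}

#' Validation step A: reject bones with anomalous appearance
#'
#' A bone whose shape or density distribution is at odds with what the
#' bone-finding model expects carries a high appearance score; scores
#' strictly above the configured threshold reject the bone. Already
#' rejected bones are left untouched.
#'
#' @param bones per-bone table (see \code{\link{boneTable}}).
#' @param config a \linkS4class{ValidationConfig}.
#' @return Updated bone table.
#' @export
rejectByAppearance <- function(bones, config = ValidationConfig()) {
  if (!all(is.finite(bones$appearance_score)) ||
      any(bones$appearance_score < 0 | bones$appearance_score > 1))
    stop("appearance_score must lie in [0, 1]")
  hit <- bones$accepted & bones$appearance_score > config@appearanceThreshold
  bones$accepted[hit] <- FALSE
  bones$rejection_reason[hit] <- "appearance"
  bones
}

#' Validation step B: reject bones deviating from the consensus bone age
#'
#' A bone whose age deviates by more than the ramp threshold
#' (\code{\link{deviationThreshold}}) from the average bone age of the
#' tubular bones is rejected. The default strategy is iterative
#' worst-first removal: each round the accepted bone with the largest
#' absolute deviation from the leave-one-out mean is tested against the
#' threshold evaluated at that mean; if it exceeds it, the bone is
#' rejected and the consensus recomputed. Iteration stops when no bone
#' exceeds its threshold or only two accepted bones remain. Ties go to the
#' lowest roster index. \code{deviationMode = "grand_single"} instead
#' performs one pass against the (contaminated) grand mean.
#'
#' @param bones per-bone table, typically after
#'   \code{\link{rejectByAppearance}}.
#' @param config a \linkS4class{ValidationConfig}.
#' @return \code{list(bones = <updated table>, consensus_ba = <mean of
#'   accepted bones, years>)}.
#' @examples
#' b <- boneTable(boneRoster(), c(rep(10, 20), 13))
#' rejectByDeviation(b)$consensus_ba   # 10: the 13-y bone is rejected
#' @export
rejectByDeviation <- function(bones, config = ValidationConfig()) {
  bones <- .canonicalBoneOrder(bones)
  if (!any(bones$accepted)) stop("no accepted bones")
  if (config@deviationMode == "grand_single") {
    idx <- which(bones$accepted)
    m <- mean(bones$bone_age[idx])
    thr <- deviationThreshold(m, config)
    hit <- idx[abs(bones$bone_age[idx] - m) > thr]
    bones$accepted[hit] <- FALSE
    bones$rejection_reason[hit] <- "deviation"
  } else {
    repeat {
      idx <- which(bones$accepted)
      if (length(idx) <= 2L) break
      ages <- bones$bone_age[idx]
      tot <- sum(ages)
      loo <- (tot - ages) / (length(ages) - 1L)
      dev <- abs(ages - loo)
      worst <- which.max(dev)                 # ties: lowest roster index
      if (dev[worst] > deviationThreshold(loo[worst], config)) {
        bones$accepted[idx[worst]] <- FALSE
        bones$rejection_reason[idx[worst]] <- "deviation"
      } else break
    }
  }
  list(bones = bones,
       consensus_ba = mean(bones$bone_age[bones$accepted]))
}

#' Image-level gates of the self-validation
#'
#' Applies, in order: (1) \code{hand_not_found} if fewer than
#' \code{minBones} bones survived bone-level validation — never
#' bypassable; (2) \code{too_sharp} if the sharpness exceeds
#' \code{sharpMax} (over-aggressive edge enhancement); (3)
#' \code{too_blurred} if it is below \code{sharpMin}; (4)
#' \code{no_radius_mature} if the mean bone age of the accepted short
#' bones (all tubular bones except radius and ulna) exceeds the sex's
#' maturity limit while the radius was rejected — near maturity the radius
#' is the only bone still carrying signal. With
#' \code{bypassQualityGates}, gates 2-4 downgrade to
#' \code{accepted_with_warning}. Accepted images get
#' \code{finalBoneAge} = mean over all accepted tubular bones, reported to
#' 2 decimals.
#'
#' @param assessment an \linkS4class{ImageAssessment} whose bone table has
#'   already been through steps A and B.
#' @param config a \linkS4class{ValidationConfig}.
#' @return The gated \linkS4class{ImageAssessment}.
#' @export
gateImage <- function(assessment, config = ValidationConfig()) {
  b <- assessment@bones
  nAcc <- sum(b$accepted)
  bypass <- config@bypassQualityGates
  warned <- FALSE

  if (nAcc < config@minBones) {
    assessment@status <- "hand_not_found"
    assessment@finalBoneAge <- NA_real_
    return(assessment)
  }

  sharp <- assessment@sharpness
  if (!is.finite(sharp)) {
    if (!bypass)
      stop("sharpness is missing but the sharpness gates are enabled")
  } else {
    if (sharp > config@sharpMax) {
      if (!bypass) {
        assessment@status <- "too_sharp"
        assessment@finalBoneAge <- NA_real_
        return(assessment)
      }
      warned <- TRUE
    }
    if (sharp < config@sharpMin) {
      if (!bypass) {
        assessment@status <- "too_blurred"
        assessment@finalBoneAge <- NA_real_
        return(assessment)
      }
      warned <- TRUE
    }
  }

  short <- b$accepted & b$bone_id %in% .shortBones()
  radiusOK <- any(b$accepted & b$bone_id == "radius")
  matureBA <- if (assessment@sex == "male") config@matureBAMale else
    config@matureBAFemale
  if (any(short) && mean(b$bone_age[short]) > matureBA && !radiusOK) {
    if (!bypass) {
      assessment@status <- "no_radius_mature"
      assessment@finalBoneAge <- NA_real_
      return(assessment)
    }
    warned <- TRUE
  }

  assessment@status <- if (warned) "accepted_with_warning" else "accepted"
  assessment@finalBoneAge <- round(mean(b$bone_age[b$accepted]), 2)
  assessment
}

#' Run the full self-validation cascade on one image
#'
#' Composition of the two bone-level steps and the four image-level gates:
#' \code{\link{rejectByAppearance}}, then \code{\link{rejectByDeviation}},
#' then \code{\link{gateImage}}. Deterministic and idempotent: feeding an
#' accepted image's surviving bones back through the cascade rejects
#' nothing further, and the bone input order never changes the result.
#'
#' @param bones per-bone table (see \code{\link{boneTable}}) — at least
#'   one bone.
#' @param sharpness dimensionless image sharpness
#'   (\code{\link{imageSharpness}}), or \code{NA} if not measured.
#' @param sex \code{"male"} or \code{"female"}.
#' @param config a \linkS4class{ValidationConfig}.
#' @param image_id case identifier carried into the result.
#' @return An \linkS4class{ImageAssessment} with every rejection reason
#'   recorded.
#' @examples
#' b <- boneTable(boneRoster(), rep(8, 21))
#' a <- runCascade(b, sharpness = 5.5, sex = "female")
#' finalBoneAge(a)   # 8
#' @export
runCascade <- function(bones, sharpness = NA_real_, sex = c("male", "female"),
                       config = ValidationConfig(), image_id = NA_character_) {
  sex <- match.arg(sex)
  if (!nrow(bones)) stop("at least one bone is required")
  bones <- .canonicalBoneOrder(bones)
  bones <- rejectByAppearance(bones, config)
  if (any(bones$accepted))
    bones <- rejectByDeviation(bones, config)$bones
  a <- new("ImageAssessment", imageId = as.character(image_id), sex = sex,
           bones = bones, sharpness = as.numeric(sharpness),
           status = "accepted", finalBoneAge = 0)
  a <- gateImage(a, config)
  validObject(a)
  a
}
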