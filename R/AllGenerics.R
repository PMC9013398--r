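#' Per-bone assessment table of an image
#'
#' Accessor for the per-bone table of an \linkS4class{ImageAssessment}:
#' one row per tubular bone with its identifier, estimated bone age,
#' appearance score, acceptance flag and rejection reason.
#'
#' @param x an \linkS4class{ImageAssessment}.
#' @return A \code{data.frame} with columns \code{bone_id},
#'   \code{bone_age}, \code{appearance_score}, \code{accepted},
#'   \code{rejection_reason}.
#' @export
setGeneric("bones", function(x) standardGeneric("bones"))

#' Gate status of an assessment
#'
#' @param x an \linkS4class{ImageAssessment}.
#' @return One of \code{"accepted"}, \code{"hand_not_found"},
#'   \code{"too_sharp"}, \code{"too_blurred"}, \code{"no_radius_mature"},
#'   \code{"accepted_with_warning"}.
#' @export
setGeneric("imageStatus", function(x) standardGeneric("imageStatus"))

#' Final bone age of an accepted image
#'
#' @param x an \linkS4class{ImageAssessment}.
#' @return Bone age in years (mean over accepted tubular bones, 2
#'   decimals), or \code{NA} if the image was rejected.
#' @export
setGeneric("finalBoneAge", function(x) standardGeneric("finalBoneAge"))

#' Number of bones that survived validation
#'
#' @param x an \linkS4class{ImageAssessment}.
#' @return Integer count of accepted bones.
#' @export
setGeneric("acceptedBoneCount", function(x) standardGeneric("acceptedBoneCount"))

#' @rdname bones
#' @aliases bones,ImageAssessment-method
setMethod("bones", "ImageAssessment", function(x) x@bones)

#' @rdname imageStatus
#' @aliases imageStatus,ImageAssessment-method
setMethod("imageStatus", "ImageAssessment", function(x) x@status)

#' @rdname finalBoneAge
#' @aliases finalBoneAge,ImageAssessment-method
setMethod("finalBoneAge", "ImageAssessment", function(x) x@finalBoneAge)

#' @rdname acceptedBoneCount
#' @aliases acceptedBoneCount,ImageAssessment-method
setMethod("acceptedBoneCount", "ImageAssessment",
          function(x) sum(x@bones$accepted))
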