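# CSV/YAML/JSON surfaces: case tables in, per-image JSON/CSV reports out,
# YAML configuration, and a reproducibility manifest.

#' Read a per-bone case table
#'
#' CSV with one row per bone and columns \code{image_id}, \code{sex},
#' \code{bone_id}, \code{bone_age_y}, \code{appearance_score}, plus an
#' optional per-image \code{sharpness} column (constant within an image).
#' Rows are validated strictly; violations are reported with their row
#' number and column.
#'
#' @param path CSV file path, or a \code{data.frame} in the same schema.
#' @return A list with one element per image:
#'   \code{list(image_id, sex, sharpness, bones = <bone table>)}.
#' @export
readCaseTable <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "sex", "bone_id", "bone_age_y", "appearance_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("case table is missing column(s): ", paste(miss, collapse = ", "))

  bad <- function(rows, col, why)
    stop(sprintf("case table row %s, column '%s': %s",
                 paste(rows, collapse = ","), col, why))
  if (!is.numeric(df$bone_age_y))
    df$bone_age_y <- suppressWarnings(as.numeric(df$bone_age_y))
  if (anyNA(df$bone_age_y) || any(!is.finite(df$bone_age_y)))
    bad(which(!is.finite(df$bone_age_y)), "bone_age_y",
        "must be a finite number")
  if (any(df$bone_age_y < 0))
    bad(which(df$bone_age_y < 0), "bone_age_y", "must be >= 0")
  unknown <- !df$bone_id %in% boneRoster()
  if (any(unknown))
    bad(which(unknown), "bone_id", "not in the 21-bone tubular roster")
  if (!all(df$sex %in% c("male", "female")))
    bad(which(!df$sex %in% c("male", "female")), "sex",
        "must be 'male' or 'female'")
  sc <- suppressWarnings(as.numeric(df$appearance_score))
  if (anyNA(sc) || any(sc < 0 | sc > 1))
    bad(which(is.na(sc) | sc < 0 | sc > 1), "appearance_score",
        "must lie in [0, 1]")
  df$appearance_score <- sc

  out <- lapply(split(df, df$image_id), function(g) {
    if (anyDuplicated(g$bone_id))
      stop(sprintf("image '%s': duplicate bone_id '%s'", g$image_id[1],
                   g$bone_id[anyDuplicated(g$bone_id)]))
    if (length(unique(g$sex)) != 1L)
      stop(sprintf("image '%s': inconsistent sex", g$image_id[1]))
    sharp <- NA_real_
    if ("sharpness" %in% names(g)) {
      s <- unique(g$sharpness[is.finite(g$sharpness)])
      if (length(s) > 1L)
        stop(sprintf("image '%s': inconsistent sharpness", g$image_id[1]))
      if (length(s)) sharp <- s
    }
    list(image_id = g$image_id[1], sex = g$sex[1], sharpness = sharp,
         bones = boneTable(g$bone_id, g$bone_age_y, g$appearance_score))
  })
  out[order(names(out))]
}

#' Validate every case of a case table
#'
#' Runs \code{\link{runCascade}} over each image of a case table.
#'
#' @param cases path/data.frame accepted by \code{\link{readCaseTable}},
#'   or its return value.
#' @param config a \linkS4class{ValidationConfig}.
#' @return Named list of \linkS4class{ImageAssessment} objects.
#' @export
validateCases <- function(cases, config = ValidationConfig()) {
  if (is.character(cases) || is.data.frame(cases))
    cases <- readCaseTable(cases)
  lapply(cases, function(cs)
    runCascade(cs$bones, sharpness = cs$sharpness, sex = cs$sex,
               config = config, image_id = cs$image_id))
}

.assessmentRecord <- function(a) {
  b <- a@bones
  list(image_id = a@imageId,
       status = a@status,
       final_bone_age_y = if (is.finite(a@finalBoneAge)) a@finalBoneAge else
         NULL,
       sharpness = if (is.finite(a@sharpness)) a@sharpness else NULL,
       accepted_bone_count = sum(b$accepted),
       bones = lapply(seq_len(nrow(b)), function(i)
         list(bone_id = b$bone_id[i],
              bone_age_y = b$bone_age[i],
              accepted = b$accepted[i],
              rejection_reason = b$rejection_reason[i])))
}

#' Write validation reports
#'
#' Serialises assessments to JSON (one object per image, deterministic key
#' order) or to a flat per-bone CSV. JSON reports round-trip through
#' \code{\link{readReport}} without loss.
#'
#' @param assessments list of \linkS4class{ImageAssessment} (or a single
#'   one).
#' @param path output file.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(assessments, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is(assessments, "ImageAssessment")) assessments <- list(assessments)
  if (format == "json") {
    recs <- lapply(assessments, .assessmentRecord)
    names(recs) <- NULL
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(assessments, function(a) {
      b <- a@bones
      data.frame(image_id = a@imageId, status = a@status,
                 final_bone_age_y = a@finalBoneAge,
                 sharpness = a@sharpness,
                 accepted_bone_count = sum(b$accepted),
                 bone_id = b$bone_id, bone_age_y = b$bone_age,
                 accepted = b$accepted,
                 rejection_reason = b$rejection_reason,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON validation report
#'
#' @param path JSON file written by \code{\link{writeReport}}.
#' @return List of per-image records (\code{image_id}, \code{status},
#'   \code{final_bone_age_y}, \code{accepted_bone_count}, \code{bones}).
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Read a ValidationConfig from YAML
#'
#' YAML keys use the snake_case field names
#' (\code{dev_threshold_high}, \code{dev_threshold_birth}, \code{ramp_end},
#' \code{min_bones}, \code{sharp_max}, \code{sharp_min},
#' \code{mature_ba_male}, \code{mature_ba_female},
#' \code{appearance_threshold}, \code{bypass_quality_gates},
#' \code{deviation_mode}); absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return A \linkS4class{ValidationConfig}.
#' @export
readValidationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  map <- c(dev_threshold_high = "devThresholdHigh",
           dev_threshold_birth = "devThresholdBirth",
           ramp_end = "rampEnd", min_bones = "minBones",
           sharp_max = "sharpMax", sharp_min = "sharpMin",
           mature_ba_male = "matureBAMale", mature_ba_female = "matureBAFemale",
           appearance_threshold = "appearanceThreshold",
           bypass_quality_gates = "bypassQualityGates",
           deviation_mode = "deviationMode")
  unknown <- setdiff(names(y), names(map))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- y
  names(args) <- map[names(y)]
  do.call(ValidationConfig, args)
}

#' Write a ValidationConfig to YAML
#'
#' @param config a \linkS4class{ValidationConfig}.
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
writeValidationConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

.configAsList <- function(config) {
  list(dev_threshold_high = config@devThresholdHigh,
       dev_threshold_birth = config@devThresholdBirth,
       ramp_end = config@rampEnd,
       min_bones = config@minBones,
       sharp_max = config@sharpMax,
       sharp_min = config@sharpMin,
       mature_ba_male = config@matureBAMale,
       mature_ba_female = config@matureBAFemale,
       appearance_threshold = config@appearanceThreshold,
       bypass_quality_gates = config@bypassQualityGates,
       deviation_mode = config@deviationMode)
}

#' Reproducibility manifest of a run
#'
#' Captures the package version, an MD5 hash of the configuration, MD5
#' hashes of the input files, and the seed. The manifest hash covers
#' everything except the timestamp, so identical inputs, config and seed
#' give an identical hash.
#'
#' @param config a \linkS4class{ValidationConfig}.
#' @param input_paths character vector of input files.
#' @param seed integer seed of the run (NA if the run is deterministic).
#' @return List with \code{tool_version}, \code{config_hash},
#'   \code{input_hashes}, \code{seed}, \code{timestamp},
#'   \code{manifest_hash}.
#' @export
runManifest <- function(config = ValidationConfig(), input_paths = character(),
                        seed = NA_integer_) {
  hashOf <- function(text) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeLines(text, f)
    unname(tools::md5sum(f))
  }
  cfgHash <- hashOf(yaml::as.yaml(.configAsList(config)))
  inHashes <- if (length(input_paths)) unname(tools::md5sum(input_paths)) else
    character()
  ver <- as.character(utils::packageVersion("BoneAgeQC"))
  manifest_hash <- hashOf(paste(c(ver, cfgHash, inHashes, seed),
                                collapse = "\n"))
  list(tool_version = ver, config_hash = cfgHash,
       input_hashes = stats::setNames(inHashes, input_paths),
       seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
       manifest_hash = manifest_hash)
}
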