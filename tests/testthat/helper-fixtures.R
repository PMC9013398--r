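# Shared fixtures: small bone tables and the brute-force rule-B oracle.

cleanBones <- function(ba = 10, n = 21) {
  boneTable(boneRoster()[seq_len(n)], rep(ba, n))
}

# Exhaustive enumeration of the accept/reject subsets that are fixed
# points of the deviation rule: every member of the subset lies within the
# ramp threshold of the leave-one-out mean (2-bone subsets are fixed
# points by convention, deviation being undefined below 3 bones).
deviationFixedPoints <- function(ages, config = ValidationConfig()) {
  n <- length(ages)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) next
    if (length(idx) == 2) { out[[length(out) + 1]] <- idx; next }
    a <- ages[idx]
    loo <- (sum(a) - a) / (length(a) - 1)
    ok <- all(abs(a - loo) <= deviationThreshold(loo, config))
    if (ok) out[[length(out) + 1]] <- idx
  }
  out
}

# Case table CSV for IO tests: one image, all 21 bones.
writeCaseCSV <- function(path, image_id = "img1", sex = "female",
                         ba = rep(9, 21), score = rep(0.1, 21),
                         sharpness = 6) {
  df <- data.frame(image_id = image_id, sex = sex,
                   bone_id = boneRoster(), bone_age_y = ba,
                   appearance_score = score, sharpness = sharpness)
  write.csv(df, path, row.names = FALSE)
  path
}
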