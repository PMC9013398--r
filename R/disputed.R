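# Disputed-case workflow: cases where the automated and manual ratings
# disagree by more than a threshold are rerated by a blinded panel; the
# panel mean serves as the reference against which each method's distance
# and grave-error count is measured.

#' Disputed-case analysis
#'
#' Selects the disputed cases — \code{|auto - manual| >
#' dispute_threshold} (strict) — takes the mean of each disputed case's
#' rerating panel as the reference, and counts (i) the cases where the
#' automated rating is strictly closer to the reference than the manual
#' one and (ii) the grave errors per method, i.e. ratings more than
#' \code{grave_threshold} from the reference. The analysis treats both
#' methods symmetrically: swapping the auto and manual columns swaps the
#' corresponding output counts.
#'
#' @param auto automated ratings, years.
#' @param manual original manual ratings, years.
#' @param panel rerating panel, a matrix/data.frame (cases x raters,
#'   typically 3). Rows may be \code{NA} for non-disputed cases; a missing
#'   panel row on a disputed case is an error.
#' @param dispute_threshold years; default 1.8.
#' @param grave_threshold years; default 1.5.
#' @return A \linkS4class{DisputedAnalysis}.
#' @examples
#' pan <- rbind(c(10.1, 9.9, 10.0), c(10.1, 9.9, 10.0), c(10, 10, 10))
#' disputedCaseAnalysis(c(10, 12.5, 10), c(12.5, 10, 10.5), pan)
#' @export
disputedCaseAnalysis <- function(auto, manual, panel,
                                 dispute_threshold = 1.8,
                                 grave_threshold = 1.5) {
  stopifnot(length(auto) == length(manual), dispute_threshold >= 0,
            grave_threshold >= 0)
  panel <- as.matrix(panel)
  if (nrow(panel) != length(auto))
    stop("panel must have one row per case")
  disp <- abs(auto - manual) > dispute_threshold
  idx <- which(disp)
  if (any(!stats::complete.cases(panel[idx, , drop = FALSE])))
    stop("missing rerating panel for a disputed case")
  ref <- rowMeans(panel[idx, , drop = FALSE])
  dAuto <- abs(auto[idx] - ref)
  dMan <- abs(manual[idx] - ref)
  new("DisputedAnalysis",
      disputeThreshold = dispute_threshold,
      graveThreshold = grave_threshold,
      nDisputed = length(idx),
      nAutoCloser = sum(dAuto < dMan),
      nManualGrave = sum(dMan > grave_threshold),
      nAutoGrave = sum(dAuto > grave_threshold))
}

#' Simulate the disputed-case rerating workflow
#'
#' Convenience wrapper: simulates a cohort under \code{spec} (one original
#' manual rating), draws a blinded \code{n_rerate}-rater panel for every
#' case (single-rater SD \code{sigmaRater}, no contamination — rerating is
#' done carefully), and runs \code{\link{disputedCaseAnalysis}}.
#'
#' @param spec a \linkS4class{SimulationSpec} with \code{nRaters = 1}.
#' @param n_rerate rerating panel size (default 3).
#' @param dispute_threshold,grave_threshold years.
#' @return A \linkS4class{DisputedAnalysis}.
#' @export
simulateDisputedWorkflow <- function(spec, n_rerate = 3L,
                                     dispute_threshold = 1.8,
                                     grave_threshold = 1.5) {
  coh <- simulateCohort(spec)
  panel <- .withSeed(spec@seed + 1L, {
    matrix(stats::rnorm(nrow(coh) * n_rerate, 0, spec@sigmaRater),
           nrow(coh), n_rerate) + coh$true_ba
  })
  disputedCaseAnalysis(coh$auto_ba, coh$rating_1, panel,
                       dispute_threshold, grave_threshold)
}
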