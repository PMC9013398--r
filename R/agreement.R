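# Accuracy and agreement statistics: RMS/MAD, multi-rater reference
# construction, quadrature decomposition of the observed error into method
# accuracy and rater variability, variance fractions, single-case
# sensitivity of RMS vs MAD, and Bland-Altman agreement analysis.

#' Root-mean-square error
#'
#' @param errors rating errors in years.
#' @return RMS in years.
#' @examples
#' rmsError(c(1, 0, 0, 0))   # 0.5
#' @export
rmsError <- function(errors) {
  if (!length(errors)) stop("empty error vector")
  sqrt(mean(errors^2))
}

#' Mean absolute deviation, in months
#'
#' The MAD convention of the RSNA bone age benchmark: the mean absolute
#' error converted from years to months.
#'
#' @param errors rating errors in years.
#' @return MAD in months (12 x mean absolute error in years).
#' @examples
#' madMonths(c(0.5, -0.5))   # 6
#' @export
madMonths <- function(errors) {
  if (!length(errors)) stop("empty error vector")
  12 * mean(abs(errors))
}

#' Reference rating from a rater panel
#'
#' The reference rating is the arithmetic mean of the panel's independent
#' manual ratings — a proxy for the true bone age.
#'
#' @param ratings numeric vector (one case) or matrix (cases x raters).
#' @return Mean rating per case, years.
#' @export
panelReference <- function(ratings) {
  if (is.matrix(ratings) || is.data.frame(ratings)) {
    if (!ncol(ratings)) stop("panel must contain at least one rater")
    rowMeans(as.matrix(ratings))
  } else {
    if (!length(ratings)) stop("panel must contain at least one rater")
    mean(ratings)
  }
}

#' SD of a k-rater reference about the true rating
#'
#' Averaging k independent ratings with single-rater SD \code{sigma_rater}
#' leaves a residual reference error of \code{sigma_rater / sqrt(k)}.
#'
#' @param sigma_rater single-rater SD, years.
#' @param k panel size (>= 1).
#' @return Reference error SD, years.
#' @examples
#' referenceErrorSD(0.68, 6)   # 0.278
#' @export
referenceErrorSD <- function(sigma_rater, k) {
  stopifnot(sigma_rater >= 0)
  if (k < 1) stop("k must be >= 1")
  sigma_rater / sqrt(k)
}

#' True accuracy by quadrature subtraction
#'
#' With independent additive errors, the observed RMS against an imperfect
#' reference overstates the method's error; the RMS about the \emph{true}
#' rating is recovered as \code{sqrt(observed_rms^2 - reference_error^2)}.
#'
#' @param observed_rms RMS against the reference, years.
#' @param reference_error RMS error of the reference itself, years.
#' @return True accuracy, years.
#' @examples
#' trueAccuracy(0.45, 0.31)   # 0.33 at 2 d.p.
#' @export
trueAccuracy <- function(observed_rms, reference_error) {
  stopifnot(observed_rms >= 0, reference_error >= 0)
  if (observed_rms < reference_error)
    stop("decomposition infeasible: observed RMS is below the reference error")
  sqrt(observed_rms^2 - reference_error^2)
}

#' Single-rater variability by quadrature subtraction
#'
#' The SD of a single manual rating about truth, given the observed RMS of
#' the method against single ratings and the method's own true accuracy:
#' \code{sqrt(observed_rms^2 - true_accuracy^2)}.
#'
#' @param observed_rms RMS against single manual ratings, years.
#' @param true_accuracy method RMS about truth, years.
#' @return Single-rater SD, years.
#' @examples
#' raterVariability(0.62, 0.33)   # 0.52 at 2 d.p.
#' @export
raterVariability <- function(observed_rms, true_accuracy) {
  stopifnot(observed_rms >= 0, true_accuracy >= 0)
  if (observed_rms < true_accuracy)
    stop("decomposition infeasible: observed RMS is below the true accuracy")
  sqrt(observed_rms^2 - true_accuracy^2)
}

#' Error variance as a fraction of the natural bone-age variance
#'
#' Healthy children at a fixed age scatter with an SD of about 1 y in bone
#' age (above ~7 y), so an error SD is best judged against that natural
#' variance: \code{100 error_sd^2 / natural_sd^2} percent.
#'
#' @param error_sd error SD, years.
#' @param natural_sd natural bone-age SD, years (default 1).
#' @return Percent of the natural variance.
#' @examples
#' varianceFraction(0.58)   # 34 to the nearest percent
#' varianceFraction(0.33)   # 11
#' @export
varianceFraction <- function(error_sd, natural_sd = 1) {
  stopifnot(natural_sd > 0, error_sd >= 0)
  100 * error_sd^2 / natural_sd^2
}

#' Sensitivity of RMS and MAD to a single case's error
#'
#' How much the cohort RMS and MAD move when one case's absolute error
#' changes from \code{err_old} to \code{err_new} months: MAD changes
#' linearly, \code{100 (err_new - err_old) / (n mad)} percent, while RMS
#' changes as \code{100 (sqrt(rms^2 + (err_new^2 - err_old^2) / (144 n)) /
#' rms - 1)} percent. The RMS reacts far more strongly to single gross
#' errors, which is why it is preferred over MAD for safety-oriented
#' accuracy reporting.
#'
#' @param n cohort size.
#' @param rms cohort RMS, years.
#' @param mad cohort MAD, months.
#' @param err_old,err_new the case's absolute error before/after, months.
#' @return \code{list(delta_rms_pct, delta_mad_pct)}.
#' @examples
#' singleCaseSensitivity(200, 0.45, 4.1, 4, 24)  # RMS +4.7%, MAD +2.4%
#' @export
singleCaseSensitivity <- function(n, rms, mad, err_old, err_new) {
  stopifnot(n >= 1, rms >= 0, mad >= 0, err_old >= 0, err_new >= 0)
  if (rms == 0 && err_new != err_old)
    stop("relative RMS change undefined for rms = 0")
  delta_mad <- 100 * (err_new - err_old) / (n * mad)
  delta_rms <- if (err_new == err_old) 0 else
    100 * (sqrt(rms^2 + (err_new^2 - err_old^2) / (144 * n)) / rms - 1)
  list(delta_rms_pct = delta_rms, delta_mad_pct = delta_mad)
}

#' Bland-Altman agreement analysis
#'
#' Per-case difference (auto - manual) against the per-case mean of the
#' two methods, with the bias (mean difference) and 95 percent limits of
#' agreement (bias +/- 1.96 SD of the differences).
#'
#' @param auto automated ratings, years.
#' @param manual manual ratings, years (single rating or panel mean).
#' @return \code{list(table = data.frame(mean, diff), bias, loa)}.
#' @examples
#' blandAltman(c(10, 8), c(9, 9))   # bias 0
#' @export
blandAltman <- function(auto, manual) {
  stopifnot(length(auto) == length(manual))
  if (length(auto) < 2L) stop("Bland-Altman needs at least 2 pairs")
  if (!all(is.finite(auto)) || !all(is.finite(manual)))
    stop("ratings must be finite")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  list(table = data.frame(mean = (auto + manual) / 2, diff = d),
       bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s))
}

#' Full agreement report for a paired-rating table
#'
#' Computes RMS (years) and MAD (months) of auto - reference, the
#' Bland-Altman bias and limits, and — when the reference's own error is
#' known or estimable — the quadrature-decomposed true accuracy and its
#' variance fraction. The reference error can be supplied directly
#' (\code{reference_error}), or estimated from a rater panel as the pooled
#' within-case rater SD divided by \code{sqrt(k)}.
#'
#' @param auto automated ratings, years.
#' @param manual single manual ratings (vector) or a panel (matrix, cases
#'   x raters); the reference is the panel mean.
#' @param reference_error RMS error of the reference about truth, years;
#'   overrides the panel estimate when given.
#' @param natural_sd natural bone-age SD for the variance fraction.
#' @return An \linkS4class{AgreementReport}.
#' @examples
#' coh <- simulateCohort(SimulationSpec(nCases = 500, nRaters = 3,
#'                                      grossErrorRate = 0, seed = 3))
#' agreementReport(coh$auto_ba,
#'                 as.matrix(coh[paste0("rating_", 1:3)]))
#' @export
agreementReport <- function(auto, manual, reference_error = NULL,
                            natural_sd = 1) {
  panel <- is.matrix(manual) || is.data.frame(manual)
  ref <- if (panel) panelReference(manual) else as.numeric(manual)
  stopifnot(length(auto) == length(ref))
  err <- auto - ref
  ba <- blandAltman(auto, ref)

  raterSD <- NA_real_
  if (panel && ncol(manual) >= 2L) {
    m <- as.matrix(manual)
    raterSD <- sqrt(mean(apply(m, 1, stats::var)))
    if (is.null(reference_error))
      reference_error <- referenceErrorSD(raterSD, ncol(m))
  }
  refErr <- if (is.null(reference_error)) NA_real_ else reference_error
  tacc <- if (is.finite(refErr)) trueAccuracy(rmsError(err), refErr) else
    NA_real_
  vfrac <- if (is.finite(tacc)) varianceFraction(tacc, natural_sd) else
    NA_real_

  new("AgreementReport", n = length(err), rms = rmsError(err),
      madMonths = madMonths(err), refError = refErr, trueAccuracy = tacc,
      raterSD = raterSD, varianceFraction = vfrac, bias = ba$bias,
      loa = ba$loa, table = ba$table)
}

#' Bootstrap decomposition of a panel-rated cohort
#'
#' Estimates the method's true accuracy from a panel-rated cohort (RMS
#' against the panel mean, quadrature-corrected by the panel-estimated
#' reference error) and attaches a case-resampling bootstrap standard
#' error.
#'
#' @param auto automated ratings, years.
#' @param panel matrix of manual ratings, cases x raters (k >= 2).
#' @param B bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return \code{list(true_accuracy, se, observed_rms, reference_error,
#'   rater_sd)}.
#' @export
decomposeAccuracy <- function(auto, panel, B = 200, seed = 1) {
  panel <- as.matrix(panel)
  stopifnot(length(auto) == nrow(panel), ncol(panel) >= 2L)
  est <- function(idx) {
    a <- auto[idx]; p <- panel[idx, , drop = FALSE]
    obs <- rmsError(a - rowMeans(p))
    rsd <- sqrt(mean(apply(p, 1, stats::var)))
    refe <- rsd / sqrt(ncol(p))
    if (obs < refe) return(NA_real_)
    sqrt(obs^2 - refe^2)
  }
  n <- length(auto)
  point <- est(seq_len(n))
  boots <- .withSeed(seed, vapply(seq_len(B), function(b)
    est(sample.int(n, n, replace = TRUE)), numeric(1)))
  rsd <- sqrt(mean(apply(panel, 1, stats::var)))
  list(true_accuracy = point,
       se = stats::sd(boots, na.rm = TRUE),
       observed_rms = rmsError(auto - rowMeans(panel)),
       reference_error = rsd / sqrt(ncol(panel)),
       rater_sd = rsd)
}

#' Percentage and fold-ratio report rounding
#'
#' The reporting conventions for rejection/dispute rates (percent to 1
#' decimal) and grave-error ratios (fold change to the nearest integer).
#'
#' @param count,total numerator and denominator counts.
#' @return \code{percentRate}: percent rounded to 1 decimal.
#' @examples
#' percentRate(59, 14036)    # 0.4
#' percentRate(121, 8250)    # 1.5
#' foldRatio(72, 6)          # 12
#' @export
percentRate <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, 1)
}

#' @rdname percentRate
#' @param a,b numerator and denominator of the fold ratio.
#' @return \code{foldRatio}: \code{a / b} rounded to the nearest integer.
#' @export
foldRatio <- function(a, b) {
  stopifnot(b > 0)
  round(a / b)
}
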