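#' Sensitivity parameters indexing one missingness scenario
#'
#' A scenario is indexed by four known constants: `or1`, the assumed odds
#' ratio between survey missingness and self-reported tobacco use; `or2`,
#' the assumed odds ratio between urine missingness and urine-verified
#' failure among self-reported abstainers; `lambda`, the factor by which
#' the provided:missing urine odds among survey non-respondents differ
#' from respondents; and `eta`, the factor by which the verified-abstinent
#' odds among would-be urine samples differ from observed ones.
#'
#' `or1 = or2 = 1` is the missing-at-random scenario; `or1 = or2 = Inf`
#' is the conventional "missing = smoking" rule.  `Inf` is a first-class
#' value for both odds ratios (spelled `"inf"` in configs and CSVs).
#'
#' @param or1,or2 Positive odds ratios, `Inf` allowed.
#' @param lambda,eta Positive scaling factors.
#' @return An object of class `sensitivity_params`.
#' @export
#' @examples
#' sensitivity_params(or1 = 3, or2 = 2)
sensitivity_params <- function(or1 = 1, or2 = 1, lambda = 1, eta = 1) {
  for (nm in c("or1", "or2", "lambda", "eta")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0)
      stop(nm, " must be a single positive number (Inf allowed for or1/or2)")
  }
  if (is.infinite(lambda) || is.infinite(eta))
    stop("lambda and eta must be finite")
  structure(list(or1 = or1, or2 = or2, lambda = lambda, eta = eta),
            class = "sensitivity_params")
}

#' @export
print.sensitivity_params <- function(x, ...) {
  cat(sprintf("sensitivity scenario: OR1 = %s, OR2 = %s, lambda = %g, eta = %g\n",
              format(x$or1), format(x$or2), x$lambda, x$eta))
  invisible(x)
}

# Allocation fraction pi = OR*Odds/(1 + OR*Odds) with Odds = fail/abst,
# resolving degenerate observed cells: no observed abstainers -> 1 (odds
# infinite, any OR); no observed failures -> 0, even under OR = Inf, so that
# pi stays continuous in OR for fixed data; both zero -> NA (caller decides
# whether anything needed allocating).
alloc_fraction <- function(or, fail_obs, abst_obs) {
  if (fail_obs <= 0 && abst_obs <= 0) return(NA_real_)
  if (abst_obs <= 0) return(1)
  if (fail_obs <= 0) return(0)
  if (is.infinite(or)) return(1)
  odds <- fail_obs / abst_obs
  (or * odds) / (1 + or * odds)
}

as_arm <- function(arm) {
  if (is.data.frame(arm)) {
    stopifnot(nrow(arm) == 1)
    arm <- as.list(arm)
  }
  arm
}

#' Stage 1: impute self-report outcomes for survey non-respondents
#'
#' Allocates an arm's `survey_missing` pool into imputed abstainers (`n21`)
#' and imputed failures (`n22`) so that the odds of tobacco use among
#' non-respondents equal `or1` times the observed odds among respondents:
#' `pi = or1 * Odds / (1 + or1 * Odds)` with `Odds = sr_failure /
#' sr_abstinent`, `n22 = pi * survey_missing`, `n21 = survey_missing - n22`.
#' At `or1 = Inf` every non-respondent is counted a failure (`pi = 1`,
#' missing = smoking); at `or1 = 1` the imputed arm rate equals the
#' complete-case rate (missing at random).
#'
#' Imputed counts are fractional and never rounded.
#'
#' @param arm One arm's counts ([arm_counts()] row or equivalent list).
#' @param or1 Assumed missingness/tobacco-use odds ratio; positive, `Inf`
#'   allowed.
#' @return A `stage1_result` list: `n21`, `n22`, `pi`,
#'   `sr_abstinent_total` (`sr_abstinent + n21`), `sr_failure_total`.
#' @export
#' @examples
#' tx2 <- arm_counts("Tx2", 296, 59, 170, 67, 34, 6, 19)
#' impute_stage1(tx2, or1 = 1)   # n22 = 67 * 170/229
impute_stage1 <- function(arm, or1) {
  arm <- as_arm(arm)
  if (!is.numeric(or1) || length(or1) != 1 || is.na(or1) || or1 <= 0)
    stop("or1 must be a single positive number (Inf allowed)")
  n2 <- arm$survey_missing
  pi <- alloc_fraction(or1, arm$sr_failure, arm$sr_abstinent)
  if (n2 > 0 && is.na(pi))
    stop("arm ", arm$arm, ": no observed survey outcomes (sr_abstinent = ",
         "sr_failure = 0) to anchor the imputation of ", n2,
         " non-respondents")
  if (n2 == 0) {
    n22 <- 0
    n21 <- 0
  } else {
    n22 <- pi * n2
    n21 <- n2 - n22
  }
  structure(list(n21 = n21, n22 = n22, pi = pi,
                 sr_abstinent_total = arm$sr_abstinent + n21,
                 sr_failure_total = arm$sr_failure + n22),
            class = "stage1_result")
}
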