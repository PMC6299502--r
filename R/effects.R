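# Pearson chi-square on a 2x2 table [(a, n1-a); (c, n2-c)], no continuity
# correction; cells may be fractional (imputed counts).
chisq_2x2 <- function(a, n1, c, n2) {
  a <- as.numeric(a); n1 <- as.numeric(n1)
  c <- as.numeric(c); n2 <- as.numeric(n2)
  b <- n1 - a
  d <- n2 - c
  m1 <- a + c
  m2 <- b + d
  if (n1 <= 0 || n2 <= 0 || m1 <= 0 || m2 <= 0)
    stop("chi-square undefined: a margin of the 2x2 table is zero")
  n <- n1 + n2
  chi2 <- n * (a * d - b * c)^2 / (n1 * n2 * m1 * m2)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compare two pooled abstinence counts
#'
#' Computes rates, the odds ratio for abstinence (exposed vs control), and
#' an uncorrected Pearson chi-square test with its two-sided p-value from
#' the chi-square(1) upper tail.  Counts may be fractional (imputed).
#'
#' @param exposed,control Numeric vectors `c(abstinent, total)`.
#' @param name Contrast label.
#' @return A one-row `contrast_result` data frame: `contrast`,
#'   `exposed_abstinent`, `exposed_total`, `control_abstinent`,
#'   `control_total`, `exposed_rate`, `control_rate`, `odds_ratio`, `chi2`,
#'   `p_value`.
#' @export
#' @examples
#' estimate_contrast(c(138, 464), c(126, 517), "counseling")  # p ~ .058
estimate_contrast <- function(exposed, control, name = "contrast") {
  a <- exposed[[1]]; n1 <- exposed[[2]]
  c_ <- control[[1]]; n2 <- control[[2]]
  stopifnot(n1 > 0, n2 > 0, a >= 0, a <= n1, c_ >= 0, c_ <= n2)
  test <- chisq_2x2(a, n1, c_, n2)
  res <- data.frame(contrast = name,
                    exposed_abstinent = a, exposed_total = n1,
                    control_abstinent = c_, control_total = n2,
                    exposed_rate = a / n1, control_rate = c_ / n2,
                    odds_ratio = (a / (n1 - a)) / (c_ / (n2 - c_)),
                    chi2 = test$chi2, p_value = test$p_value,
                    stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Pool imputed arm totals for one outcome
#'
#' @param imputed An [impute_trial()] result.
#' @param pool Character vector of arm labels.
#' @param outcome `"self_report"` (numerator `sr_abstinent_total`) or
#'   `"urine_verified"` (numerator `verified_abstinent_total`);
#'   denominator is the pooled randomized total either way.
#' @return Numeric vector `c(abstinent, total)`.
#' @export
pool_arms <- function(imputed, pool,
                      outcome = c("self_report", "urine_verified")) {
  outcome <- match.arg(outcome)
  stopifnot(length(pool) >= 1)
  unknown <- setdiff(pool, imputed$arm)
  if (length(unknown))
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "))
  sel <- imputed[imputed$arm %in% pool, ]
  num <- if (outcome == "self_report") sum(sel$sr_abstinent_total)
         else sum(sel$verified_abstinent_total)
  c(abstinent = num, total = sum(sel$n_total))
}

contrast_from_imputed <- function(imputed, trial, outcome) {
  out <- lapply(names(trial$contrasts), function(nm) {
    ct <- trial$contrasts[[nm]]
    estimate_contrast(pool_arms(imputed, ct$exposed, outcome),
                      pool_arms(imputed, ct$control, outcome), nm)
  })
  do.call(rbind, out)
}

#' Complete-case contrast estimates
#'
#' Restricts each pool to subjects with an observed outcome: for
#' `self_report`, survey respondents (`sr_abstinent + sr_failure`) with
#' numerator `sr_abstinent`; for `urine_verified`, subjects with a urine
#' result (`urine_abstinent + urine_failure`) with numerator
#' `urine_abstinent`.
#'
#' @param trial A validated [trial_counts()] object with contrasts.
#' @param outcome Outcome scale, as in [pool_arms()].
#' @return A `contrast_result` data frame, one row per contrast.
#' @export
#' @examples
#' complete_case(enhanced_quit_win(), "self_report")  # counseling OR 1.31
complete_case <- function(trial,
                          outcome = c("self_report", "urine_verified")) {
  outcome <- match.arg(outcome)
  assert_valid_counts(trial)
  arms <- trial$arms
  cc_pool <- function(labels) {
    sel <- arms[arms$arm %in% labels, ]
    if (outcome == "self_report")
      c(sum(sel$sr_abstinent), sum(sel$sr_abstinent + sel$sr_failure))
    else
      c(sum(sel$urine_abstinent),
        sum(sel$urine_abstinent + sel$urine_failure))
  }
  out <- lapply(names(trial$contrasts), function(nm) {
    ct <- trial$contrasts[[nm]]
    estimate_contrast(cc_pool(ct$exposed), cc_pool(ct$control), nm)
  })
  do.call(rbind, out)
}
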