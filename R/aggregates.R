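#' Construct aggregated counts for one treatment arm
#'
#' An arm is summarised by seven counts: the randomized total `n`, the
#' self-report survey outcome split (abstinent / failure / survey missing),
#' and, among self-reported abstainers, the urine verification split
#' (verified abstinent / verified failure / urine missing).  Two accounting
#' identities tie them together:
#' `sr_abstinent + sr_failure + survey_missing == n_total` and
#' `urine_abstinent + urine_failure + urine_missing == sr_abstinent`.
#'
#' Urine counts may be fractional: when inadequate samples are
#' proportionally redistributed (see [redistribute_untested()]) or after
#' imputation, non-integer counts arise and are carried through unrounded.
#'
#' @param arm_label Character label, unique within a trial.
#' @param n_total Number of randomized subjects.
#' @param sr_abstinent,sr_failure,survey_missing Self-report survey counts.
#' @param urine_abstinent,urine_failure,urine_missing Urine verification
#'   counts among self-reported abstainers; may be non-integer.
#' @return A one-row data frame with the seven count columns plus `arm`.
#' @seealso [trial_counts()], [validate_counts()]
#' @export
#' @examples
#' arm_counts("Tx1", 306, 65, 194, 47, 38, 6, 21)
arm_counts <- function(arm_label, n_total, sr_abstinent, sr_failure,
                       survey_missing, urine_abstinent, urine_failure,
                       urine_missing) {
  data.frame(arm = as.character(arm_label),
             n_total = n_total,
             sr_abstinent = sr_abstinent,
             sr_failure = sr_failure,
             survey_missing = survey_missing,
             urine_abstinent = urine_abstinent,
             urine_failure = urine_failure,
             urine_missing = urine_missing,
             stringsAsFactors = FALSE)
}

#' Bundle arm counts and contrast definitions into a trial
#'
#' @param arms A data frame of per-arm counts with the columns produced by
#'   [arm_counts()] (one row per arm).
#' @param contrasts Named list of contrasts; each element is a list with
#'   character vectors `exposed` and `control` naming disjoint, nonempty
#'   subsets of the arm labels (e.g. the two factorial margins of a 2x2
#'   design).
#' @return An object of class `trial_counts`.
#' @export
trial_counts <- function(arms, contrasts = list()) {
  stopifnot(is.data.frame(arms))
  required <- c("arm", "n_total", "sr_abstinent", "sr_failure",
                "survey_missing", "urine_abstinent", "urine_failure",
                "urine_missing")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols))
    stop("arms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(arms$arm))
    stop("arm labels must be unique")
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (!all(c("exposed", "control") %in% names(ct)))
      stop("contrast '", nm, "' needs 'exposed' and 'control' arm labels")
    pools <- c(ct$exposed, ct$control)
    if (!length(ct$exposed) || !length(ct$control))
      stop("contrast '", nm, "' has an empty pool")
    if (length(intersect(ct$exposed, ct$control)))
      stop("contrast '", nm, "' pools overlap")
    unknown <- setdiff(pools, arms$arm)
    if (length(unknown))
      stop("contrast '", nm, "' references unknown arms: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(arms = arms[required], contrasts = contrasts),
            class = "trial_counts")
}

#' @export
print.trial_counts <- function(x, ...) {
  cat("Aggregated trial counts:", nrow(x$arms), "arm(s),",
      sum(x$arms$n_total), "subjects\n")
  print(x$arms, row.names = FALSE)
  if (length(x$contrasts)) {
    cat("Contrasts:\n")
    for (nm in names(x$contrasts))
      cat("  ", nm, ": {", paste(x$contrasts[[nm]]$exposed, collapse = "+"),
          "} vs {", paste(x$contrasts[[nm]]$control, collapse = "+"), "}\n",
          sep = "")
  }
  invisible(x)
}

#' Check the accounting identities of a trial's counts
#'
#' Verifies, for every arm, non-negativity and the two sum identities (the
#' survey split adds to the randomized total; the urine split adds to the
#' self-reported abstainers).  Fractional counts are compared with an
#' absolute tolerance of `tol`.
#'
#' @param trial A [trial_counts()] object.
#' @param tol Absolute tolerance for the sum identities.
#' @return Character vector of violation messages; empty when the trial is
#'   internally consistent.  Each message names the arm, the identity
#'   broken, and both sides of the equality.
#' @export
#' @examples
#' twin <- enhanced_quit_win()
#' validate_counts(twin)  # character(0)
validate_counts <- function(trial, tol = 1e-9) {
  stopifnot(inherits(trial, "trial_counts"))
  arms <- trial$arms
  out <- character(0)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    numcols <- names(a)[-1]
    neg <- numcols[unlist(a[numcols]) < 0]
    if (length(neg))
      out <- c(out, sprintf("arm %s: negative count(s): %s", a$arm,
                            paste(neg, collapse = ", ")))
    lhs <- a$sr_abstinent + a$sr_failure + a$survey_missing
    if (abs(lhs - a$n_total) > tol)
      out <- c(out, sprintf(
        "arm %s: sr_abstinent + sr_failure + survey_missing = %g but n_total = %g",
        a$arm, lhs, a$n_total))
    lhs <- a$urine_abstinent + a$urine_failure + a$urine_missing
    if (abs(lhs - a$sr_abstinent) > tol)
      out <- c(out, sprintf(
        "arm %s: urine_abstinent + urine_failure + urine_missing = %g but sr_abstinent = %g",
        a$arm, lhs, a$sr_abstinent))
  }
  out
}

assert_valid_counts <- function(trial) {
  bad <- validate_counts(trial)
  if (length(bad))
    stop("invalid trial counts:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(trial)
}

#' Redistribute untested urine samples proportionally
#'
#' Samples that were provided but could not be assayed (e.g. inadequate
#' volume) are assumed to follow the same verified-abstinent / verified-
#' failure split as the tested samples, and are reallocated to those two
#' columns before any imputation.
#'
#' @param abst_tested,fail_tested Counts of tested samples by result.
#' @param n_untested Number of provided-but-untested samples.
#' @return Numeric vector `c(abst_add, fail_add)` summing to `n_untested`.
#' @export
#' @examples
#' redistribute_untested(153, 24, 5)  # c(4.322, 0.678)
redistribute_untested <- function(abst_tested, fail_tested, n_untested) {
  stopifnot(abst_tested >= 0, fail_tested >= 0, n_untested >= 0)
  if (n_untested == 0) return(c(abst_add = 0, fail_add = 0))
  tested <- abst_tested + fail_tested
  if (tested <= 0)
    stop("cannot redistribute ", n_untested,
         " untested samples: no tested samples to take proportions from")
  abst_add <- n_untested * abst_tested / tested
  c(abst_add = abst_add, fail_add = n_untested - abst_add)
}

#' Packaged counts of the Enhanced Quit & Win trial
#'
#' Six-month aggregated outcome counts of a 2x2 factorial quit-and-win
#' cessation trial in college smokers (n = 1217): single vs. multiple
#' contests crossed with counseling vs. no counseling.  Urine counts are the
#' published per-arm values after proportional redistribution of five
#' inadequate samples.  Two factorial contrasts are predefined:
#' `counseling` (Tx2+Tx4 vs Tx1+Tx3) and `contests` (Tx3+Tx4 vs Tx1+Tx2).
#'
#' @return A [trial_counts()] object with four arms.
#' @export
#' @examples
#' enhanced_quit_win()
enhanced_quit_win <- function() {
  arms <- rbind(
    arm_counts("Tx1", 306, 65, 194, 47, 38, 6, 21),
    arm_counts("Tx2", 296, 59, 170, 67, 34, 6, 19),
    arm_counts("Tx3", 309, 61, 197, 51, 35, 6, 20),
    arm_counts("Tx4", 306, 79, 156, 71, 50, 7, 22))
  trial_counts(arms, contrasts = list(
    counseling = list(exposed = c("Tx2", "Tx4"), control = c("Tx1", "Tx3")),
    contests   = list(exposed = c("Tx3", "Tx4"), control = c("Tx1", "Tx2"))))
}

#' Read and write per-arm counts as CSV
#'
#' The CSV schema has one row per arm and header
#' `arm,n_total,sr_abstinent,sr_failure,survey_missing,urine_abstinent,urine_failure,urine_missing`.
#' Contrast definitions are not part of the file; supply them via
#' `contrasts` (run configuration).
#'
#' @param path File path.
#' @param contrasts Contrast definitions passed to [trial_counts()].
#' @param validate Raise an error if the counts break an accounting
#'   identity.
#' @return `read_counts_csv()` returns a [trial_counts()] object;
#'   `write_counts_csv()` returns `path` invisibly.
#' @export
read_counts_csv <- function(path, contrasts = list(), validate = TRUE) {
  arms <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial <- trial_counts(arms, contrasts)
  if (validate) assert_valid_counts(trial)
  trial
}

#' @rdname read_counts_csv
#' @param trial A [trial_counts()] object.
#' @export
write_counts_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_counts"))
  utils::write.csv(trial$arms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
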