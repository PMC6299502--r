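grid_row <- function(outcome, or1, or2, lambda, eta, cr) {
  cbind(data.frame(outcome = outcome, or1 = or1, or2 = or2,
                   lambda = lambda, eta = eta, stringsAsFactors = FALSE),
        cr)
}

new_grid_report <- function(rows, outcome, includes_complete_case) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "includes_complete_case") <- includes_complete_case
  class(out) <- c("grid_report", "data.frame")
  out
}

#' Sensitivity grid for the self-report abstinence outcome
#'
#' For each assumed `or1`, imputes every arm's survey non-respondents
#' (stage 1), pools arms per contrast, and estimates rates, odds ratios and
#' chi-square p-values.  A complete-case row (restricted to survey
#' respondents, `or1 = NA`) is prepended by default; at `or1 = 1` the
#' imputed rates coincide with it, and `or1 = Inf` is the missing = smoking
#' analysis.
#'
#' @param trial A validated [trial_counts()] object with contrasts.
#' @param or1_values Assumed odds ratios, in display order.
#' @param include_complete_case Prepend the complete-case analysis.
#' @return A `grid_report` data frame in long format (one row per
#'   scenario x contrast) with columns `outcome, or1, or2, lambda, eta,
#'   contrast, exposed_abstinent, exposed_total, control_abstinent,
#'   control_total, exposed_rate, control_rate, odds_ratio, chi2, p_value`.
#' @export
#' @examples
#' run_self_report_grid(enhanced_quit_win(), or1_values = c(1, Inf))
run_self_report_grid <- function(trial, or1_values = c(1, 2, 3, 4, 5, Inf),
                                 include_complete_case = TRUE) {
  assert_valid_counts(trial)
  stopifnot(length(or1_values) >= 1, all(or1_values > 0))
  if (!length(trial$contrasts))
    stop("trial has no contrast definitions")
  rows <- list()
  if (include_complete_case)
    rows[[length(rows) + 1]] <- grid_row(
      "self_report", NA_real_, NA_real_, NA_real_, NA_real_,
      complete_case(trial, "self_report"))
  for (or1 in or1_values) {
    imputed <- impute_trial(trial, sensitivity_params(or1 = or1))
    rows[[length(rows) + 1]] <- grid_row(
      "self_report", or1, NA_real_, NA_real_, NA_real_,
      contrast_from_imputed(imputed, trial, "self_report"))
  }
  new_grid_report(rows, "self_report", include_complete_case)
}

#' Sensitivity grid for the urine-verified abstinence outcome
#'
#' Runs the two-stage imputation over the Cartesian product of the assumed
#' odds ratios (`or1` outer loop, `or2` inner loop) at each combination of
#' `lambda` and `eta`, pools arms per contrast, and estimates effects.
#'
#' @inheritParams run_self_report_grid
#' @param or2_values Assumed urine-stage odds ratios.
#' @param lambda,eta Scaling factors; scalars by default, vectors to grid
#'   them as well (outermost loops).
#' @return A `grid_report` data frame in long format; see
#'   [run_self_report_grid()].
#' @export
#' @examples
#' run_verified_grid(enhanced_quit_win(), or1_values = 1, or2_values = c(1, Inf))
run_verified_grid <- function(trial, or1_values = c(1, 2, 3, 4, 5, Inf),
                              or2_values = c(1, 2, 3, 4, 5, Inf),
                              lambda = 1, eta = 1) {
  assert_valid_counts(trial)
  stopifnot(length(or1_values) >= 1, length(or2_values) >= 1,
            all(or1_values > 0), all(or2_values > 0),
            all(lambda > 0), all(eta > 0))
  if (!length(trial$contrasts))
    stop("trial has no contrast definitions")
  rows <- list()
  for (lam in lambda) for (et in eta)
    for (or1 in or1_values) for (or2 in or2_values) {
      imputed <- impute_trial(
        trial, sensitivity_params(or1 = or1, or2 = or2,
                                  lambda = lam, eta = et))
      rows[[length(rows) + 1]] <- grid_row(
        "urine_verified", or1, or2, lam, et,
        contrast_from_imputed(imputed, trial, "urine_verified"))
    }
  new_grid_report(rows, "urine_verified", FALSE)
}

fmt_or_inf <- function(x) {
  ifelse(is.na(x), "", ifelse(is.infinite(x), "inf",
                              formatC(x, format = "g")))
}

fmt_rate <- function(x) sprintf("%.1f%%", 100 * x)
fmt_p <- function(x) sub("^0\\.", ".", sprintf("%.3f", x))

#' Render a grid report in the publication's wide layout
#'
#' One row per scenario; per contrast, four columns: exposed and control
#' rates (percent, 1 decimal), abstinence odds ratio (2 decimals) and
#' chi-square p-value (3 decimals, no leading zero).
#'
#' @param report A `grid_report` from [run_self_report_grid()] or
#'   [run_verified_grid()].
#' @return A character data frame ready for printing.
#' @export
format_grid <- function(report) {
  stopifnot(inherits(report, "grid_report"))
  key <- paste(report$or1, report$or2, report$lambda, report$eta)
  rows <- lapply(unique(key), function(k) {
    sub <- report[key == k, ]
    lab <- if (is.na(sub$or1[1])) c(OR1 = "complete case", OR2 = "")
           else c(OR1 = fmt_or_inf(sub$or1[1]), OR2 = fmt_or_inf(sub$or2[1]))
    cells <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      stats::setNames(
        c(fmt_rate(r$exposed_rate), fmt_rate(r$control_rate),
          sprintf("%.2f", r$odds_ratio), fmt_p(r$p_value)),
        paste0(r$contrast, c(".exposed", ".control", ".OR", ".p")))
    })
    as.data.frame(as.list(c(lab, unlist(cells))), check.names = FALSE,
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(out$OR2 == "")) out$OR2 <- NULL
  out
}

#' @export
print.grid_report <- function(x, ...) {
  cat("Sensitivity grid (", attr(x, "outcome"), " outcome, ",
      length(unique(paste(x$or1, x$or2, x$lambda, x$eta))),
      " scenario(s))\n", sep = "")
  print(format_grid(x), row.names = FALSE)
  invisible(x)
}

#' Write a grid report as long-format CSV
#'
#' Infinite odds ratios are spelled `inf`; the complete-case row (if
#' present) has empty `or1`/`or2`.
#'
#' @param report A `grid_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(report, path) {
  stopifnot(inherits(report, "grid_report"))
  out <- data.frame(outcome = report$outcome,
                    or1 = fmt_or_inf(report$or1),
                    or2 = fmt_or_inf(report$or2),
                    lambda = report$lambda, eta = report$eta,
                    contrast = report$contrast,
                    exposed_rate = report$exposed_rate,
                    control_rate = report$control_rate,
                    odds_ratio = report$odds_ratio,
                    chi2 = report$chi2, p_value = report$p_value,
                    exposed_abstinent = report$exposed_abstinent,
                    exposed_total = report$exposed_total,
                    control_abstinent = report$control_abstinent,
                    control_total = report$control_total,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
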