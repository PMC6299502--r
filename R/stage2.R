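#' Stage 2a: split imputed abstainers by urine availability
#'
#' Among the `n21` survey non-respondents imputed as self-report abstainers,
#' estimates how many would have provided a urine sample (`u_imp`) versus
#' not (`v_imp`), assuming the provided:missing odds among non-respondents
#' are `lambda` times the observed odds `u_obs / v_obs` among respondents:
#' `u_imp = n21 * lambda * u_obs / (lambda * u_obs + v_obs)`.
#'
#' @param stage1 A [impute_stage1()] result for the same arm.
#' @param arm The arm's counts.
#' @param lambda Positive finite availability-odds scaling factor.
#' @return Numeric vector `c(u_imp, v_imp)` summing to `n21`.
#' @export
split_urine_availability <- function(stage1, arm, lambda = 1) {
  arm <- as_arm(arm)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0,
            is.finite(lambda))
  n21 <- stage1$n21
  u_obs <- arm$urine_abstinent + arm$urine_failure
  v_obs <- arm$urine_missing
  if (n21 == 0) return(c(u_imp = 0, v_imp = 0))
  if (u_obs <= 0 && v_obs <= 0)
    stop("arm ", arm$arm, ": no observed urine availability pattern to ",
         "scale (u_obs = v_obs = 0) while n21 = ", n21)
  u_imp <- n21 * lambda * u_obs / (lambda * u_obs + v_obs)
  c(u_imp = u_imp, v_imp = n21 - u_imp)
}

#' Stage 2b: split would-be urine samples by verification result
#'
#' Among the `u_imp` urine samples that could have been provided by imputed
#' abstainers, estimates verified-abstinent (`f11_imp`) versus verified-
#' failure (`f12_imp`) counts, assuming the verified-abstinent odds are
#' `eta` times the observed odds `f11_obs / f12_obs`:
#' `f11_imp = u_imp * eta * f11_obs / (eta * f11_obs + f12_obs)`.
#'
#' @param u_imp Imputed number of available urine samples.
#' @param f11_obs,f12_obs Observed verified-abstinent / verified-failure
#'   counts.
#' @param eta Positive finite verified-abstinence-odds scaling factor.
#' @return Numeric vector `c(f11_imp, f12_imp)` summing to `u_imp`.
#' @export
split_imputed_urine_outcomes <- function(u_imp, f11_obs, f12_obs, eta = 1) {
  stopifnot(is.numeric(eta), length(eta) == 1, eta > 0, is.finite(eta))
  if (u_imp == 0) return(c(f11_imp = 0, f12_imp = 0))
  if (f11_obs <= 0 && f12_obs <= 0)
    stop("no observed urine results (f11_obs = f12_obs = 0) to scale while ",
         "u_imp = ", u_imp)
  f11_imp <- u_imp * eta * f11_obs / (eta * f11_obs + f12_obs)
  c(f11_imp = f11_imp, f12_imp = u_imp - f11_imp)
}

#' Stage 2c: allocate all urine-missing subjects under OR2
#'
#' Splits the combined urine-missing pool `v_total` (observed plus imputed
#' unavailable samples) into verified abstainers (`f21`) and verified
#' failures (`f22`), assuming the failure odds among the urine-missing are
#' `or2` times the odds among available samples:
#' `pi_prime = or2 * Odds' / (1 + or2 * Odds')` with
#' `Odds' = f12_dot / f11_dot`, `f22 = v_total * pi_prime`.  At `or2 = Inf`
#' every urine-missing subject is a verified failure (the naive
#' treatment-failure allocation).
#'
#' @param f11_dot,f12_dot Verified-abstinent / verified-failure totals over
#'   observed plus imputed available samples.
#' @param v_total Combined urine-missing pool.
#' @param or2 Assumed urine-missingness/failure odds ratio; positive, `Inf`
#'   allowed.
#' @return List with `f21`, `f22`, `pi_prime`.
#' @export
allocate_missing_urine <- function(f11_dot, f12_dot, v_total, or2) {
  if (!is.numeric(or2) || length(or2) != 1 || is.na(or2) || or2 <= 0)
    stop("or2 must be a single positive number (Inf allowed)")
  pi_prime <- alloc_fraction(or2, f12_dot, f11_dot)
  if (v_total == 0)
    return(list(f21 = 0, f22 = 0, pi_prime = pi_prime))
  if (is.na(pi_prime))
    stop("no available urine results (f11_dot = f12_dot = 0) to anchor the ",
         "allocation of ", v_total, " urine-missing subjects")
  f22 <- v_total * pi_prime
  list(f21 = v_total - f22, f22 = f22, pi_prime = pi_prime)
}

#' Stage 2: impute urine-verified outcomes for one arm
#'
#' Composes the three stage-2 steps in fixed order — the `lambda` split of
#' imputed abstainers by urine availability, the `eta` split of would-be
#' samples by verification result, then the `or2` allocation of the entire
#' urine-missing pool — and totals verified abstinence for the arm:
#' `verified_abstinent_total = f11_dot + f21`.  Everyone not verified
#' abstinent counts as a failure in the arm-level rate, so
#' `verified_failure_total = n_total - verified_abstinent_total`.
#'
#' @param arm The arm's counts.
#' @param stage1 The arm's [impute_stage1()] result.
#' @param params A [sensitivity_params()] scenario (its `or1` is assumed to
#'   be the one `stage1` was computed under).
#' @return A `stage2_result` list with all imputed components: `u_obs`,
#'   `v_obs`, `u_imp`, `v_imp`, `f11_imp`, `f12_imp`, `f11_dot`, `f12_dot`,
#'   `v_total`, `f21`, `f22`, `pi_prime`, `verified_abstinent_total`,
#'   `verified_failure_total`.
#' @export
#' @examples
#' tx1 <- arm_counts("Tx1", 306, 65, 194, 47, 38, 6, 21)
#' s1 <- impute_stage1(tx1, or1 = 1)
#' impute_stage2(tx1, s1, sensitivity_params())  # verified total ~ 66.3
impute_stage2 <- function(arm, stage1, params) {
  arm <- as_arm(arm)
  stopifnot(inherits(params, "sensitivity_params"))
  u_obs <- arm$urine_abstinent + arm$urine_failure
  v_obs <- arm$urine_missing
  uv <- split_urine_availability(stage1, arm, params$lambda)
  fi <- split_imputed_urine_outcomes(uv[["u_imp"]], arm$urine_abstinent,
                                     arm$urine_failure, params$eta)
  f11_dot <- arm$urine_abstinent + fi[["f11_imp"]]
  f12_dot <- arm$urine_failure + fi[["f12_imp"]]
  v_total <- v_obs + uv[["v_imp"]]
  al <- allocate_missing_urine(f11_dot, f12_dot, v_total, params$or2)
  verified <- f11_dot + al$f21
  structure(list(u_obs = u_obs, v_obs = v_obs,
                 u_imp = uv[["u_imp"]], v_imp = uv[["v_imp"]],
                 f11_imp = fi[["f11_imp"]], f12_imp = fi[["f12_imp"]],
                 f11_dot = f11_dot, f12_dot = f12_dot, v_total = v_total,
                 f21 = al$f21, f22 = al$f22, pi_prime = al$pi_prime,
                 verified_abstinent_total = verified,
                 verified_failure_total = arm$n_total - verified),
            class = "stage2_result")
}

#' Run both imputation stages on every arm of a trial
#'
#' Imputation is stratified by treatment arm: each arm is imputed from its
#' own observed counts only, and pooling across arms happens afterwards in
#' the effect-estimation step.
#'
#' @param trial A validated [trial_counts()] object.
#' @param params A [sensitivity_params()] scenario.
#' @return An `imputed_trial` data frame, one row per arm, carrying the
#'   observed counts, every imputed component of both stages, and the
#'   outcome totals `sr_abstinent_total` and `verified_abstinent_total`.
#' @export
#' @examples
#' impute_trial(enhanced_quit_win(), sensitivity_params(or1 = 3, or2 = 2))
impute_trial <- function(trial, params) {
  assert_valid_counts(trial)
  stopifnot(inherits(params, "sensitivity_params"))
  rows <- lapply(seq_len(nrow(trial$arms)), function(i) {
    arm <- trial$arms[i, ]
    s1 <- impute_stage1(arm, params$or1)
    s2 <- impute_stage2(arm, s1, params)
    cbind(arm,
          data.frame(pi = s1$pi, n21 = s1$n21, n22 = s1$n22,
                     sr_abstinent_total = s1$sr_abstinent_total,
                     sr_failure_total = s1$sr_failure_total),
          as.data.frame(unclass(s2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("imputed_trial", "data.frame")
  out
}
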