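tx1 <- arm_counts("Tx1", 306, 65, 194, 47, 38, 6, 21)

test_that("urine availability splits by the lambda-scaled observed odds", {
  s1 <- impute_stage1(tx1, or1 = 1)        # n21 = 47 * 65/259
  expect_equal(s1$n21, 11.80, tolerance = 1e-2)
  uv <- split_urine_availability(s1, tx1, lambda = 1)
  expect_equal(unname(uv[1]), s1$n21 * 44 / 65, tolerance = 1e-12)
  expect_equal(unname(uv[1]), 7.988, tolerance = 5e-3)
  expect_equal(unname(uv[2]), 3.812, tolerance = 5e-3)
  expect_equal(sum(uv), s1$n21, tolerance = 1e-12)

  # survey non-respondents half as likely to provide urine
  uv_half <- split_urine_availability(s1, tx1, lambda = 0.5)
  expect_equal(unname(uv_half[1]), s1$n21 * 22 / 43, tolerance = 1e-12)
  expect_equal(unname(uv_half[1]), 6.037, tolerance = 5e-3)

  # nothing imputed at stage 1 -> nothing to split
  s_inf <- impute_stage1(tx1, or1 = Inf)
  expect_equal(unname(split_urine_availability(s_inf, tx1, 1)), c(0, 0))

  # no observed availability pattern
  bare <- arm_counts("B", 20, 0, 10, 10, 0, 0, 0)
  sb <- impute_stage1(bare, 1)   # n21 = 0 under pi = 1, fine
  expect_equal(unname(split_urine_availability(sb, bare, 1)), c(0, 0))
  expect_error(split_urine_availability(
    list(n21 = 4), arm_counts("D", 20, 5, 5, 10, 0, 0, 0), 1),
    "availability")
})

test_that("would-be urine samples split by the eta-scaled verified odds", {
  fi <- split_imputed_urine_outcomes(7.988, 38, 6, eta = 1)
  expect_equal(unname(fi[1]), 7.988 * 38 / 44, tolerance = 1e-12)
  expect_equal(unname(fi[1]), 6.899, tolerance = 1e-3)
  expect_equal(unname(fi[2]), 1.089, tolerance = 1e-3)
  expect_equal(unname(split_imputed_urine_outcomes(0, 38, 6, 1)), c(0, 0))
  expect_equal(unname(split_imputed_urine_outcomes(10, 5, 5, eta = 2)[1]),
               10 * 2 / 3, tolerance = 1e-12)
  # all observed samples verified abstinent -> all imputed ones too
  expect_equal(unname(split_imputed_urine_outcomes(4, 9, 0, 1)), c(4, 0))
  expect_error(split_imputed_urine_outcomes(3, 0, 0, 1), "no observed")
})

test_that("the urine-missing pool is allocated by OR2 as at stage 1", {
  al <- allocate_missing_urine(44.899, 7.089, 24.812, or2 = 1)
  expect_equal(al$pi_prime, (7.089 / 44.899) / (1 + 7.089 / 44.899),
               tolerance = 1e-12)
  expect_equal(al$pi_prime, 0.13636, tolerance = 1e-4)
  expect_equal(al$f22, 3.384, tolerance = 1e-3)
  expect_equal(al$f21, 21.428, tolerance = 1e-3)

  expect_equal(allocate_missing_urine(10, 2, 7, Inf)$f21, 0)
  expect_equal(allocate_missing_urine(10, 2, 0, 3)$f21, 0)
  expect_equal(allocate_missing_urine(10, 2, 0, 3)$f22, 0)
  expect_error(allocate_missing_urine(0, 0, 5, 1), "anchor")
})

test_that("stage-2 composition reproduces hand-computed verified totals", {
  # independent oracle: direct arithmetic through the three steps
  n21 <- 47 * 65 / 259
  u_imp <- n21 * 44 / 65
  f11_imp <- u_imp * 38 / 44
  f11_dot <- 38 + f11_imp
  f12_dot <- 6 + (u_imp - f11_imp)
  v_total <- 21 + (n21 - u_imp)
  odds <- f12_dot / f11_dot
  f21 <- v_total * (1 - odds / (1 + odds))
  expected <- f11_dot + f21

  s1 <- impute_stage1(tx1, 1)
  s2 <- impute_stage2(tx1, s1, sensitivity_params(or1 = 1, or2 = 1))
  expect_equal(s2$verified_abstinent_total, expected, tolerance = 1e-12)
  expect_equal(s2$verified_abstinent_total, 66.33, tolerance = 1e-2)
  expect_equal(s2$verified_failure_total, 306 - expected, tolerance = 1e-12)

  # missing = smoking at both stages keeps only observed verified abstainers
  s1i <- impute_stage1(tx1, Inf)
  s2i <- impute_stage2(tx1, s1i, sensitivity_params(or1 = Inf, or2 = Inf))
  expect_equal(s2i$verified_abstinent_total, 38)

  # nothing missing anywhere: params are irrelevant
  clean <- arm_counts("K", 100, 40, 60, 0, 25, 15, 0)
  for (p in list(sensitivity_params(), sensitivity_params(5, 3, 0.5, 2),
                 sensitivity_params(Inf, Inf))) {
    s <- impute_stage2(clean, impute_stage1(clean, p$or1), p)
    expect_equal(s$verified_abstinent_total, 25)
  }
})

test_that("stage-2 conservation chain, OR2 identity and lambda/eta
           neutrality at OR1 = Inf hold on random arms", {
  set.seed(635)
  for (rep in 1:20) {
    arm <- random_arm()
    for (p in list(sensitivity_params(1, 1), sensitivity_params(2, 3),
                   sensitivity_params(3, 2, 0.5, 2),
                   sensitivity_params(1, Inf))) {
      s1 <- impute_stage1(arm, p$or1)
      u_obs <- arm$urine_abstinent + arm$urine_failure
      if (s1$n21 > 0 && u_obs == 0 && arm$urine_missing == 0) next
      if (u_obs == 0 && arm$urine_missing > 0) next  # nothing to anchor eta
      s2 <- impute_stage2(arm, s1, p)
      expect_equal(s2$u_imp + s2$v_imp, s1$n21, tolerance = 1e-9)
      expect_equal(s2$f11_imp + s2$f12_imp, s2$u_imp, tolerance = 1e-9)
      expect_equal(s2$f21 + s2$f22, s2$v_total, tolerance = 1e-9)
      expect_true(all(unlist(s2[c("u_imp", "v_imp", "f11_imp", "f12_imp",
                                  "f21", "f22")]) >= -1e-12))
      expect_equal(s2$verified_abstinent_total + s2$verified_failure_total,
                   arm$n_total, tolerance = 1e-9)
      if (is.finite(p$or2) && s2$f21 > 0 && s2$f11_dot > 0 &&
          s2$f12_dot > 0)
        expect_equal((s2$f22 / s2$f21) / (s2$f12_dot / s2$f11_dot), p$or2,
                     tolerance = 1e-9)
    }
    # or1 = Inf leaves nothing for lambda or eta to act on
    s1_inf <- impute_stage1(arm, Inf)
    if (arm$urine_abstinent + arm$urine_failure > 0) {
      a <- impute_stage2(arm, s1_inf, sensitivity_params(Inf, 2, 1, 1))
      b <- impute_stage2(arm, s1_inf, sensitivity_params(Inf, 2, 0.25, 4))
      expect_equal(a$verified_abstinent_total, b$verified_abstinent_total,
                   tolerance = 1e-12)
    }
  }
})

test_that("fixture rates fall monotonically in OR1 and OR2", {
  twin <- enhanced_quit_win()
  ors <- c(1, 2, 3, 4, 5, Inf)
  for (i in seq_len(nrow(twin$arms))) {
    arm <- twin$arms[i, ]
    verified <- sapply(ors, function(o1) sapply(ors, function(o2) {
      s1 <- impute_stage1(arm, o1)
      impute_stage2(arm, s1, sensitivity_params(o1, o2))$
        verified_abstinent_total
    }))
    # columns: fixed or1, increasing or2; rows: fixed or2, increasing or1
    expect_true(all(apply(verified, 2, diff) <= 1e-12))
    expect_true(all(apply(verified, 1, diff) <= 1e-12))
  }
})
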