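# quitsens

Sensitivity analysis for tobacco-cessation trials whose primary outcome —
biochemically verified abstinence — can be missing at **two stages**: the
follow-up survey where participants self-report their smoking status, and
the urine (cotinine) test offered only to self-reported abstainers.

## Who this is for

Trial statisticians and tobacco-control researchers who must report
abstinence effects despite survey non-response and missing biochemical
samples. Because missing-at-random (MAR) and missing-not-at-random (MNAR)
mechanisms are indistinguishable from observed data, a defensible analysis
sweeps a family of assumptions rather than committing to one — in
particular, it should contain both the MAR analysis and the conventional
"missing = smoking" rule as endpoints of the same dial.

## The method

All imputation is single imputation on **aggregated per-arm counts**,
stratified by treatment arm. For one arm with `n` randomized subjects,
write `n11`/`n12` for observed self-reported abstinence/failure and `n2.`
for survey non-respondents.

**Stage 1 (survey).** Assume an odds ratio `OR1` between survey
missingness and tobacco use. With `Odds = n12/n11` observed among
respondents,

    pi  = OR1 * Odds / (1 + OR1 * Odds)
    n22 = pi * n2.        (imputed failures)
    n21 = n2. - n22       (imputed abstainers)

`OR1 = 1` reproduces the complete-case (MAR) rate; `OR1 = Inf` imputes all
non-respondents as failures (missing = smoking).

**Stage 2 (urine).** Among self-reported abstainers, `f11`/`f12` are
verified abstinence/failure and `v` the missing samples. The `n21` imputed
abstainers are first split into would-be provided (`u_imp`) and missing
(`v_imp`) samples assuming the provided:missing odds scale by a factor
`lambda`; `u_imp` is then split into would-be verified results by scaling
the verified-abstinent odds by `eta`; finally the *entire* urine-missing
pool `v = v_obs + v_imp` is allocated under a second odds ratio `OR2`
exactly as at stage 1. The arm's verified-abstinent total is
`f11. + f21`, and everyone else counts as failure.

Arms are pooled per intervention contrast after imputation; effects are
abstinence rates, odds ratios, and uncorrected Pearson chi-square tests
(fractional imputed counts are used as-is).

## Worked example

The package ships the aggregated counts of a 2x2 factorial quit-and-win
trial (1217 college smokers; single/multiple contests crossed with
counseling/no counseling) as `enhanced_quit_win()`.

```r
library(quitsens)
twin <- enhanced_quit_win()
run_self_report_grid(twin, or1_values = c(1, 3, Inf))
```

```
Sensitivity grid (self_report outcome, 4 scenario(s))
           OR1 counseling.exposed counseling.control counseling.OR counseling.p
 complete case              29.7%              24.4%          1.31         .058
             1              29.8%              24.4%          1.31         .034
             3              25.8%              22.0%          1.23         .125
           inf              22.9%              20.5%          1.15         .303
 contests.exposed contests.control contests.OR contests.p
            28.4%            25.4%        1.16       .291
            28.6%            25.4%        1.18       .212
            25.2%            22.5%        1.16       .275
            22.8%            20.6%        1.14       .359
```

Reading the counseling columns: under MAR (`OR1 = 1`) counseling raises
self-reported abstinence from 24.4% to 29.8% (odds ratio 1.31, p = .034),
but the effect loses significance as soon as non-respondents are assumed
even moderately more likely to be smoking (`OR1 >= 2`) — the conclusion is
sensitive to the missingness assumption. The contests effect (~1.16) barely
moves, because the two contest groups have similar missing rates.
`run_verified_grid()` produces the analogous `OR1 x OR2` grid for the
verified outcome, and `write_grid_csv()` saves any grid in long format.

A command-line interface covers the same pipeline
(`inst/scripts/quitsens`): `run` (grids from a counts CSV or `--fixture`),
`simulate` (individual-level MNAR trial generator, aggregated to the same
CSV schema plus a latent-truth sidecar), and `validate` (accounting-identity
checks). See `?quitsens_cli`.

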