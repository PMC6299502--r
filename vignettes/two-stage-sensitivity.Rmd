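---
title: "Two-stage imputation sensitivity analysis for verified abstinence outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage imputation sensitivity analysis for verified abstinence outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitsens)
```

## The problem

Cessation trials typically measure abstinence by a follow-up survey and
then invite self-reported abstainers to provide a urine sample for
cotinine verification. The primary outcome — biochemically verified
abstinence — is therefore missing whenever the survey is missed *or* the
urine sample is not provided, and the two stages may have different
missingness mechanisms. Since observed data cannot distinguish
missing-at-random (MAR) from missing-not-at-random (MNAR), the analysis
here treats the strength of the outcome–missingness association as a
*known sensitivity parameter* and sweeps it, rather than estimating it.

Two conventions mark the ends of the spectrum. Under MAR, missing
outcomes are imputed at the observed rates. Under "missing = smoking",
every subject without a fully verified abstinent outcome is a treatment
failure — the dominant convention in the field, and a strong MNAR
assumption: it corresponds to a perfect correlation (infinite odds ratio)
between missingness and smoking.

## Model and procedure

All computation is on aggregated per-arm counts; imputation is stratified
by arm (never pooled first), so each arm's mechanism is anchored only in
its own observed data. Pooling across arms into intervention contrasts
happens after imputation.

**Stage 1.** For one arm, let $n^{11}, n^{12}$ be observed self-reported
abstinence and failure and $n^{2\cdot}$ the survey non-respondents. Given
the assumed odds ratio $OR_1$ between survey missingness and tobacco use,
the non-respondents split as

$$n^{22} = n^{2\cdot}\,\pi,\qquad
  \pi = \frac{OR_1\,\mathrm{Odds}}{1 + OR_1\,\mathrm{Odds}},\qquad
  \mathrm{Odds} = n^{12}/n^{11},$$

and $n^{21} = n^{2\cdot} - n^{22}$. By construction the imputed table
satisfies $(n^{22}/n^{21})/(n^{12}/n^{11}) = OR_1$ exactly. At $OR_1 = 1$
the imputed arm rate equals the complete-case rate; as $OR_1 \to \infty$,
$\pi \to 1$ and the rule becomes missing = smoking.

**Stage 2.** Among self-reported abstainers, $f^{11(obs)}, f^{12(obs)}$
are verified abstinence/failure and $v^{(obs)}$ the missing samples
($u^{(obs)} = f^{11(obs)} + f^{12(obs)}$ provided). Three sub-steps, in
fixed order and with no re-normalisation afterwards:

1. *Availability* ($\lambda$): the $n^{21}$ imputed abstainers split into
   would-be provided/missing samples by
   $u^{(imp)}/v^{(imp)} = \lambda\, u^{(obs)}/v^{(obs)}$ with
   $u^{(imp)} + v^{(imp)} = n^{21}$.
2. *Would-be results* ($\eta$):
   $f^{11(imp)}/f^{12(imp)} = \eta\, f^{11(obs)}/f^{12(obs)}$ with
   $f^{11(imp)} + f^{12(imp)} = u^{(imp)}$.
3. *Allocation* ($OR_2$): with $f^{11\cdot} = f^{11(obs)} + f^{11(imp)}$
   (similarly $f^{12\cdot}$) and $v = v^{(obs)} + v^{(imp)}$, the entire
   urine-missing pool splits as $f^{22} = v\,\pi'$,
   $\pi' = OR_2\,\mathrm{Odds}'/(1 + OR_2\,\mathrm{Odds}')$,
   $\mathrm{Odds}' = f^{12\cdot}/f^{11\cdot}$.

The arm's verified-abstinent total is $f^{11\cdot} + f^{21}$; everyone
else counts as a failure in the arm-level rate, so totals are conserved at
every step (the package tests these identities to $10^{-9}$).

A note on $\lambda$: its defining relation scales the *provided:missing
odds* of a urine sample, which is how it is implemented here, even though
one might loosely describe it as scaling the "missing rate". $\lambda < 1$
means survey non-respondents would have been less likely to provide urine.
$\eta$ likewise scales the verified-abstinent odds of would-be samples.

## Parameters, defaults, units

| Parameter | Meaning | Default | Range |
|---|---|---|---|
| `or1` | survey-missingness vs tobacco-use odds ratio | 1 | $(0, \infty]$ |
| `or2` | urine-missingness vs verified-failure odds ratio | 1 | $(0, \infty]$ |
| `lambda` | availability-odds factor for non-respondents | 1 | $(0, \infty)$ |
| `eta` | verified-abstinence-odds factor for would-be samples | 1 | $(0, \infty)$ |

The default grid is $\{1,2,3,4,5,\infty\}$ for both odds ratios with
$\lambda = \eta = 1$, the layout used in the motivating trial's report. In
incentivised-quit settings one usually expects $OR_1 \ge 1$ (smokers are
the likelier non-respondents), but the formulas are valid for
$0 < OR_1 < 1$ too — such values assert that *abstainers* were likelier to
drop out — and the package permits them. `Inf` is a first-class value with
a dedicated branch, spelled `inf` in configs and CSVs; it is not
approximated by a large float (though the tests confirm agreement with
$OR = 10^9$ to $10^{-6}$ of a subject).

## Numerical choices and degenerate inputs

* Imputed counts are fractional and never rounded internally; rounding is
  purely a display concern (rates to 0.1%, odds ratios to 2 decimals,
  p-values to 3). Accounting identities on fractional counts are checked
  with absolute tolerance $10^{-9}$.
* Degenerate observed cells: with no observed abstainers ($n^{11} = 0$)
  the observed odds are infinite, so $\pi = 1$ for any $OR_1$; with no
  observed failures ($n^{12} = 0$), $\pi = 0$ for *every* $OR_1$,
  including $\infty$ — the $\infty \cdot 0$ indeterminacy is resolved in
  favour of the observed odds of zero, keeping $\pi$ continuous in $OR_1$
  for fixed data. With nothing observed at all and a nonempty missing
  pool, the imputation has no anchor and errors. The same policy applies
  to $\pi'$ at stage 2.
* Proportional redistribution of provided-but-untested samples
  (`redistribute_untested()`) happens before any imputation and requires
  at least one tested sample.
* Effects use the uncorrected Pearson chi-square on the pooled 2x2 table,
  accepting fractional counts, with two-sided p-values from the
  $\chi^2_1$ upper tail. No continuity correction or exact test is
  applied; the uncorrected statistic reproduces the published
  complete-case and MAR p-values of the packaged example (.058/.034),
  which fixed this choice. Confidence intervals are out of scope.

## The packaged fixture

`enhanced_quit_win()` carries the published per-arm counts of a
2x2 factorial quit-and-win trial (four arms of 296–309 subjects,
contests x counseling). Five urine samples of inadequate volume were
redistributed proportionally to the verified columns (86%/14%) in the
published per-arm table; the fixture stores those post-redistribution
per-arm values verbatim — as printed, integers — because the per-arm
assignment of the five samples was not published and cannot be re-derived.
The stored rows satisfy both accounting identities exactly and reproduce
every published grid cell at display precision, which the acceptance tests
assert cell by cell.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_trial()` generate individual-level trials to
test parameter recovery without any external data. Per subject: latent
abstinence is Bernoulli; abstainers self-report abstinence with
probability `self_report_honesty` (users always report use); survey
missingness depends on latent tobacco use through a true odds ratio
`true_or1`; among observed self-reported abstainers, biochemical
confirmability is Bernoulli and urine missingness depends on it through
`true_or2`. Probabilities are scaled on the odds scale
($p \mapsto OR\,p/(1-p+OR\,p)$), which never leaves $[0,1]$. A single
seeded stream drives each run, with per-arm substreams derived
deterministically from the seed, so identical scenarios give identical
counts.

Under honest reporting the generator's latent mechanisms coincide with the
analysis model's observables, so analysing at the generating odds ratios
is consistent: in the recovery experiment (4 arms of 300, abstinence
probability 0.25, confirmability 0.8, survey/urine base missingness
0.2/0.3 — the scale of the motivating trial — with
`true_or1 = true_or2 = 3`, 200 replicates) the mean bias of pooled
verified rates is within Monte-Carlo error of zero, while analysing the
same data with `or1 = or2 = Inf` is systematically pessimistic. These
problem sizes are the package's standing test conditions.

What the simulator does *not* emulate: dishonest reporting interacting
with verification (with `self_report_honesty < 1` the analysis odds ratios
refer to *self-reported* status, the generator's to latent truth, so exact
recovery is asserted only at honesty 1), covariate-driven missingness,
repeated measurement occasions, or lab error in the cotinine assay.
Passing recovery tests therefore show internal consistency of the
imputation under its own assumptions — not that any particular `OR`
matches a real trial's mechanism, which is exactly why the surrounding
package reports grids rather than single answers.

## Design choices made where the design was open

* **Stratified, not adjusted.** Imputation is per-arm; no covariate or
  treatment-adjusted imputation model is offered. This keeps each arm's
  mechanism assumption transparent and the arithmetic exactly
  reproducible from a published count table.
* **Single imputation, no uncertainty in the imputed counts.** p-values
  reflect sampling variation of the (imputed) 2x2 table only, not
  imputation uncertainty; multiple imputation at the individual level is
  deliberately out of scope.
* **`lambda`/`eta` as scalars per run** (the CLI accepts lists to grid
  them), mirroring how such analyses are usually reported; they are known
  factors, not estimated quantities.
* **Long-format reports** (one row per scenario x contrast) as the
  machine-readable output, with the wide publication-style rendering as a
  formatting layer only.

## Known limitations

Beyond the simulator's scope above: the method needs at least one observed
subject in each anchoring margin (survey outcomes; urine results when
anything urine-related must be imputed); zero-margin pooled tables make
the chi-square undefined and raise errors rather than silently returning
0/1; and because imputed counts enter the test as if observed, p-values
are anti-conservative to a degree that grows with the missing fraction —
grids should be read as sensitivity displays, not as a correction for
missingness.
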