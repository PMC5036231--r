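---
title: "Methods: owner-reported limber tail cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: owner-reported limber tail cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbertail)
```

## The problem

Limber tail (acute caudal myopathy; also called cold tail, swimmer's tail or
frozen tail) is a self-resolving flaccidity of the canine tail, usually with a
stiff, painful tail base, that mostly affects larger working breeds. Because
it resolves without treatment, most episodes are never presented to a
veterinarian, so practice records badly undercount the disease burden (the
"symptom iceberg"). Owner-reported cohort data are the natural substrate for
studying it, and this package implements the full analysis pipeline such a
study needs:

1. **Screening** free-text owner illness reports for candidate incidents with
   a keyword rule.
2. **Classification** of questionnaire sign profiles into final case/control
   status under an explicit case definition.
3. **Exact epidemiological inference**: Clopper-Pearson binomial intervals,
   conditional maximum-likelihood odds ratios with exact confidence intervals
   and Fisher tests for 2x2 tables, and logistic risk models.
4. A **permutation test** of whether cases share sires (or dams) more than
   random samples of the cohort - a screen for familial predisposition.
5. A **synthetic cohort generator** that emulates all the input tables with
   known ground truth, so each stage is testable end to end.

## Screening rule

A report is a candidate incident when its text contains "tail" together with
at least one of thirteen stems: cold, dead, droopy, drop, limb, limber, limp,
rudder, staved, stiff, stride, swim, swimmers. Matching is case-insensitive
plain substring matching. The stems only make sense as substrings ("limb"
is there to catch "limber", "swim" catches "swimming" and "swimmer's"), which
is also why "tail" itself is matched as a substring ("tailbase"). The price of
substring matching - occasional false hits such as "climbing" - is covered by
two mechanisms: texts containing "tail" with no stem go to a manual-review
queue, and review outcomes are injected as a reproducible overrides table
(`dog_id`, `include`/`exclude`) rather than interactive input. Note that
"frozen", although a common owner phrasing, is *not* among the stems; frozen
tail reports are exactly the kind of text the review queue exists for.

Reports by the same dog on the same date are collapsed into one incident;
otherwise each matching report is an incident. The screening summary also
reports the fraction of candidate dogs whose incidents never involved a
veterinary visit, with an exact binomial interval - an estimate of what a
practice-records study would miss.

## Case definition and reclassification

Final status is a pure function of the questionnaire response and the
provisional (screening-derived) status. The case definition: *some degree of
tail limpness* (limp at the end or along the entire length) *and no report of
an alternative cause*. Three deliberate choices:

* "Unsure" on a limpness sign counts as "no": case status requires positively
  reported flaccidity. The conservative direction was chosen because the
  definition is itself a diagnosis of exclusion.
* Any concrete attribution (tail injury, impacted anal glands, another cause)
  vetoes case status even when limpness is reported.
* A provisional case whose questionnaire shows no limpness leaves the case
  arm. By default it is retained as a control - under this accounting 31
  provisional cases and 93 provisional controls resolve to 38 cases and 86
  controls, the arithmetic of the worked example bundled as
  `limber_worked_example()`. Setting `demote_excluded = TRUE` instead assigns
  a three-way `excluded` status that appears in neither arm (84 controls in
  the worked example); both accountings are reported by the transition
  summary.

Owner inconsistencies - a "no" to the pain question together with a non-zero
pain score - are counted and reported, never corrected.

Duration categories recode as: "a few hours" = 0.125 days, "a few days" = 3
days, "a week or more" = 8 days; explicit day counts pass through;
unrecognised categories become `NA` with a warning and are excluded from
summaries.

## Exact 2x2 inference

Conditional on both margins of a 2x2 table, the exposed-case count follows
Fisher's noncentral hypergeometric distribution with noncentrality equal to
the odds ratio $\psi$. Everything is computed on that one-dimensional
conditional likelihood, in log space:

* **Point estimate**: the conditional MLE, i.e. the $\psi$ at which the
  conditional mean equals the observed count, found by monotone root search
  on $\log\psi$ (tolerance $10^{-10}$). This differs slightly from the sample
  cross-product ratio; for the bundled swimming table (36, 2, 68, 18) the
  cross-product is 4.76 while the conditional MLE is 4.72.
* **Confidence interval**: the default inverts the two-sided
  minimum-likelihood-ordering exact test - the interval is the set of $\psi$
  whose two-sided p-value is at least $1-$level, located by a coarse scan of
  $\log\psi \in [-40, 40]$ refined by root search. This ordering is the
  conventional companion of the two-sided exact test and is the method that
  reproduces published exact 2x2 intervals such as 4.7 (1.1 to 29.9) and
  5.1 (1.1 to 24.9); the equal-tail ("central") interval, which is what
  `fisher.test()` reports, is available via `method = "central"` and is
  noticeably wider on skewed tables (upper bound 44.2 rather than 30 for the
  swimming table).
* **Display precision caveat**: the exact minlike upper endpoint for the
  swimming table is 29.983. At one decimal this rounds to 30.0 while the
  published display is 29.9 (its truncation); the lower endpoint 1.057 matches
  the published 1.1 only under rounding. The package always reports the
  unrounded endpoint; tests compare published displays at one unit in the last
  printed digit.
* **Tests**: the two-sided Fisher p-value uses the minimum-likelihood
  ordering (sum of all conditional tables no more probable than the observed,
  with the customary $1+10^{-7}$ tie tolerance); one-sided p-values are tail
  sums. Zero cells on the support boundary yield boundary estimates (0 or
  $\infty$) and one-sided intervals, flagged rather than silent.

The test suite validates this machinery two independent ways: against
`stats::fisher.test` (estimate, central interval, p-values) and against a
brute-force enumeration oracle (plain `choose()` products, grid-plus-optimize
maximisation) over every table with all margins at most 12, to $10^{-6}$.

## Binomial intervals and incidence

Clopper-Pearson intervals use the beta-quantile characterisation, with the
interval pinned to 0/1 at boundary counts. `cumulative_incidence()` adds a
sensitivity bound for questionnaire non-response that treats all
non-responders as unaffected - e.g. 9 promoted controls among 93 responders
(9.7%) falls to 9/127 (7.1%) when 34 non-responders are counted in the
denominator. Exactness makes the interval conservative: over the binomial
distribution at $n = 93$, $p = 0.1$ its coverage exceeds 95%, which the suite
verifies both exactly (summing the binomial pmf) and by simulation.

## Logistic risk models

`fit_logistic()` is a validated wrapper around IRLS maximum likelihood
(`stats::glm`, binomial family) reporting Wald intervals on both the log-odds
and odds-ratio scales. Non-convergence and (quasi-)complete separation - any
fitted probability within $10^{-8}$ of 0/1 or a coefficient beyond 15 - are
flagged explicitly, because separated fits otherwise return huge, meaningless
Wald intervals. Latitude and longitude are fitted as two single-predictor
models by default, with a joint fit alongside, since a household's coordinates
are strongly collinear with region; all three fits are reported.

## Parental-contribution permutation test

For a set of $n$ sampled dogs grouped by sire (or dam) with per-parent
offspring counts $c_1, \dots, c_k$, two summaries are computed:

* offspring-weighted (default): $\sum c_i^2 / \sum c_i$ - each parent
  weighted by its own contribution, the reading under which parents of several
  sampled offspring are "weighted and averaged". For counts
  $\{3, 2, 2, 1^{31}\}$ over 38 dogs it equals $48/38 \approx 1.263$.
* plain mean: $n / k$ ($38/34 \approx 1.118$ for the same counts).

Both equal 1 exactly when all parents are distinct and $n$ when one parent
contributed every dog. The figure defining the original statistic is not
recoverable from text alone, so both readings are implemented and reported
side by side; the offspring-weighted form is the default because the source
procedure describes weighting multi-offspring contributors.

The null distribution comes from `n_perm` simple random samples without
replacement of the case-set size, drawn from the full cohort (not from
cases and controls only). The upper-tail p-value uses the add-one rule
$p = (1 + \#\{S_\text{null} \ge S_\text{obs}\})/(n_\text{perm}+1)$, so the
smallest attainable p is $1/(n_\text{perm}+1)$; a published raw tail count of
2/10,000 corresponds to 0.0003 under this rule rather than 0.0002, a
difference the package documents rather than hides. Clustering is declared
significant when the observed statistic exceeds the 97.5th percentile of the
null sample. Dogs with an unknown parent on the chosen axis are dropped from
the case set and the sampling frame alike, with counts recorded. An
exhaustive enumerator (`exhaustive_null()`, capped at $10^6$ subsets) serves
as the brute-force oracle for the Monte-Carlo sampler.

## The synthetic cohort generator

The generator defines the study conditions under which everything is tested.

* **Pedigree**: single generation (parents are not cohort members), one sire
  and dam per dog, allocated by a Dirichlet-multinomial: assignment
  probabilities drawn once per parent pool from a symmetric Dirichlet with
  one `concentration` knob. Large concentrations approach uniform
  contributions; small ones let a few parents dominate. No distribution for
  real litter patterns is available, so concentration defaults to 1 (a flat
  Dirichlet), which spans realistic skew; a 38-dog sample from such a cohort
  can show exactly the illustrative $\{3,2,2,1^{31}\}$ pattern.
* **Covariates**: defaults emulate a UK Labrador cohort - 79% swimmers (the
  control-arm rate 68/86), 4% working dogs, latitude normal (52.9, 1.6)
  truncated to [49, 61] degrees north, plus sex, neuter status, coat,
  household type and smoking at unremarkable rates. Latitude is generated
  directly in degrees; postcodes and geocoding are deliberately not
  simulated because the analysis consumes coordinates.
* **Disease model**: $\mathrm{logit}\,P(\text{affected}) = \beta_0 +
  \beta_\text{swim}\,\text{swims} + \beta_\text{work}\,\text{working} +
  \beta_\text{lat}(\text{lat} - 52.9) + u_\text{sire}$, with $u_\text{sire}
  \sim N(0, \sigma_s^2)$ shared within sire. Default effects are the
  published odds ratios (4.7, 5.1, 1.47 per degree); $\beta_0 =
  \mathrm{logit}(0.02)$ puts the marginal affected fraction near the observed
  9.7% incidence at the default covariate mix; $\sigma_s = 1$ gives familial
  clustering of the kind the permutation test detects. $\sigma_s = 0$ makes
  the case set exchangeable with random cohort draws, the basis of the
  calibration tests.
* **Free text**: three template classes with ground-truth labels - keyword
  phrases modelled on the owner phrasings (limp/limber tail, swimmer's tail,
  cold tail), keyword-free tail phrases ("she couldn't wag it", "frozen
  tail") that only manual review can recover, and non-tail distractors.
  Every affected dog reports at least once; 10% of its reports are
  keyword-free (the under-reporting route by which provisional controls are
  later promoted); repeat episodes occur with probability 0.2 each; 21% of
  tail reports involve a veterinary visit (the observed 11/53).
* **Questionnaires**: one per dog (repeat submissions are collapsed, since
  the case-control analysis is per dog). Affected dogs report end-limpness
  with probability 0.85, whole-length limpness 0.4, stiff base 0.5; 5%
  attribute their signs to another cause. Unaffected dogs report signs at
  rate 5/93, mostly attributed or lacking limpness - mirroring the observed
  false-alarm pattern (3 anal-gland attributions and 2 non-limp sign sets
  among 93 provisional controls). Pain and quality-of-life scores are
  integers on 0-10 from a latent bivariate normal whose correlation is
  **calibrated by quadrature** so the reported (rounded, clamped) scores
  carry the configured Pearson correlation of 0.72 - naive rounding would
  attenuate it by about 0.015, outside sampling error at n = 10,000.
  Duration categories default to a mix whose recoded mean is 3.5 days.

What the generator does *not* emulate: multigenerational kinship, litter
structure, longitudinal questionnaire schedules, postcode geography, recall
bias, and informative non-response. Passing tests therefore demonstrate that
the methods recover known structure under a faithful but idealised data
process, not that any particular field estimate is unbiased under real-world
reporting behaviour.

## Verification protocols and problem sizes

Quantities printed in the original study that need its raw data (latitude OR
1.47, permutation P = 0.0002, mean duration 3.5 days, mean pain 6.0,
correlation 0.72) are replaced by parameter-recovery and calibration
properties at sizes chosen to keep the whole suite in the minutes range:

* **Logistic recovery**: one 20,000-dog cohort, 100 replicate status
  simulations with $\sigma_s = 0$ (so the conditional and marginal models
  coincide); each generating coefficient must fall inside its 95% Wald
  interval in at least 90 of 100 fits.
* **Permutation calibration**: 800 dogs over 100 sires (concentration 0.4,
  so contributions are heterogeneous and the statistic near-continuous),
  incidence 12%, $\sigma_s = 0$; 500 replicate datasets, 199 permutations
  each; the 500 p-values must pass a Kolmogorov-Smirnov uniformity test at
  the 1% level. The heterogeneous design matters: on small cohorts with
  near-uniform sires the statistic is coarsely discrete and the add-one
  p-value is visibly super-uniform through ties.
* **Oracle agreement**: Monte-Carlo tail probability within three binomial
  standard errors of the exhaustive value on a 6-dog two-sire pedigree
  (10,000 permutations), and the 2x2 estimates against brute-force
  enumeration for all margins up to 12.
* **Power**: on a 600-dog, 120-sire cohort with case counts around 38,
  rejection at the 5% level is monotone over $\sigma_s \in \{0.5, 1.5, 2.5\}$
  (500 replicates each) and exceeds 0.5 at the top of the grid (a
  1000-replicate design simulation put it near 0.9).

## Known limitations

* The exact minlike interval search scans a fixed $\log\psi$ grid of width
  0.05 before refinement; acceptance regions narrower than that (not
  attainable for tables with both margins positive and moderate counts)
  would be missed.
* The permutation test treats the pedigree as fixed and complete; unknown
  parents are dropped, not imputed, which loses power when missingness is
  informative.
* Mixed-effects models of height/weight/exercise with a per-dog random
  effect are intentionally out of scope; the analysis report lists them as
  not implemented.
* The classifier encodes one reading of the case definition; whether a stiff
  painful base with "unsure" limpness should ever count as a case is left to
  the strict rule (it does not), with the raw sign profile preserved for
  sensitivity analyses.
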