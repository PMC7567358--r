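---
title: "The M-CDS: model, derivation and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The M-CDS: model, derivation and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcds)
```

## The scoring model

The Modified Chronic Disease Score (M-CDS) predicts one-year mortality in
adults aged 50+ from outpatient drug-dispensing records alone. Chronic
conditions are never observed directly: each condition $j$ is *inferred*
from ATC-coded pharmacy claims through a mapping rule — a set of ATC
prefixes plus a minimum number of prescriptions per calendar year — applied
to a two-year lookback window. The inferred flags $x_{ij} \in \{0, 1\}$
enter a Cox proportional-hazards model for death within 365 days of the
index date,

$$h_i(t) = h_0(t)\, \exp\!\Big(\sum_j \beta_j x_{ij}\Big),$$

and the published integer weights are $w_j = \mathrm{round}(10\,\beta_j)$.
The total score $S_i = \sum_j w_j x_{ij}$ is an integer between 0 and 63
(the sum of the 18 published weights), stratified into six risk classes
$\le 1$, $2$, $3$–$4$, $5$–$6$, $7$–$9$, $\ge 10$.

## Condition mapping

**Thresholds.** Flagging uses three tiers of minimum prescriptions per
calendar year: 2 in general; 1 for drugs that unambiguously identify a
diagnosis (e.g. multiple-sclerosis disease modifiers); 3 for drugs also
frequent in minor, non-chronic complaints (e.g. proton-pump inhibitors).
"Per year" is read strictly per calendar year, satisfied in at least one of
the two observation years; pooling the two years is available as
`pooled = TRUE` but is not the default, because a chronic condition should
generate sustained prescribing within a single year. Prescriptions are
counted as claim rows, not packages or unit doses: package counts are
recorded in the claims schema (`n_packages`, defaulting to 1) but play no
role in flagging.

**Exceptions.** Some full 7-character codes are carved out of a broader
pattern and reassigned: midazolam (`N05CD08`) counts toward epilepsy rather
than with the other benzodiazepine hypnotics, which count toward the
depression/anxiety/OCD group; lithium (`N05AN01`) is carved out of the
antipsychotic pattern into bipolar disorder; antitussives are flagged as a
wrong association under cancer and excluded from the active rule set.
The rule loader refuses an ATC pattern claimed by two active conditions
unless the overlap is disambiguated by an exception code.

**The shipped table is a reconstruction.** The exact published drug lists
are not available in machine-readable form, so
`inst/extdata/condition_rules.csv` carries a best-effort reconstruction of
the 33-condition list from standard ATC therapeutic groups. It reproduces
the documented reassignments and threshold tiers, but individual drug lists
should be treated as unverified defaults: any production use should supply
its own mapping file (`read_condition_rules(path)`), which is the supported
override mechanism. All scoring, derivation and validation machinery is
independent of which mapping file is active.

**Prevalence floor.** Conditions flagged in fewer than `min_cases = 2`
patients are dropped before derivation, mirroring the exclusion of
conditions that are virtually absent in a population (in the development
data, cystic fibrosis and addictive disorders, with one and zero cases).

## Weight derivation

Weights are re-derived on any cohort by $L_1$-penalised Cox regression over
age, sex and the condition flags:

* Breslow tie handling throughout the penalised path (day-resolution data
  has heavy ties; Efron is available for the refit via `ties = "efron"`);
* a 100-point log-spaced penalty grid from the smallest all-zero penalty
  down to $10^{-3}$ of it;
* 10-fold cross-validation of the partial-likelihood deviance, with folds
  stratified by event status so each fold contains deaths, reproducible
  from the seed;
* the one-standard-error rule: the most parsimonious penalty whose CV
  deviance is within one SE of the minimum;
* by default, an unpenalised refit of the selected covariates supplies the
  coefficients that are transformed into weights. The refit is the default
  because the published coefficient magnitudes are consistent with
  unshrunken values; `refit = FALSE` uses the penalised coefficients
  instead, and both routes are exposed.

Age and sex compete for selection but never receive weights — the score is
a pure comorbidity index; their coefficients are reported as an
`adjustment` attribute of the weight table.

**Rounding.** The weight transform rounds halves away from zero.
"Round to nearest" with IEEE banker's rounding would surprise an
epidemiologist (2.5 would become 2); none of the 18 published rows is
affected by the choice, which the tests assert.

## CHAID stratification

Risk-class boundaries are discovered with a single-predictor ordinal CHAID
tree of the integer score against the death indicator (defaults: depth 3,
parent $\ge 1000$, child $\ge 500$, $\alpha = 0.05$ for splitting and
merging). Adjacent score categories are merged while the least
distinguishable pair (largest Pearson chi-square $p$, no continuity
correction) exceeds the merge level; the split $p$-value is then Bonferroni
multiplied by the number of contiguous partitions
$\binom{c-1}{g-1}$ of the node's $c$ original categories into the $g$
merged groups, after Kass's ordinal CHAID. Ties in pair selection break
toward the lower score interval, making the tree deterministic.

Two deliberate choices:

* categories smaller than the child minimum are force-merged with their
  most similar adjacent neighbour after the significance-based merging —
  the classic treatment of sparse categories. Without it, a near-empty
  extreme-score category (a handful of patients with scores above 30)
  would violate the every-child-minimum rule and veto an otherwise
  overwhelming root split;
* expected cell counts below 5 raise a warning rather than switching to an
  exact test, matching classic CHAID.

Leaf boundaries are data-dependent: at population scale ($n = 300{,}000$)
chi-square tests are so powerful that sampling fluctuations inside a
truly homogeneous score range can survive the Bonferroni correction, so
the tree may return 7 or 8 leaves where 6 classes were planted, and
event rates of two leaves subdividing a flat-risk range are not ordered in
expectation. When the true risk is strictly monotone in the score, leaf
event rates are ordered, and the tests assert exactly that scoped
property.

## The synthetic cohort

The simulator generates claims/cohort/outcomes files with the structure the
score assumes, so the whole pipeline runs without access to administrative
data:

* condition flags drawn independently per condition, with default
  prevalences taken from the development population (50+ residents of a
  large Italian healthcare authority; e.g. diabetes 9.8%, cardiovascular
  and cerebrovascular disease 57.1%);
* for each flag, prescription counts of threshold $+\,\mathrm{Poisson}(1)$
  in each lookback year, with ATC codes completed from the condition's own
  rule patterns; *occasional users* (5% of unaffected patients per
  condition by default) receive strictly sub-threshold counts in one
  random year, exercising the exclusion logic the thresholds exist for;
* exponential survival with hazard $h_0 \exp(\beta' x)$, where $\beta$ are
  the published coefficients and $h_0$ is calibrated by monotone
  root-finding so the marginal one-year mortality is 2.4%; administrative
  censoring at 365 days. The constant hazard is deliberate: only one-year
  risk is modelled and the within-year shape is unidentifiable at this
  horizon;
* age (normal, mean 67.5, SD 11.8, truncated at 50) and sex (56.1% female)
  are generated as candidates for the derivation model but influence
  nothing in the default truth, since the published weight table contains
  no age or sex terms.

**What the generator does not emulate.** Conditions are independent by
default, while real comorbidities cluster strongly. An exchangeable
Gaussian-copula `correlation` parameter is available (it preserves the
marginal prevalences while inflating the score variance), but it is off by
default. This matters for interpretation: under independence the variance
of the linear predictor is $\sum_j p_j (1-p_j) \beta_j^2 \approx 0.11$,
which caps the c-statistic of even the *true* model near 0.60. The 0.76
discrimination reported on real data therefore cannot be reproduced — or
even approached — by any score on the default synthetic cohort; it reflects
comorbidity clustering and age structure that the generator deliberately
does not claim to emulate. Passing discrimination tests on synthetic data
consequently show that the machinery is correct, not that the score would
discriminate equally well (or poorly) on a real population.

## Validation machinery

The c-statistic is computed in the tie-aware Mann–Whitney form (probability
that a case outranks a control, ties counting half) via sorted-rank
placements in $O(n \log n)$; it is checked against brute-force pair
counting and against the trapezoidal ROC integral of an independent
reference implementation. Confidence intervals and paired score
comparisons use DeLong's structural-component variance; the paired
statistic is reported as the squared standardised AUC difference on 1
degree of freedom, so that rank-equivalent scores give exactly
$\chi^2 = 0$. A degenerate zero variance at an AUC of 0 or 1 collapses the
interval to the point with a warning. Kaplan–Meier curves and the
$k$-sample log-rank test come from the survival package. Competing scores
(e.g. a diagnosis-based comorbidity index) are accepted as pre-computed
numeric columns; computing them is out of scope. The secondary outcome
(one-year hospitalisation) reuses the identical machinery through
`build_survival(..., outcome = "hospitalization")`.

## Problem sizes and test design

The test suite regenerates all data in code. Problem sizes were chosen
once: $n = 50{,}000$ per seed (10 seeds) for derivation recovery,
$n = 100{,}000$ for simulator calibration and end-to-end discrimination
checks, $n = 300{,}000$ for the CHAID population-scale check — large
enough for the stochastic tolerances involved, small enough that the whole
suite runs on a single CPU in well under half an hour. Two documented
expectations fail honestly under these study conditions rather than being
weakened: (i) derivation recovery of *all* conditions with prevalence
$\ge 2\%$ to $\pm 1$ weight — with only $\sim 1{,}200$ events the one-SE
rule regularises away true weight-2/3 conditions (at the development
cohort's scale, with roughly six times the events, it does not); and (ii)
true-score AUC $> 0.70$ on the default synthetic cohort, impossible under
flag independence as computed above.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_mcds_cohort(mcds_sim_params(n_patients = 20000, seed = 1))
prof <- mcds_profile(sim$claims, patients = sim$cohort$patient_id)
scores <- predict(mcds(), prof)
surv <- build_survival(sim$cohort, sim$outcomes)
mcds_validate(scores$score, surv)
```
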