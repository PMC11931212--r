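---
title: "A Markov cohort model for the lifetime burden of smokeless tobacco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the lifetime burden of smokeless tobacco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stburden)
```

## The problem and the model

Smokeless tobacco (chewing tobacco, snuff, gutka and similar products) raises
the risk of oral, pharyngeal and esophageal cancers, of stroke, and of
all-cause mortality. `stburden` estimates the *lifetime* health and economic
burden attributable to its use for a population: the healthcare costs, life
years and disability-adjusted life years (DALYs) that would be avoided if no
one used smokeless tobacco, given how people currently start, quit and relapse.

The engine is a prevalence-based Markov state-transition cohort model run in
annual cycles. Each 5-year age–sex cohort is followed from its entry age to
age 89 through 14 mutually exclusive states:

* **never user**,
* **current user**,
* ten one-year **tunnel states** counting years since quitting (a former user
  must pass through them in order, so risk and relapse can depend on time
  since quitting),
* a **long-term former** state (10+ years since quitting), and
* an absorbing **dead** state.

States describe tobacco use, not disease. Disease enters as age- and
sex-specific *population prevalence* of the four conditions, apportioned each
cycle across exposure classes (never / current / former 0–4 years / former
5–10 years / former 10+ years) using relative risks, such that the
share-weighted mean always reproduces the population value. The same
apportionment is applied to all-cause mortality. Two structural assumptions
follow the underlying evidence base: risk returns to the never-user level ten
years after quitting (the 10+ multiplier is exactly 1), and use has no effect
on mortality or disease below age 35.

The attributable burden is a scenario difference. The *status quo* run starts
the cohort at the observed use-state distribution and lets it evolve under
calibrated initiation, quit and relapse probabilities. The *no-use*
counterfactual keeps the whole cohort never-using. Life years gained, YLD
averted, DALYs averted (their sum) and costs saved are the discounted
differences between the two runs.

## Apportionment and the conservation contract

For an outcome with population rate $p$, exposure-class shares $s_k$ among the
alive and relative risks $m_k$ (never $=1$), the never-user rate is

$$ r_\text{never} = \frac{p}{\sum_k s_k m_k}, \qquad r_k = m_k \, r_\text{never}, $$

so $\sum_k s_k r_k = p$ identically. This conservation is the model's central
falsifiable contract: at every cycle the share-weighted status-specific
mortality equals the life table and the share-weighted disease prevalence
equals the input prevalence (the test suite asserts this to $10^{-10}$).
Published odds ratios are used directly as prevalence ratios in this
apportionment; for diseases at the prevalences involved (well under 5%) the
distinction is second order. Class rates are capped at 1 with a warning rather
than an error so extreme sensitivity-analysis draws cannot abort a run.

The population attributable fraction follows as
$\mathrm{PAF} = \sum_k s_k (m_k - 1) \, / \, (1 + \sum_k s_k (m_k - 1))$,
which equals $1 - r_\text{never}/p$; the tests check both routes against each
other.

## Mortality in the counterfactual

Each cycle of the status-quo run derives status-specific mortality from the
life-table probability at that age and the cohort's *own current* exposure
shares, so the cohort's overall mortality is anchored to the observed life
table by construction. The no-use counterfactual uses the never-user mortality
implied by that same apportionment (and, analogously, the never-user disease
prevalence). This choice makes the null model exact: if every relative risk is
1, the two scenarios coincide and the attributable burden is identically zero.
Using the raw population mortality in the counterfactual instead is available
via `st_config(no_st_mortality = "population")`; it makes the counterfactual
population carry some of the exposed group's excess risk and is not the
default.

## Calibrating initiation and quitting

Surveys provide cross-sectional never/current/former proportions in 5-year
bands, not transition probabilities. The calibrators treat the age profile as
a synthetic cohort: for each pair of consecutive bands they find the constant
annual initiation probability $i$ and quit probability $c$ such that the
model, run forward five one-year cycles from the current band's state (with
differential mortality and the relapse schedule), lands exactly on the next
band's observed never and former shares among the alive. The two
one-dimensional problems (never share is monotone in $i$, former share in $c$)
are solved by bracketed root-finding (`stats::uniroot`, tolerance $10^{-14}$)
and alternated to convergence; the projected 14-state vector is carried from
band to band, so the full age profile is reproduced, not just band-by-band
margins. Values are clamped to $[0,1]$ with a warning when a target is
unreachable (e.g. a never share that *rises* with age). Above the oldest
observed band both probabilities are held at their last calibrated values.

Because the same engine generates and fits the dynamics, the calibration is
exactly self-consistent: schedules used to generate synthetic banded
prevalence are recovered to better than $10^{-6}$, and the calibrated model
reproduces the observed prevalence table to well under 0.5 percentage points
(both asserted in the tests and recomputed by `scripts/acceptance.R`).

Relapse cannot be identified from a single cross-section and its magnitudes
are not part of the packaged evidence tables. The default schedule declines
geometrically with time since quitting, $r(t) = 0.10 \times 0.6^{t-1}$ for
tunnel years $t = 1..10$ with no relapse after 10 years — a high first-year
relapse decaying to near zero within a decade, the shape reported for tobacco
cessation generally. It is a configurable input (`default_relapse()`,
`write_schedule()`/`read_schedule()`), and the calibrated quit probabilities
absorb its level: doubling relapse raises calibrated quitting at every age
(tested), leaving the fitted prevalence path unchanged.

## Burden accounting

Within a cycle, death is resolved first and behaviour change applies to
survivors — the standard ordering in annual-cycle cohort models, and the one
that keeps mortality conservation exact. Costs and YLD accrue to the alive
occupancy at cycle start; there is no half-cycle correction, matching plain
annual prevalence-based accounting. Life years count the alive fraction per
cycle. Everything is discounted at 3% per annum (costs *and* outcomes), with
$t = 0$ at cohort entry; the cycle at age 89 is the last accounted one.

Unit costs are annual per prevalent case: one cancer cost applies to all
three cancers (the packaged cost table has a single cancer row per country),
while stroke blends a first-year (incident) and subsequent-year (prevalent)
cost with 10% of prevalent strokes assumed incident; the prevalent-stroke
cost is 10% of the incident cost. Disability weights are averages per
prevalent case by disease and coarse age group (15–49, 50–69, 70+), additive
across diseases. YLL is not computed against a standard life table: in a
two-scenario design the discounted life-year difference *is* the mortality
component of the DALYs averted, so DALYs averted $= \Delta LY + \Delta YLD$.

Entry-state attribution (who bears the burden?) propagates the never-,
current- and former-at-entry sub-cohorts through the *full cohort's* per-cycle
transition matrices — the Markov update is linear in the state, so the
entry-share-weighted sub-traces reconstruct the full trace exactly and the
decomposition of attributable cost is exact to rounding. Each sub-cohort is
compared against its own never-forever baseline. For young cohorts a large
share of the attributable cost falls on those who are never users at entry
but initiate later — the pattern that motivates uptake-prevention policy.

## Parameter uncertainty

The probabilistic sensitivity analysis redraws every uncertain parameter per
draw: relative risks from lognormals parameterised by the log-mean and its
standard error, disability weights and the incident-stroke fraction from
betas, unit costs from gammas, then reruns the deterministic pipeline and
summarises each output by the empirical 2.5th/97.5th percentiles of the
draws. Transition probabilities are held at their calibrated values — no
uncertainty distributions are available for them, a documented limitation.
Parameters are drawn independently.

Two numerical choices deserve note. First, structural constraints are
re-enforced after sampling: the 10+-years multiplier stays 1, and an
outcome's three sampled strata are redrawn until the ordering current ≥
former 0–4 ≥ former 5–10 ≥ 1 holds (the packaged lognormals overlap, so this
truncates their tails; the means of constrained parameters therefore sit
slightly above their unconstrained values — unconstrained parameters are
verified against their analytic means in the tests). Second, the packaged
gamma parameters printed for costs are inconsistent with the USD point
estimates (they appear to be on a different currency scale), so the default
samples costs as Gamma(shape 100, scale = point/100) — a 10% coefficient of
variation consistent with shape 100 — while the verbatim printed pairs remain
loadable with `default_distributions(gamma_mode = "table1")`.

All randomness flows through one seed; the whole PSA is bit-reproducible.

## The synthetic data generator

`synthetic_bundle()` produces a complete, validated country bundle with no
external data: Gompertz-increasing mortality (about $3\times10^{-4}$ at 15 to
0.15–0.19 at 89, male excess 20%), a never-user share declining monotonically
with age and a hump-shaped current-use curve (male levels roughly twice
female, peaking in middle age at ~25–30% for men), disease prevalence rising
with age (cancers a fraction of a percent, stroke a few percent at old age),
populations of about five million per 5-year male band declining 3% per year
of age, and the packaged risk/weight/cost/distribution tables. A 2%
multiplicative jitter keeps curves from being suspiciously smooth;
`current_use_scale = 0` produces an unexposed population whose attributable
burden is zero end to end.

The generator emulates the *shape* of survey, life-table and
burden-of-disease inputs, not any country's actual values. Passing tests
therefore demonstrate the internal correctness of the machinery —
conservation, calibration recovery, null-model zero, decomposition,
reproducibility — and plausible magnitudes, not the published estimates for
any real country, which require the original stratified input tables. With
the defaults the per-individual results for a 15-year-old male (about 0.14
life years gained, 0.14 DALYs averted, US$19 saved; recomputed by
`scripts/acceptance.R`) fall in the range reported for South Asian
populations.

## Problem sizes and numerical tolerances

The packaged analyses run 12 entry bands × 2 sexes to age 89 (75 annual
cycles for the youngest cohort); the acceptance script uses 200 PSA draws
over two cohorts, and the default config's 5000 draws remain practical for a
full analysis. Row-stochasticity of every transition matrix holds to
$10^{-12}$; trace mass conservation to $10^{-10}$; calibration root-finding to
$10^{-14}$ on the share scale; decomposition identities to $10^{-9}$ on the
dollar scale. Attribution shares are reported as `NA` (undefined) when the
total attributable cost is below $10^{-9}$ dollars rather than dividing by a
rounding residue.

## Known limitations

* Relapse magnitudes and the split of entering former users across tunnel
  years (uniform over years 1–10 by default; `former_split = "long"` or
  custom weights available) are structural defaults, not estimates.
* Odds ratios are used as prevalence ratios; fine for rare outcomes, coarser
  for stroke at old ages.
* Disease prevalence is treated as independent across diseases with additive
  disutility, and recovery is not modelled explicitly (it is embedded in the
  age profile of prevalence).
* Costs are healthcare costs per prevalent case only — no productivity or
  caregiver costs — and the same cancer cost applies to all three cancers.
* Transition probabilities carry no uncertainty in the PSA.

```{r example, eval = FALSE}
b <- synthetic_bundle(1)
sched <- calibrate_transitions(b)
burden_for_cohort(b, "male", "15-19", sched)
agg <- aggregate_country(b, sched)
autoplot(agg)
```
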