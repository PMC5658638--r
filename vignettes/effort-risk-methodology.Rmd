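---
title: "Scoring consumer effort in finding and paying for care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring consumer effort in finding and paying for care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortrisk)
```

## The problem and the model

Health-care consumers spend real work — "effort" — on administrative tasks
around care: getting claims paid, contesting denials, chasing adjustments,
discovering that a provider was out of network, and calling or visiting the
payer's portal to work any of this out. effortrisk quantifies that burden per
diagnosis so that payers can see which conditions drag their members through
the most administration, independent of clinical complexity.

The observation unit is the *household*: all members covered under one plan,
because one caretaker typically absorbs the administrative work for everyone
on the plan. Six countable effort factors are tallied per household over a
12-month window:

| factor | what is counted | weight (%) |
|---|---|---|
| calls | phone inquiries to the payer's contact center | 40 |
| denials | claim lines denied by the payer | 25 |
| web_mobile | web-portal plus mobile-app inquiries | 15 |
| out_of_network | claim lines from out-of-network providers | 8 |
| adjustments | claim lines that required reprocessing | 7 |
| household | distinct members with claims | 5 |

The weights are percentages of total effort elicited from a 12-member expert
panel (call agents, nurses, claims adjustors, data analysts) at a large US
payer; they must sum to 100 and are consumed as configuration
(`read_weights()`), never hard-coded, because another organization's panel
would weigh its own factors.

For each diagnosis code $c$ the pipeline computes the mean $\bar{x}_{c,f}$
of each factor $f$ over the households carrying $c$, and the effort-risk
score is the weighted sum

$$ S_c \;=\; \sum_{f} \frac{w_f}{100} \, \bar{x}_{c,f}. $$

Diagnoses are then ranked by $S_c$. The score is unitless; it is an ordering
device, not a cost estimate.

## Pipeline stages and their conventions

**Scoping** (`count_diagnoses()`, `select_top_coverage()`). One occurrence is
one code on one claim line, so a line carrying $k$ codes contributes $k$
occurrences and repeat codes across a household's claims all count — the
convention under which an extract's diagnosis occurrences outnumber its
claims severalfold. Analysis is restricted to the shortest
descending-frequency prefix of codes whose cumulative occurrence share first
reaches a threshold (default 0.80); ties in counts are broken by ascending
code string so the prefix is deterministic, and the achieved coverage is
reported to full precision (it is typically slightly above the threshold).
This keeps the common diagnoses that describe most households while dropping
rare codes whose carriers almost always also carry a common comorbidity.

**Aggregation** (`household_factor_counts()`, `per_diagnosis_averages()`).
All six factors are counted at household level. A household's whole-year,
whole-household counts are attributed *in full* to every code the household
carries: contact events carry no diagnosis, so inquiries cannot be
apportioned, and applying the same rule to the claim-side factors keeps all
six columns on the same observation convention. Denied and adjusted are
independent flags — a claim that is denied and then adjusted increments
both, since each is a distinct effort event. Out-of-network usage is counted
per flagged claim line (visits are not separately represented in a claims
extract). Household size is the count of distinct members with claims, per
the factor's definition, not plan enrollment. Medians are computed alongside
means (even-sized samples take the midpoint of the central pair) but play no
role in scoring; they are emitted for inspection.

**Scoring** (`effort_risk_score()`, `rank_diagnoses()`). Components
$w_f/100 \cdot \bar{x}_{c,f}$ are kept at full precision and the total is
their unrounded sum; two-decimal *half-up* rounding (`round_half_up()`) is
applied only when rendering. This is why a diagnosis whose components render
as 0.11, 0.36, 0.04, 1.78, 0.26, 0.26 can correctly total 2.80: the internal
sum is 2.8008. Ranking sorts by unrounded total, ties broken by ascending
code.

**Correlations** (`factor_correlations()`). Pearson correlations of the six
factor counts across households (Spearman optionally); the household is the
only unit where all six factors are jointly observed. Zero-variance factors
yield NA cells with a warning rather than a fabricated value. No causal
reading is attached: a denial may *lead to* an adjustment and a call, but
the factors are treated as distinct kinds of effort.

## The synthetic-claims generator

No claims extract can be shipped, so `simulate_claims()` generates one with
the statistical structure the analysis assumes and — crucially — a
closed-form ground truth for what the pipeline should estimate.

* **Households.** Sizes are $1 + \mathrm{Poisson}(\mu_s - 1)$ with
  $\mu_s = 2.5$ members by default (a realistic mean plan-household size).
* **Code carriage.** Each household carries code $c$ independently with
  probability $p_c \propto \mathrm{rank}(c)^{-z}$, scaled so the expected
  number of carried codes is 3; empty draws are redrawn. With $z = 1$ and a
  150-code vocabulary this reproduces the qualitative structure of real
  extracts, where a modest fraction of codes accounts for ~80% of all
  diagnosis occurrences.
* **Events.** Per carried code, yearly counts of the five event factors are
  independent Poisson draws with per-code means from `factor_rate_table`.
  The default table (`default_rate_table()`) spreads rates over ranges
  matching published per-diagnosis averages (denials 3–16/yr, out-of-network
  0.5–11.5/yr, ...) using a fixed golden-ratio sequence of the code's rank —
  deterministic, and spread without collinearity between factors. Factor
  draws are independent across factors by design: the expert panel's view
  was that effort on one factor does not imply effort on another.
* **Claims.** Every member files one ordinary unflagged base claim and every
  carried code appears on at least one line, so household size and carriage
  are observable even at zero event rates; each factor event becomes one
  flagged claim line (or one contact event, recorded with household id only,
  mirroring the real non-attribution of inquiries to diagnoses).

Because carriage is independent across codes, conditioning on carrying $c$
leaves the other codes' carriage probabilities unchanged, and the *attributed*
truth the pipeline estimates has the closed form

$$ m_{c,f} \;=\; r_{c,f} + \sum_{c' \neq c} p_{c'}\, r_{c',f}, $$

with the household-size truth equal to $\mu_s$ for every code
(`expected_scores()`). Note the estimand is not the per-code rate $r_{c,f}$:
whole-household attribution adds the expected contribution of co-carried
codes. For the same reason the synthetic per-diagnosis averages sit above
the published magnitudes (a household carrying three codes accumulates three
codes' worth of denials, all attributed to each); the generator is
calibrated for structure — skew, spread, attribution — not to reproduce any
published table's levels.

What the generator does *not* emulate: comorbidity correlation between
specific codes, seasonality, enrollment churn, cost amounts, or
diagnosis-targeted contact behaviour. Passing recovery tests therefore shows
the estimator is correct under the stated attribution convention, not that
real contact-center data meet it.

## Validation

* **Worked example and published table.** The package ships the published
  top-25 per-diagnosis averages (`reference_averages()`); scoring them with
  the default weights reproduces 23 of 25 printed totals exactly after
  half-up rounding, and the remaining two within 0.01 — the published totals
  were evidently computed from unrounded averages while the table prints
  averages at two decimals. One published component cell (denials 1.77 for
  knee dislocation, where $0.25 \times 7.11 = 1.7775$ renders 1.78) is
  internally inconsistent with half-up rounding and is documented as
  irreproducible; the total is not affected since totals never pass through
  rounded components.
* **Oracle equivalence.** On 200 randomized toy datasets (≤ 50 households),
  `count_diagnoses()` and `per_diagnosis_averages()` equal a deliberately
  naive rescan oracle exactly, and coverage selection equals a
  scan-all-prefixes oracle, including minimality and nestedness across
  thresholds.
* **Parameter recovery.** Simulating 50,000 households under the default
  configuration and running the full pipeline (including 0.80-coverage
  scoping, ~50 codes in scope), estimated per-code factor means fall within
  3 standard errors of the closed-form truth for ≥ 95% of (code, factor)
  cells, and the Spearman correlation between recovered and true effort
  scores exceeds 0.95 (observed ≈ 0.98). Codes outside the scoped set are
  carried by only a few hundred households at this scale; their means are
  unbiased but noisy, which is precisely why the scoping rule precedes
  aggregation.

Problem sizes used by the test suite (50,000 households for recovery, 200
toy datasets for oracle equivalence, 2,000 households for the skew property)
were chosen so the whole suite runs comfortably on a laptop while leaving
the statistical assertions well-powered.

## Numerical and design choices

* Half-up rounding is implemented with a $10^{-9}$ nudge before `floor` to
  absorb binary representation error (base `round()` rounds half to even and
  cannot reproduce printed tables).
* `select_top_coverage()` forces the final cumulative share to exactly 1 to
  guard against accumulated floating error at threshold 1.0, and compares
  against the threshold with a $10^{-12}$ slack.
* Weights must sum to 100 within $10^{-9}$; degenerate but legal sets (one
  factor at 100%) are accepted.
* Orphan contacts (household with inquiries but no claims) are retained with
  zero claim-side counts and a warning; scoped codes missing from the claims
  index are dropped with a warning. Both situations indicate upstream
  linkage problems that should be audible, not fatal.
* Stages communicate through documented plain-text formats (CSV/TSV/YAML),
  so every boundary can be inspected and independently re-tested; the
  one-shot `run_pipeline()` is byte-identical to composing the stages by
  hand.

## Limitations

The score inherits the expert panel's weights; different organizations
should elicit their own. Whole-household attribution deliberately smears
effort across a household's diagnoses, so a low-effort diagnosis frequently
co-occurring with a high-effort one will score high — this is a property of
the estimand, not a bug, but it forbids causal readings. One year of data
cannot distinguish chronic from incident burden. The synthetic generator
supports correctness claims about the pipeline, not claims about any real
population.
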