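---
title: "Measuring the economic burden of overseas medical treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the economic burden of overseas medical treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtoburden)
```

## The problem

When a health system cannot offer tertiary care, patients travel abroad for
treatment, typically accompanied by family caretakers. The episode is
financed from two sources: a government subsidy (covering direct medical
costs and the airfare of the patient and one caretaker, paid directly to
providers) and the household's own pocket. Quantifying this burden needs
three linked analyses: what one visit costs and who pays; whether the
household's health spending is *catastrophic* relative to its budget; and
what the country as a whole spends per year. `mtoburden` implements all
three on a common traveler-level data model, plus a calibrated synthetic
generator so the pipeline can be exercised and tested without confidential
microdata.

## Data model and categorical conventions

One row is one surveyed traveler (`survey_columns()` documents the CSV
schema): demographics, funding stratum (`subsidized` / `private`),
utilization (destination, length of stay, caretakers, visits per year), an
ICD-10 diagnosis code, twelve itemized cost columns split by payer, the
inputs of the productivity-loss formula, and the household's monthly
out-of-pocket spending on health, food and other items.

Money is held in integer cents internally (`as_cents()`), which makes sums
associative, payer splits exactly conservative, and CSV round-trips
bit-exact; values are rendered as USD with two decimals.

Continuous variables are collapsed to the analysis categories by
`categorize()`. Two conventions are the package's own, since only the class
labels are conventional in this literature:

* **Household size**: small = at most 5 members, medium 6–10, large over
  10. The boundary value 5 is placed in "small" so the classes partition.
* **Length of stay**: any started week counts as that week — at most 7 days
  is "&le;1 week", 8–14 days "2 weeks", 15–21 "3 weeks", 22–30 "1 month",
  longer ">1 month". (An alternative reading, nearest whole week, would
  put day 10 in week 1; we use the started-week rule so that "2 weeks"
  means 8–14 days.)

Income quintiles are sample-based: cut points at the 20/40/60/80% type-7
quantiles, boundary ties resolved downward so assignment is monotone in
income and independent of row order.

ICD-10 codes are mapped to the 22 major chapter blocks (shipped as a
plain-text table, `icd10_chapters()`). Chapter Z00–Z99 (contact with health
services rather than morbidity) is flagged ineligible for disease-profile
tables and `filter_disease_profile()` removes it together with missing
codes, reporting the omitted count; a missing code is a first-class
sentinel, never an error.

## Cost accounting

`visit_total_cost()` sums the twelve components over both payers.
Productivity loss is deliberately excluded everywhere from cost totals: it
is a loss of income, not an expenditure, and is reported in its own column.
`productivity_loss()` values it as
$(\text{hours lost per day} / 8) \times \text{days abroad} \times
\text{income per day}$; the 8-hour working day converts reported hours into
a wage fraction (the raw three-way product of hours, days and a *daily*
wage would be dimensionally inconsistent), and the divisor is configurable
via `workday_hours`.

Per-capita allocation (`per_capita_costs()`) uses the one structural fact
available — caretakers bear no medical costs — and otherwise the minimal
assumption that shared non-medical costs split equally over the party of
$k+1$. Whether a real survey's per-capita figures attributed shared costs
this way is not documentable from published summaries; equal split is our
choice and the identity $M + (k+1)\,\mathrm{caretaker}_{pc} = \text{total}$
is enforced by test.

Mean component shares (`component_shares()`) are means of per-traveler
ratios, not ratios of means: the share statistic should be scale-free so a
single expensive traveler cannot dominate it.

## Catastrophic health expenditure

With budget share $s_i$ = monthly health spending over total monthly
expenditure and threshold $z = 0.10$:

$$H = \frac{1}{n}\#\{i : s_i > z\}, \qquad
O = \frac{1}{n}\sum_i \max(s_i - z, 0), \qquad
MPO = O/H .$$

Exceedance is strict ("in excess of" the threshold); a `strict = FALSE`
mode gives $\ge$ for sensitivity analysis. $z + MPO$ equals the mean budget
share among exceeders — an algebraic identity the test suite checks
exactly, along with monotonicity of $H$ and $O$ in $z$ and equivalence to a
brute-force oracle on small vectors. $MPO$ is undefined (NA, flagged) when
no household exceeds.

The denominator is the routine monthly budget (health + food + other). The
overseas episode's out-of-pocket cost is *not* amortized into the month:
there is no defensible amortization rule without knowing the episode's
financing horizon, and mixing a one-off episode into a monthly denominator
would make $H$ an artifact of that choice. This materially affects $H$, so
it is a documented mode boundary rather than a hidden guess.

## National extrapolation and the bootstrap

Annual cost per stratum is $c = a \times b$: $a$ the median per-capita cost
per visit from the survey (patients and caretakers separately), $b$ the
annual visit count. Patient visit counts come from administrative registers
and are **inputs, never estimated**; caretaker visits are derived as
round-half-up(mean caretakers × patient visits). The product is exact in
cents. Totals are expressed against GDP (default $1{,}431$m) and population
(default 336,224).

Uncertainty: visit counts are treated as fixed, so the only sampled
quantity is the median. `bootstrap_se()` draws $B = 1000$ resamples of size
$n$ with replacement, recomputes median × visits, and reports the SD across
replicates. $B$ defaults to 1000 — enough that the bootstrap-SE's own MC
error is well below the sampling error it measures. The suite verifies the
estimator against the asymptotic formula
$\mathrm{SE}(\hat m) \approx 1/(2 f(m) \sqrt n)$ on log-normal samples;
because a single sample's bootstrap SE fluctuates around the asymptotic
value with relative SD of order $n^{-1/4}$ (about 20% at $n = 344$), the
check averages over 10 independent samples so that it compares the
estimator's expectation, not one sample's noise, at a 15% tolerance.

## The synthetic generator: what it emulates, and what it does not

`survey_config()` fixes the study conditions: 344 subsidized and 471
private travelers; per-stratum cost components with median/IQR targets
(subsidized itemized by payer, e.g. subsidy medical 500 (106.25–1462.5),
oop airfare 400 (336–672); private combined-travel target split into home
travel / airfare / destination travel medians 180/750/120, consistent with
home-country travel costing more than destination travel on average);
caretaker party sizes shifted-Poisson with means 2.3 / 3.3; a 43%
catastrophic incidence target at $z = 0.10$. A fully populated YAML of the
same defaults ships in `inst/extdata/survey_config.yaml` and round-trips
through `read_survey_config()`.

Calibration choices, made once from the targets:

* **Skewed costs** are log-normal — the minimal two-parameter family for
  strictly positive, highly skewed spending. `lognormal_from_median_iqr()`
  sets $\mu = \log(\text{median})$, $\sigma = \log(q_3/q_1)/(2 \times
  0.67449)$; the quartile *ratio* is reproduced exactly, each quartile
  exactly when the printed IQR is log-symmetric.
* **Zero-heavy components** (a printed first quartile of 0, or a median of
  0) are Bernoulli($\pi_0$) zero + log-normal. When the median is positive
  the positive part is solved so the *overall* median and $q_3$ hit the
  targets exactly ($\pi_0 = 0.3$); components printed as 0 (0–0), such as
  visa and foreign-exchange fees, get $\pi_0 = 0.9$ with a nominal
  positive tail.
* **Household budget shares** come from a two-component Beta mixture —
  Beta(1.2, 25) for routine households, Beta(3.5, 8.5) for health-burdened
  ones — with the mixture weight solved numerically so the exceedance
  probability at $z$ equals the configured incidence. The shape parameters
  were chosen so the mean share among exceeders is ≈ 28%. An incidence
  outside the two components' exceedance range is a configuration error.
* **Dispersion families** for caretaker counts (shifted Poisson) and
  budget totals (log-normal, median $1000/month) are conventions; no
  dispersion information is available to calibrate them, and they are
  recorded in the config for exactly that reason.

All randomness flows from one root seed through named per-component
streams (`stream/stratum/component`), so the generator is a pure function
of its config and adding a component never perturbs the draws of another —
both properties are under test.

What the generator does **not** emulate: dependence between disease
chapter and cost (chapters are drawn independently of spending; per-chapter
cost tables are outputs, not calibration constraints), joint dependence
between demographics and diagnosis (so, e.g., pregnancy codes are not
restricted by sex or age), recall error, and non-response. Emergent
aggregates are consequences of the component calibration rather than
targets — e.g. the median per-capita episode total comes out near $1300
under the defaults, and the overall travel mean share near 48–51% across
seeds. Passing tests therefore demonstrate that the *statistics* are
computed correctly on data with the right marginal structure, not that the
generator reproduces every joint feature of a real survey.

## Statistical tests

* `rank_sum_test()`: Wilcoxon–Mann–Whitney with mid-ranks. For small
  samples (up to 40,000 enumerable group assignments) the p-value is the
  exact two-sided permutation probability of the U statistic — valid under
  ties, and exactly reproducible by independent enumeration; beyond that,
  the normal approximation with continuity correction (the two agree to
  well under 0.01 at the sizes where they hand over).
* `chi_square_test()`: Pearson, no continuity correction, df =
  $(r-1)(c-1)$; a zero expected count is an error recommending category
  merge.
* `trend_test()`: Cuzick's rank test across ordered groups — chosen as the
  standard non-parametric trend test for ordered categories (income
  quintiles, household-size classes); statistic $T = \sum_j l_j S_j$ with
  tie-corrected variance, two-sided normal p. Its null calibration
  (rejection ≈ 5%) and agreement with its own permutation distribution are
  under test.

Quantiles use linear interpolation (R type 7) throughout; percentages are
rendered to one decimal. Two-sided p-values; the 5% level is reported,
never used to drop rows.

## Problem sizes in the test suite

Calibration checks run at 20,000 generated records, the bootstrap oracle at
$n = 344$, $B = 2000$ over 10 samples, and null-calibration loops at 500
simulations — sizes at which binomial/MC error bands are tight enough to be
meaningful while the whole suite completes in well under a minute.

## Known limitations

* Visit-count inputs carry no uncertainty; the bootstrap covers only the
  sampled medians.
* Equal splitting of shared costs and the 8-hour working day are
  conventions, configurable but not estimable from the data model.
* The catastrophic denominator excludes the episode itself (see above);
  analyses wanting an amortized denominator must construct it explicitly.
* Block-level ICD-10 handling only: codes are validated to letter+digits
  and chapter ranges, not against a full 4-character code catalogue.
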