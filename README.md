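# mtoburden

Economic-burden analysis of overseas medical treatment (MTO) from
traveler-level household survey data.

Small island states often cannot provide tertiary care at home, so patients
travel abroad — usually with accompanying caretakers — and the episode is
paid partly by a government subsidy (direct medical costs and airfare) and
partly out of the household's pocket. `mtoburden` implements the full
analysis pipeline for such a survey:

* **Cost accounting per visit** — itemized cost components (direct medical,
  travel, lodging, food, ...) split by payer (subsidy vs out-of-pocket),
  with per-capita allocation over the travel party: caretakers bear no
  medical costs, so with medical cost *M*, non-medical cost *G* and *k*
  caretakers, `caretaker_pc = G/(k+1)` and `patient_pc = M + G/(k+1)`.
  Productivity loss `(hours lost/8) × days abroad × daily income` is
  reported separately, never inside cost totals. All money arithmetic is
  exact in integer cents.
* **Catastrophic health expenditure** — with household health budget share
  *s<sub>i</sub>* and threshold *z* (default 10%):
  headcount *H* = fraction with *s<sub>i</sub>* > *z*;
  overshoot *O* = mean of max(*s<sub>i</sub>* − *z*, 0); mean positive
  overshoot *MPO* = *O*/*H*, so *z* + *MPO* is the exceeders' mean budget
  share. Subgroup tables by funding stratum, region, household size and
  income quintile with chi-square tests.
* **National extrapolation** — per stratum (patients and caretakers in each
  funding group), annual cost *c* = *a* × *b* where *a* is the median
  per-capita cost per visit from the survey and *b* the annual visit count
  from administrative registers (caretaker visits = mean party size ×
  patient visits); totals expressed as a share of GDP and per head of
  population, with bootstrap standard errors (resample the per-capita cost
  sample, recompute `median × visits`, take the SD over replicates).
* **A calibrated synthetic survey generator** — two funding strata
  (344 subsidized / 471 private), log-normal cost components calibrated to
  median/IQR targets, zero-inflated components for rarely-incurred costs,
  and household budget shares from a Beta mixture whose exceedance
  probability at *z* is solved numerically to hit a configured catastrophic
  incidence (default 43%). Everything is seeded through named independent
  streams, so runs are bit-reproducible.
* **Non-parametric tests** — rank-sum (exact permutation for small samples,
  normal approximation beyond), Pearson chi-square, and Cuzick's rank test
  for trend across ordered groups.

## Worked example

```r
library(mtoburden)

records <- generate_survey(survey_config(seed = 42))   # 815 travelers

catastrophic_stats(health_share(records), z = 0.10)
#> Catastrophic health expenditure (z = 10%, n = 815)
#>   headcount H   : 41.3%
#>   overshoot O   : 7.7 points
#>   MPO (O/H)     : 18.7 points (exceeder mean share 28.7%)

econ <- economic_cost_table(records, visits_subsidized = 3546,
                            visits_private = 15462, B = 1000, seed = 42)
econ$strata[, c("label", "median_pc", "visits", "annual_cost", "se")]
#>                   label median_pc visits annual_cost     se
#> 1   subsidized-patients   2085.86   3546     7396460 707719
#> 2 subsidized-caretakers    682.77   8061     5503809 183097
#> 3      private-patients    1006.29  15462    15559101 526049
#> 4    private-caretakers     552.63  50982    28173673 991705
econ$totals$total_cost
#> [1] 56633043
```

41.3% of the simulated households exceed the 10% threshold (the generator's
configured incidence is 43%; the difference is binomial sampling noise at
n = 815), and those households devote on average 28.7% of their monthly
budget to health. The extrapolation multiplies each stratum's median
per-capita cost by its annual visit count: here an annual burden of about
$56.6m, with bootstrap SEs alongside each stratum (visit counts are treated
as fixed administrative inputs).

Reading real data instead of simulating: `load_survey("survey.csv")`
validates each row against the documented schema (`survey_columns()`) and
collects invalid rows with reasons in the `"rejected"` attribute. A thin
command-line front end over the same functions ships in `inst/cli/mto.R`
(`simulate`, `costs`, `catastrophic`, `extrapolate`, `report` subcommands).

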