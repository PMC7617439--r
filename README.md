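# lifegap

Life expectancy and years-of-life-lost for a diagnosed-exposure group
versus matched comparators in primary-care-style electronic health
records.

Routine primary-care databases record diagnoses, registration windows and
deaths for millions of people. For a condition diagnosed in such records —
the motivating case is adult ADHD in UK general practice — `lifegap`
answers the question *how many years of life does the diagnosed group
lose?* by chaining the standard epidemiological machinery:

1. **Exposure-density matched cohort.** Each diagnosed adult enters at the
   latest of diagnosis date, practice quality date, registration + 6
   months, practice data start, study start and 18th birthday (no immortal
   time), and exits at the earliest of death, deregistration, practice
   data end and study end. Ten comparators per exposed person are sampled
   from the risk set at the entry date, matched on practice, sex and year
   of birth, and assigned the same entry date.
2. **Lexis person-time.** Follow-up `[entry, exit)` is split at birthdays
   into single-year-of-age strata (18–100, older ages pooled at 100);
   person-years are days/365.25 and the death day belongs to the stratum
   containing `exit − 1`.
3. **Poisson rate smoothing.** Stratum deaths `D_x ~ Poisson(P_x m(x))`
   with `log m(x) = β0 + β1 z + β2 z²`, `z = (age − 50)/10`, and a log
   person-time offset; one fit per group × sex. A joint model with an
   exposure indicator gives the age-adjusted mortality rate ratio (the
   crude ratio is reported alongside).
4. **Period life table** (ONS complete-table style): `q_x = m_x / (1 +
   (1 − a) m_x)` with `a = 0.5`, radix 100 000 at age 18, terminal closure
   `L₁₀₀ = l₁₀₀/m₁₀₀`; reported life expectancy is total, `18 + e₁₈`.
5. **Parametric bootstrap.** Coefficient draws from the fitted model's
   asymptotic normal distribution are pushed through the life table;
   percentile intervals for life expectancy and (via paired draws) for
   years of life lost.

A seeded synthetic generator with a Gompertz hazard `m(x) = a·exp(bx)`
and a configurable exposure rate ratio stands in for licensed databases,
so the whole pipeline is testable against numerically integrated truth.

## Worked example

A synthetic matched study: 60 practices × 3000 persons, 2% diagnosed
prevalence, generating hazard ratio 2, 1:10 matching.

```r
library(lifegap)
cfg <- pipeline_config(
  output_dir = "lifegap-demo",
  sim = sim_config(n_practices = 60, persons_per_practice = 3000,
                   exposure_prevalence = 0.02, exposure_rate_ratio = 2,
                   birth_year_range = c(1935, 1975), seed = 1),
  match_ratio = 10, n_sim = 1000, match_seed = 2, sim_seed = 3)
res <- run_pipeline(cfg)
print(res$report)
print(res$fit)
```

```
Cohort build report
  exposed identified:            2374
  excluded, no diagnosis date:   0
  excluded, too few matches:     516
  exposed included:              1858
  comparison included:           18580
  (exposed with zero follow-up:  1141)
Life-expectancy gap model
  strata: 332 cells, 1279 deaths, 153934 person-years
  LE comparison.female     84.94 (81.26-98.05)
  LE comparison.male       83.11 (81.44-85.89)
  LE exposed.female        75.04 (66.57-85.48)
  LE exposed.male          75.55 (71.75-82.17)
  YLL female                9.90 (-1.22-26.39)
  YLL male                  7.56 (0.86-12.14)
  MRR female                2.15 (1.59-2.90) adjusted; 2.05 crude
  MRR male                  2.00 (1.68-2.38) adjusted; 1.90 crude
```

Reading the output: the build report traces the exclusion flow (exposed
persons whose within-practice risk set could not supply ten comparators
are dropped and counted). Total life expectancy at 18 in the unexposed arm
sits near the generating truth of 82.67 years (`gompertz_le(3e-5, 0.09)`),
the exposed arm near the doubled-hazard truth of 75.07, so the years of
life lost land near the true 7.6; the age-adjusted mortality rate ratios
recover the generating ratio of 2. The female intervals are wide because
the 2%-prevalence exposed arm is small and mostly male, leaving few female
deaths — exactly the behaviour such a study shows on real data.

The pipeline writes full-precision interchange files (`cohort.csv`,
`strata.csv`, `rates.csv`, `fits.json`, `lifetable.csv`,
`estimates.json`), a markdown report with baseline, death and rate tables,
and a `MANIFEST.json` with the configuration fingerprint. Each stage is
also exposed directly: `simulate_ehr()`, `build_cohort()`,
`tabulate_strata()`, `crude_rates()`, `lifegap()` (the central model
object, with `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/
`residuals` methods), `le_interval()`, `yll_interval()` and
`estimate_mrr()`. A thin CLI lives at `exec/lifegap`
(`lifegap run --config config.yaml`, plus `simulate`, `build-cohort`,
`person-time`, `fit`, `life-expectancy`, `validate`).

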