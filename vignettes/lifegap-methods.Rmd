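---
title: "Estimating life-expectancy deficits from matched primary-care cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating life-expectancy deficits from matched primary-care cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifegap)
```

## The problem

How many years of life does a diagnosed condition cost? For conditions
recorded in primary-care databases — the motivating case is adult ADHD in UK
general practice — the question can be answered from routinely collected
records: identify diagnosed adults, follow them and matched undiagnosed
comparators until death or censoring, estimate age-specific mortality rates
in each group, and convert those rates into period life tables. The
difference in total life expectancy between the comparison and exposed
groups is the years-of-life-lost (YLL) attributable, descriptively, to
carrying the diagnosis.

`lifegap` implements that pipeline end to end. Because the licensed
databases it targets cannot be redistributed, the package ships a seeded
synthetic generator that reproduces the *structure* of such data with a
known generating hazard, so that every stage — matching, person-time
splitting, rate modelling, life tables, confidence intervals — can be
validated against closed-form or numerically integrated truth.

## The estimator

Deaths in each stratum (group $g$, sex $s$, single year of age $x$ from 18
to 100) are modelled as

$$D_{x} \sim \text{Poisson}\big(P_{x}\, m(x)\big), \qquad
  \log m(x) = \beta_0 + \beta_1 z + \beta_2 z^2, \quad z = (x - 50)/10,$$

where $P_x$ is person-years of observation (entering as a log offset).
Rates are expected to vary smoothly with age, and the smooth model borrows
strength across sparsely observed ages. The fitted rates $\hat m_x$ feed a
complete period life table:

$$q_x = \frac{m_x}{1 + (1-a)\,m_x}, \qquad
  l_{x+1} = l_x (1 - q_x), \qquad
  L_x = l_{x+1} + a\, d_x,$$

with $a = 0.5$ (deaths occur on average halfway through the year of age),
radix $l_{18} = 100\,000$, terminal age 100 closed by $L_{100} =
l_{100}/m_{100}$ (constant hazard beyond the open interval), and
$e_{18} = T_{18}/l_{18}$. Reported life expectancy is the *total* expected
length of life, $18 + e_{18}$. YLL is the comparison-minus-exposed
difference of totals. Uncertainty is propagated by a parametric bootstrap:
coefficient triples are drawn from
$\mathcal N(\hat\beta, \widehat{\mathrm{Cov}}(\hat\beta))$, each draw is
pushed through rate prediction and the life table, and percentile intervals
of the resulting life expectancies (and of their paired differences, for
YLL) are reported. Mortality rate ratios come from a joint Poisson model
with an exposure indicator next to the same age terms; the crude
(deaths/person-years) ratio is reported alongside, labelled, because
published analyses do not always say which variant they print.

## Cohort construction

Entry into the exposed arm is the **latest** of: the exposure diagnosis
date, the practice's data-quality date, registration plus six calendar
months, the practice's first data-contribution date, the study start
(2000-01-01 by default) and the 18th birthday. Starting exposed follow-up
at diagnosis excludes immortal time — a diagnosed person cannot have died
before the diagnosis that put them in the cohort. Exit is the **earliest**
of death, deregistration, the practice's last contribution date and the
study end (2019-01-16 by default).

Comparators are drawn by exposure-density sampling: at each exposed
person's entry date, `match_ratio` (default 10) persons are sampled
uniformly from the risk set — same practice, sex and year of birth, not
diagnosed on or before that date, and observable at it under their own
(unexposed-rule) eligibility window — and assigned the same entry date.
Design choices the source material leaves open, each configurable:

* **Comparators diagnosed later** are censored as comparators at their
  diagnosis date and, if eligible, head their own exposed set from that
  date. This keeps the exposure-density logic consistent: a person's
  pre-diagnosis time is unexposed time.
* **Without replacement globally**: a person serves as comparator in at
  most one set, keeping comparison person-time non-overlapping.
* **Strictness**: the minimum acceptable risk set (`min_matches`) defaults
  to the full ratio; exposed persons with smaller risk sets are excluded
  and counted, mirroring the "too few matched comparison participants"
  exclusion reported in real studies, whose exact threshold is unstated.
* **"+6 months"** is calendar-month addition with day-of-month overflow
  clamped to month end.
* Candidate lists are sorted by person identifier before seeded sampling,
  so matching is reproducible and order-independent.

Exposed persons with an empty eligibility window (for example, death on the
entry date) are counted in a diagnostics tally, separate from the two
reported exclusion reasons, so the inclusion identity
`included = identified - no_date - insufficient` always holds exactly.

## Person-time

Follow-up windows are half-open, `[entry, exit)`. Each window is split at
successive birthdays; every day is attributed to the age attained that day.
Because only the year of birth is carried (as in the motivating database),
the working date of birth is 1 July of the birth year — at most a six-month
error, identical for matched persons since matching is on birth year. The
death day is attributed to the stratum containing `exit - 1` day, which
keeps a death on a birthday inside the interval actually lived and avoids
zero-length death segments. Person-years are days divided by 365.25, a
single constant used everywhere. Ages above 100 are pooled into the
age-100 stratum. Conservation — stratum person-years summing exactly (to
1e-9 years) to raw window lengths, stratum deaths summing to cohort
deaths — is asserted in the test suite at member and cohort level.

## Numerical choices

* **Age transformation.** The quadratic is fitted in $z = (x-50)/10$ for
  conditioning; a property test refits with $z' = x/100$ and checks the
  predicted rates agree to 1e-8 relative, so the parameterisation is
  immaterial.
* **Zero person-year strata** carry no likelihood information and are
  dropped from the fit.
* **The IRLS tolerance** is 1e-10 relative change with at most 100
  iterations; unconverged fits are flagged and refused downstream.
* **The q conversion is capped at 1.** For $a<1$ the textbook formula
  exceeds 1 once $m$ is large; ordinary fits never get there, but extreme
  bootstrap draws from sparse arms do, and the cap keeps every draw's table
  valid ($0 \le q \le 1$ is an invariant).
* **Zero rates are legal** at non-terminal ages (the zero-hazard limit
  gives total life expectancy of exactly 101 under the terminal
  convention); the terminal rate must be positive while survivors remain.
* **Coefficient draws** use a symmetric eigenvalue factorisation with
  eigenvalues in $[-10^{-10}, 0]$ clipped to zero; more negative values are
  an error. Draws whose life expectancy is non-finite (overflowing rates
  from near-degenerate fits) are rejected and counted; more than 1%
  rejections aborts the analysis rather than silently reporting a
  truncated distribution.
* **Defaults the source material does not fix:** 1000 bootstrap draws and
  percentile intervals. Both are configurable; the exposed and comparison
  groups are drawn independently (they are fitted separately) and paired
  by draw index for the YLL difference.
* **Rounding** (half away from zero, two decimals for percentages) happens
  only in the reporting layer; every interchange file carries full
  precision.

## The synthetic generator

The generator emulates the features of primary-care records that the
analysis actually consumes: practices with data-quality and contribution
windows; persons with year-of-birth only, registration churn (exponential
waiting time, independent of death), an optional exposure diagnosis (age
drawn uniformly between 6 and 40 by default), baseline condition flags
recorded at registration, and a Townsend deprivation quintile carried as a
descriptive field. Mortality follows a Gompertz hazard
$m(x) = a\,e^{bx}$, multiplied by `exposure_rate_ratio` from the diagnosis
age onward; death ages are drawn by exact inversion of the piecewise
cumulative hazard, so a person who dies before their would-be diagnosis is
automatically sampled from the unexposed portion and is never diagnosed.
The defaults $a = 3\times10^{-5}$, $b = 0.09$ put unexposed total life
expectancy near 80 years ($\int_{18}^{\infty} S(x)/S(18)\,dx + 18 =
82.67$, available exactly via `gompertz_le()`); they are defaults, not
claims about any population. The exposed arm defaults to 78% male,
matching the strong male skew of diagnosed ADHD; the unexposed arm to 50%.
One root seed spawns per-practice child streams keyed to the practice
identifier, so generated tables are invariant to the order in which
practices are processed and byte-identical across runs.

What the generator deliberately does **not** emulate: calendar trends in
diagnosis incidence (real diagnosis years cluster in particular decades),
cause of death, clinical coding, socioeconomic confounding, or any
dependence between deprivation, conditions and mortality. Passing tests
therefore demonstrate that the *pipeline arithmetic and inference* are
correct under the stated hazard model — not that the model captures every
feature of real primary-care data.

## Validation studies and problem sizes

The test suite validates the pipeline at sizes chosen to balance
statistical resolution against a single-CPU run:

* life-table columns against an independently coded naive recursion, 100
  random rate vectors, agreement to 1e-10;
* coefficient recovery and deviance nesting on model-true strata;
* a 200 000-person unexposed cohort whose pipeline life expectancy must
  land within 0.5 years of the integrated generating truth (the two sexes
  receive identical hazards, so they are pooled for this comparison);
* 20 replicated studies with generating rate ratio 2.0 and at least 500
  exposed deaths each, requiring the joint-model 95% CI to cover 2.0 in at
  least 17;
* 50 replicated cohorts checking that the 95% life-expectancy interval
  covers the integrated truth with empirical coverage between 0.90 and
  0.99.

## A short example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  output_dir = "lifegap-demo",
  sim = sim_config(n_practices = 60, persons_per_practice = 3000,
                   exposure_prevalence = 0.02, exposure_rate_ratio = 2,
                   birth_year_range = c(1935, 1975), seed = 1),
  match_ratio = 10, n_sim = 1000, match_seed = 2, sim_seed = 3)
res <- run_pipeline(cfg)
summary(res$fit)
plot(res$fit)
```

The same stages are available piecewise (`simulate_ehr()`,
`build_cohort()`, `tabulate_strata()`, `lifegap()`) and from the shell via
the `exec/lifegap` script (`run`, `simulate`, `validate`, ... subcommands
reading a YAML configuration).

## Known limitations

The quadratic-in-age log rate is an assumption, not a theorem: hazards
with genuine curvature beyond quadratic (for example strong young-adult
excess mortality from external causes) will be smoothed through, and the
package deliberately offers no splines or overdispersion variants. The
bootstrap reflects sampling uncertainty of the Poisson fit only — not
matching variability or generator-level design uncertainty. Small exposed
arms (a handful of deaths) produce near-degenerate fits; the pipeline
refuses them loudly rather than reporting meaningless intervals. Matched
comparators are sampled from the same practices as exposed persons, so
practice-level mortality recording differences cancel by design, but
nothing in the package addresses confounding by indication or by
socioeconomic status — deliberately so, since deprivation may lie on the
causal pathway between diagnosis and mortality.
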