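---
title: "Methods: a lifetime Markov cost-utility model of cryoballoon vs radiofrequency ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model of cryoballoon vs radiofrequency ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcua)
```

## The decision problem

Catheter ablation is the standard rhythm-control intervention for
paroxysmal atrial fibrillation (AF). Two modalities compete: point-by-point
radiofrequency ablation (RFA) and single-shot cryoballoon ablation (CBA).
Their clinical performance is similar; their prices and downstream
consequences (recurrence, re-intervention, complications, stroke) are not.
`afcua` implements a cost-utility comparison of the two from a
health-system perspective: a cohort of 50-year-old patients is followed
over its remaining lifetime in a discrete-time Markov model with one-year
cycles, and each strategy is summarised by its discounted lifetime cost
(2019--20 USD) and quality-adjusted life years (QALYs). The strategies are
compared through the incremental cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta E$ against a willingness-to-pay
threshold of $\lambda$ = \$7,142 per QALY (one GDP per capita for the
study setting, with $2\lambda$ = \$14,285 as a secondary threshold), or
equivalently through the incremental net monetary benefit
$\lambda\,\Delta E - \Delta C$.

## Model structure

Both arms share one structure; only parameter values differ.

* **AF pre-intervention** -- the whole cohort starts here at cycle 0. The
  index ablation happens within this cycle: the procedure cost, the
  probability-weighted complication costs and disutility, and operative
  mortality are applied here.
* **NSR** -- normal sinus rhythm after a successful index ablation.
  Relapse (`p_recur_late` per year) returns the patient to the
  re-intervention tunnel.
* **AF post-intervention** -- a one-cycle *tunnel*: everyone who recurs
  (in the first year, `p_recur_y1`, or later from NSR) passes through it
  exactly once. During that cycle the single permitted re-intervention is
  applied with probability `p_redo_rfa + p_redo_cba`, split between the
  two modalities, each charging its own procedure cost and applying its
  own complications, operative mortality and first-year recurrence.
* **NSR after re-ablation** -- sinus rhythm restored by the
  re-intervention. Behaves like NSR (same cost, utility, relapse rate)
  except that relapse leads to terminal medicated AF: third ablations are
  not modelled.
* **AF post-re-intervention** -- terminal medicated AF, for failed
  re-ablations, patients never re-ablated, and relapses after a
  re-ablation.
* **Post-stroke** -- entered from any AF state at `p_stroke` per year;
  an acute case fatality (`p_stroke_death` = 0.3536) is applied at entry,
  the entry cycle carries the first-year stroke cost and disutility, and
  survivors stay in the chronic post-stroke state.
* **Death** -- absorbing. Background age-specific mortality from the life
  table applies from every living state.

Two NSR copies are one more state than the published five-plus-death
description. The duplication is what lets a memoryless cohort enforce the
stated *single* re-ablation rule exactly: with a single NSR state, either
every relapse re-enters the re-intervention tunnel (which triples the
discounted number of re-interventions per patient, from 0.31 to 0.89, and
inflates both arms' costs and QALYs by roughly 11%), or no late relapse is
ever re-treated (which understates re-intervention in the higher-recurrence
RFA arm and biases the comparison). Both one-state alternatives were
examined during calibration and rejected.

### Competing risks within a cycle

All exits from a living state in a cycle (background death, operative
death, stroke onset) are combined on the rate scale: each annual
probability $p$ is converted to a constant hazard $r = -\log(1-p)$, the
hazards are added, the total exit probability is $1 - e^{-\sum r}$, and it
is allocated across causes in proportion to their hazards. This keeps
every transition row exactly stochastic whatever the parameter values.
Rows are validated to sum to 1 within $10^{-9}$ at every cycle, and the
death column is checked to be non-decreasing along every trace.

### Reward timing and discounting

State rewards (annual cost and utility) are accrued **at the end of each
lived cycle** by default (`settings$reward_timing = "end"`): the year
spent in a state counts once it has been lived, so the notional cycle-0
year "in AF before the procedure" -- the procedure actually happens at
time zero -- accrues no state reward. One-off event rewards (procedure
bills, complication disutilities, first-year stroke cost) are charged in
the cycle the event occurs; the index procedure is therefore undiscounted.
Costs and QALYs are both discounted at 5%/year with
$df(t) = (1+r)^{-t}$, cycle 0 undiscounted.

The start-of-cycle convention (every occupied cycle 0..T accrues, the
classical "count the cohort where it stands" rule) is available as
`reward_timing = "start"`; it values the cohort's lifetime about one
undiscounted year higher in both arms and leaves the incremental
comparison nearly unchanged. An optional half-cycle correction
(`half_cycle_correction = TRUE`) halves the first and last accruing cycle;
it is off by default, as nothing in the source analysis indicates one was
used.

### Horizon

"Lifetime" is realised as one-year cycles until the cohort reaches the
life table's terminal age (where the annual death probability is 1),
capped at 60 cycles. At a 5% discount rate and with death absorption the
cap is numerically irrelevant: from age 50 with a table ending at 100 the
model runs 50 cycles.

## Parameters

All base values, standard deviations and distribution families are the
published ones: beta distributions for probabilities, utilities and
disutility magnitudes, gamma for costs; `table1_bundle()` returns the set
and `inst/extdata/table1.yaml` is the same set as a configuration file.
Two typographic slips in the source table are corrected: the
re-intervention-with-CBA probability of the CBA arm is read as 0.0951
(printed with a doubled decimal point), and the phrenic-palsy cost takes
the default cost SD rather than the pericardial row's SD printed beside
it.

Where the source leaves an SD blank (complication probabilities, the
stroke rate, the two mortality parameters, the vascular and phrenic
complication costs, the disutilities) a **default-SD policy** applies:
20% of the mean for beta-distributed quantities, 10% for costs. Both
fractions are settings (`default_sd_probability`, `default_sd_cost`).

Distributions are fitted by the method of moments:
$\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$ for the beta
family; shape $= m^2/s^2$, scale $= s^2/m$ for the gamma family. Fitting
followed by moment recomputation is tested to be the identity to
$10^{-9}$ relative. Negative-mean quantities (disutilities) are sampled on
the magnitude and negated.

Deterministic sensitivity ranges default to base $\pm 2$ SD, clipped to
each parameter's domain -- a deliberately wide interval -- and can be
overridden per parameter in the configuration file. The discount rate's
range is 0--0.1.

## Background mortality: the synthetic life table

The model needs an age-indexed table of annual death probabilities. The
shipped default, `generate_life_table()`, is a **synthetic stand-in**, not
transcribed national data: a Gompertz hazard
$q(a) = 1 - \exp(-c\,e^{b (a - 50)})$ anchored so that $q(50) = 0.0037$
(the published value for the 50-year-old general population) and forced to
1 at age 100. The slope $b = 0.10$/yr was fixed once so that remaining
life expectancy at 50 is about 29 years, matching period life tables for
the study population; the tests assert the 28--32 band. Any real life
table drops in as a two-column `age,q` CSV without code change, and
results that depend on old-age mortality detail should be read with the
stand-in in mind.

## Probabilistic sensitivity analysis

`run_psa()` repeats the whole comparison under parameter uncertainty:
in each of the (default) 10,000 Monte Carlo repetitions every uncertain
parameter is redrawn from its fitted distribution -- shared parameters
(costs of the health states, utilities, disutilities, operative and
stroke mortality) once per draw and used in both arms; arm-specific
parameters independently per arm. The discount rate (a pure analysis
choice, swept deterministically instead) and the life table are not
sampled, and no correlation is imposed between parameters. Because the
two re-intervention shares are sampled independently, a rare draw can push
their sum above 1; such draws are renormalised proportionally onto the
simplex, which keeps every draw a valid model without breaking seed
determinism.

Each draw's incremental pair $(\Delta E, \Delta C)$ is classified into the
six cost-effectiveness-plane components: C1 (quadrant IV: more effective,
cheaper -- superior), C2/C4 (quadrant I: ICER below/above $\lambda$),
C3/C5 (quadrant III: less effective and cheaper, with savings per QALY
forgone above/below $\lambda$), C6 (quadrant II -- inferior). A draw in
quadrant III counts as cost-effective for the new strategy exactly when
$\Delta C/\Delta E > \lambda$, so the cost-effective components are
$\{C1, C2, C3\}$ -- algebraically the positive half-plane of
$\lambda\,\Delta E - \Delta C$, which makes the quadrant report, the NMB
verdict and the acceptability curve mutually consistent (this is
property-tested). Ties ($\Delta E = 0$) are classified by cost sign
alone; they have probability zero under the continuous distributions but
are defined for degenerate tests.

## Numerical choices

* Threshold search is plain bisection on the incremental NMB, default
  tolerance 0.5 (half a dollar on cost parameters), capped at 200
  iterations; a bracket without a sign change is a classed error, which
  the report writer records as a "no threshold" outcome.
* Transition-row stochasticity is enforced at $10^{-9}$; occupancy rows
  conserve mass to the same tolerance.
* Annual probabilities equal to 1 (terminal life-table age, degenerate
  tests) are handled as infinite hazards: all competing exit mass goes to
  the certain cause.
* Seeded runs restore the caller's RNG state, and the same seed
  reproduces a PSA bit for bit.

## What the synthetic data do and do not establish

The synthetic generator reproduces the *statistical shape* of the study's
inputs -- the printed means, SDs and distribution families, and a
plausible monotone life table anchored at the printed age-50 death
probability. Passing tests therefore demonstrate that the implementation
is internally correct (mass conservation, oracle agreement between the
cohort engine and an individual-level microsimulation, moment-fit
identities, decision-rule equivalences) and that the published results are
reproduced *given this structure and these inputs*. They do not validate
the clinical evidence behind the parameters, the transferability of the
single-centre micro-costing, or old-age mortality beyond the Gompertz
stand-in.

In the test suite the cohort engine is checked against the
microsimulation oracle with $10^5$ simulated subjects per arm using an
exact per-cell binomial criterion at a Bonferroni-corrected family level
(a per-cell 3-SE normal cutoff would be exceeded somewhere by chance
among the ~1,400 simultaneously compared cells, and the normal
approximation is poor in near-empty cells); well-populated cells are
additionally held to the plain 3-SE bound. The probabilistic analysis is
run at the published size of 10,000 repetitions.

## Known limitations

* The re-intervention shares are read as unconditional probabilities of
  receiving each modality after a recurrence (remainder never re-ablated);
  the source does not define whether they are conditional modality shares.
* Stroke risk applies from the AF states only (`stroke_from_nsr = FALSE`
  by default). Applying 5%/yr from NSR for life is available as a switch
  but is inconsistent with lifetime QALYs in the 8--9 range and roughly
  triples the ICER.
* Complications other than stroke are one-off expected costs and
  disutilities in the procedure cycle; no lasting complication states.
* No anticoagulation modelling beyond the flat state costs, no
  value-of-information analysis, no correlation structure in the PSA.

## Reproducing the published analyses

```{r base-case, eval = FALSE}
fit <- cua()                 # published parameters, synthetic life table
summary(fit)

tornado(fit$bundle)          # DSA: ICER at each parameter's +/- 2 SD bounds
find_threshold(fit$bundle, "rfa.cost_procedure", bracket = c(4000, 8000))

psa <- simulate(fit, nsim = 10000, seed = 1)
psa$quadrants                # six-component plane report
head(ceac(psa))              # acceptability curve
```

`scripts/acceptance.R` runs exactly this pipeline from the installed
package and writes the headline numbers as JSON.
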