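# afcua

Cost-utility analysis of **cryoballoon ablation (CBA)** versus
**radiofrequency ablation (RFA)** for paroxysmal atrial fibrillation, as a
tested, configuration-driven R package for health economists and HTA
analysts.

A cohort of 50-year-old patients is followed through a lifetime Markov
model (one-year cycles) over the states *AF pre-intervention -> NSR / AF
post-intervention (single re-intervention) -> NSR after re-ablation / AF
post-re-intervention -> post-stroke -> death*, with age-specific background
mortality from a life table, procedure complications, and stroke with acute
case fatality. Each strategy is summarised by discounted lifetime cost
*C* (2019-20 USD) and QALYs *E* (both discounted at 5%/yr), and compared
through

- the incremental cost-effectiveness ratio `ICER = (C1 - C2) / (E1 - E2)`,
  judged against a willingness-to-pay threshold λ = $7,142/QALY (one GDP
  per capita; 2λ = $14,285 as a secondary threshold), and
- the incremental net monetary benefit `λ·ΔE − ΔC`.

Uncertainty is handled both deterministically (one-way and two-way sweeps,
tornado ranking over ±2 SD ranges, bisection threshold search) and
probabilistically (Monte Carlo over method-of-moments beta/gamma parameter
distributions, cost-effectiveness-plane quadrant report, acceptability
curve). Every input ships with the package: the published parameter set
(`table1_bundle()`, also as `inst/extdata/table1.yaml`) and a synthetic
Gompertz life table anchored at q(50) = 0.0037. See the methods vignette
(`vignettes/ablation-cua-methods.Rmd`) for the model's assumptions and
design decisions.

## Worked example

```r
library(afcua)

fit <- cua()          # base case: published parameters, synthetic life table
fit
#> Lifetime Markov cohort cost-utility analysis: CBA vs RFA
#>
#>             quantity      RFA      CBA
#>              Cost($) 12265.56 14882.98
#>                QALYs     8.53     8.76
#>  Incremental Cost($)        -  2617.42
#>    Incremental QALYs        -     0.24
#>         ICER($/QALY)        - 11050.74
#>
#> At WTP $7,142/QALY: CBA is not cost effective at wtp
```

CBA buys 0.24 extra QALYs for an extra $2,617 -- about $11,051 per QALY,
above the $7,142 threshold (not cost-effective) but below twice the
threshold, where the verdict flips (`summary(fit)` reports both). The value
of RFA at which the verdict changes, and the probabilistic analysis:

```r
find_threshold(fit$bundle, "rfa.cost_procedure", bracket = c(4000, 8000))
#> threshold on rfa.cost_procedure: 5922.61 (bracket [4000, 8000], tol 0.244, 13 iterations)

psa <- simulate(fit, nsim = 2000, seed = 42)
psa
#> PSA: 2000 Monte Carlo draws (seed 42)
#> Cost-effectiveness plane report (WTP $7,142/QALY)
#>  component quadrant ie_sign ic_sign     rule frequency proportion
#>         C1       IV    IE>0    IC<0 Superior       129     0.0645
#>         C2        I    IE>0    IC>0 ICER<WTP       677     0.3385
#>         C3      III    IE<0    IC<0 ICER>WTP        13     0.0065
#>         C4        I    IE>0    IC>0 ICER>WTP       588     0.2940
#>         C5      III    IE<0    IC<0 ICER<WTP        40     0.0200
#>         C6       II    IE<0    IC>0 Inferior       553     0.2765
#>     Indiff   origin    IE=0    IC=0      0/0         0     0.0000
#> P(new strategy cost-effective)  0.4095
#> P(comparator cost-effective)    0.5905
```

So once RFA costs more than about $5,923 the cheaper-but-less-effective
argument for it collapses, and under full parameter uncertainty CBA is the
cost-effective choice in roughly 40% of draws (RFA in 60%).

Other entry points: `one_way()`, `two_way()`, `tornado()` for the
deterministic sweeps; `plot(fit)` (cohort traces) and `plot(psa)` (CE
plane); `report_base()` / `report_dsa()` / `report_psa()` write the full
CSV/JSON outputs of each analysis plus a run manifest, and
`inst/cli/afcua.R` wraps them for the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","afcua.R",package="afcua"))')" \
  psa --config inst/extdata/table1.yaml --output out/ --draws 10000 --seed 1
```

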