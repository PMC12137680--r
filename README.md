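# pepstruct

Postprandial protein digestion delivers free amino acids, dipeptides and
tripeptides to the blood, but routine assays cannot tell these fractions
apart. `pepstruct` estimates that split from a cheap paired measurement: the
ninhydrin amine-group signal of a 10 kD plasma filtrate read before (`F`) and
after (`T`) acidic hydrolysis of peptide bonds. It is aimed at physiologists
and clinical researchers running mixed meal tolerance tests (MMTT) who want
stacked free/dipeptide-derived/tripeptide-derived AUC decompositions from
`(F, T)` time series.

## The model

Hydrolysis releases one extra amine group per dipeptide and two per
tripeptide, so with `F` normalized to 1 and `W = T/F`:

```
A + x1 + 2x2 + 3x3 + y1 + 2y2 + 3y3 + 4y4 = F = 1
x + 2y = W − 1,   1 ≤ W ≤ 3
x1 = (1−α)x, x2 = x3;  y1 = (1−β)y, y2 = y3 = y4;  α, β ∈ [0, 0.3]
```

where `A` counts free amino acids, `x`/`y` the di-/tripeptide pools, and
`α`/`β` the fractions of peptides carrying a second (side-chain) amine —
bounded by 0.3 because ~30% of amino acids are two-amine. A single `W` pins
the composition down only to a bounded feasible set of `(α, β, A)`; the
estimator reports the expected amine-group shares under a uniform
distribution on that set (the "mean structure"), computed either by
deterministic quadrature or by seeded Monte-Carlo rejection sampling. A
baseline-adjusted trapezoidal AUC pipeline then splits each MMTT response
into `AUC_T = AUC_F + AUC_DD + AUC_TD`, and a synthetic MMTT generator with
known ground truth validates the whole chain. See the vignette in
`vignettes/amine-structure-estimation.Rmd` for the full account.

## Worked example

One-shot estimation at a measured ratio `W = 2`:

```r
library(pepstruct)
mean_structure(2)
#> Mean amine-group structure at W = 2 ( quadrature )
#>                       free AA dipeptide tripeptide
#> before hydrolysis (F)  0.1857    0.3873     0.4269
#> after hydrolysis (T)   0.0929    0.3557     0.5514
```

Reading the second row: at `W = 2`, on average 9.3% of the total amino-acid
equivalents entering the blood arrive as free amino acids, 35.6% inside
dipeptides and 55.1% inside tripeptides.

A full cohort run on synthetic data (six subjects, 10% assay noise):

```r
sc  <- sim_scenario(seed = 3)                 # default MMTT design
dec <- decompose_mmtt(simulate_readings(sc))  # per-subject AUC split
summary(dec)
#> Group-level AUC summary (mean ± SD, µg/mL·min)
#>    group health_state mmtt component     mean      sd n flag
#>  Control      Healthy  HFD     AUC_F  3135.39  558.52 6
#>  Control      Healthy  HFD    AUC_DD  5865.87 1081.93 6
#>  Control      Healthy  HFD    AUC_TD  9187.69  971.81 6
#>  Control      Healthy  HFD     AUC_T 18188.96  881.60 6
```

so ~17% of the postprandial amino-acid appearance is free, ~32% dipeptide-
derived and ~51% tripeptide-derived; `plot(dec)` draws the stacked bars.
The same operations are available from a shell via `inst/exec/pepstruct`
(`estimate`, `decompose`, `summarize`, `simulate`, `recover`).

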