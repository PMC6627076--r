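# mitoburden

How many somatic mtDNA mutations does a cell accumulate by old age?
`mitoburden` is an R package for geneticists and modelers who want a
transparent, configurable answer. It implements a per-cell burden model

    B = G · Z · (X1 + X2 + X3) · µ / 2

where `G` = 16,569 bp is the mitochondrial genome length, `Z` the
per-cell mtDNA copy number (log10-uniform over 100–10,000), `µ` the
POLG replication error rate (uniform over 2.8×10⁻⁸–5.6×10⁻⁷ per base),
and `X1`, `X2`, `X3` the replication rounds contributed by development
(mean 45), relaxed-replication turnover (mean 280 by age 70 at a
3-month half-life) and stem-cell cycling (mean 91 at a 40-week cycle);
the division by 2 converts the raw error rate into an effective
mutation rate, since each new mutant molecule has an even chance of
immediate loss. The package provides:

* closed-form expected burdens (`expectedBurden`) and all the
  replication-round / de novo-rate arithmetic (`turnoverRounds`,
  `hscExtraRounds`, `divisionsToCellCount`, `perDivisionMutationCount`,
  `birthBurdenRange`, `bodyCopyEstimate`);
* Monte Carlo sampling of the full per-cell burden distribution for
  proliferating and non-proliferating cells (`sampleBurden`), with
  tail-probability tables (`tailProbabilities`), reversed-CDF curves
  (`reversedCDF`) and summaries (`burdenSummary`);
* deterministic heteroplasmy projection under a per-round proliferative
  advantage (`projectHeteroplasmy`, `roundsToThreshold`) and a neutral
  binomial segregation simulator (`segregateStochastic`);
* a JSON-configured report driver (`runBurdenReport`) and a
  command-line wrapper (`inst/scripts/mitoburden`).

## Worked example

```r
library(mitoburden)

m <- BurdenModel()           # defaults: proliferating cell, age 70
round(expectedBurden(m))
#> [1] 1013
round(expectedBurden(BurdenModel(proliferating = FALSE)))
#> [1] 792

s <- sampleBurden(m, nSamples = 1e6, seed = 1)
tailProbabilities(s)
#> TailTable (1000000 draws, seed 1):
#>  mutations probability
#>       <=10    0.000105
#>       <=50    0.030238
#>      <=100    0.082780
#>      <=200    0.193923
#>      >=500    0.607503
#>     >=1000    0.457681
#>     >=1500    0.370966
#>     >=2000    0.310976
#>     >=3000    0.230346
#>     >=5000    0.138206

projectHeteroplasmy(0.01, advantage = 0.02, nRounds = 280)
#> [1] 0.1407557
```

Reading: a typical proliferating cell is expected to carry ~1013 de
novo mtDNA mutations by age 70; about 61% of such cells carry at least
500 mutations, and under 0.1% get away with fewer than 10. A variant
present at 1% at birth with a 2% per-round proliferative advantage
drifts up to ~14% heteroplasmy in a non-dividing lineage (280 rounds)
over the same span.

A full report — expectation JSON, tail table, reversed CDF, histogram,
drift projections and a reproducibility manifest — comes from

```sh
Rscript inst/scripts/mitoburden --outdir report --seed 1
```

or `runBurdenReport()` from R; every output embeds the seed and the md5
of the resolved configuration, and identical seeds reproduce outputs
byte for byte.

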