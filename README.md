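# rangedrivers

Habitat modification and introduced mammalian predators are the two main
drivers of range contraction for many island birds, but their onsets are
historically confounded, so their relative contributions are hard to
separate.  `rangedrivers` implements a landscape-scale partitioning of a
river specialist's range contraction into those two components, built
around bootstrapped boosted regression tree (BRT) species distribution
models on a reach-scale river network.  It is aimed at quantitative
ecologists who want the full pipeline — from presence records to a
driver partition with uncertainty — as tested, reusable functions.

## The method

1. **Model fitting.** Presence reaches are combined with an equal number
   of background reaches drawn from a geographically constrained area
   (reaches whose Gaussian kernel density of presences exceeds a low
   quantile of the density at presences).  A stagewise logistic BRT
   (tree complexity 5, learning rate 0.01, Bernoulli deviance with
   Newton terminal updates) is fitted, with ten-fold cross-validation
   selecting the number of trees; 200 bootstrapped simulations (each
   withholding a stratified 20% of rows) provide uncertainty.

2. **Scenario prediction.** Each ensemble member predicts a relative
   likelihood of occurrence (RLO) per reach under three scenarios:
   *potential contemporary* (today's covariates, predators controlled),
   *potential pre-human* (the five land-cover/climate covariates
   `segIndigenousForest`, `usIndigenousForest`, `segShade`,
   `segTempSummer`, `segTempSeasonality` replaced by pre-human values),
   and *observed contemporary* (potential-contemporary predictions
   restricted to reaches with actual observations).  ExDet screening
   (univariate NT1 / combinational NT2 novelty) flags reaches where the
   model extrapolates.

3. **Partition.** Effective habitat is EH = Σ reaches RLO × reach length
   (km).  Per simulation, the habitat-modification contraction is
   100 × (1 − EH_contemporary / EH_prehuman) and the additional
   predation contraction is 100 × (1 − EH_observed / EH_contemporary);
   both are summarized as mean ± sd across simulations.

Because the real observation and environmental databases this class of
analysis uses are not publicly deposited, the package includes a
synthetic riverscape generator (`generate_network()`,
`generate_predictors()`, `occupancy_truth()`, `simulate_presences()`)
with known ground truth, so the whole pipeline is testable by parameter
recovery.

## A worked example

```r
library(rangedrivers)

cfg <- pipeline_config(n_sims = 25)   # desk-scale: 3000 reaches, 25 members
res <- run_pipeline(cfg, seed = 3)
print(res)
```

```
rangedrivers pipeline run (seed 3)
  reaches: 3000  presences: 242  ensemble: 25 members x 150 trees
  withheld AUC 0.698 +/- 0.043
  EH potential_contemporary: 970 +/- 8 km
  EH potential_prehuman: 1256 +/- 15 km
  EH observed_contemporary: 117 +/- 1 km
Range-contraction partition over 25 simulations
  habitat modification: 22.8 +/- 0.7 %
  additional predation: 87.9 +/- 0.0 %
  (ratio-of-means variants: 22.8 %, 87.9 %)
  recovery vs truth:
                driver estimate_pct truth_pct abs_error_pct
1 habitat_modification     22.78025  29.95225     7.1720030
2            predation     87.91049  87.56864     0.3418469
```

Reading the output: under pre-human land cover the model hindcasts
1256 km of effective habitat; contemporary land cover reduces that to
970 km (a 22.8% contraction attributable to habitat modification, truth
30.0% for this seed's synthetic landscape), and the observed range holds
only 117 km (an *additional* 87.9% contraction attributable to
predation, truth 87.6%).  `res$recovery` tabulates these estimates against the
generative truth; `res$extrapolation` reports the percentage of the
network where predictions leave the training envelope.

A shell entry point with the same defaults lives at
`inst/scripts/rangedrivers-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/rangedrivers-pipeline.R",
                                       package = "rangedrivers"))')" \
    run --seed 3 --out runs/demo --n-sims 25
```

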