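# nichenull

Species co-occurrence analysis of binary site-by-species matrices against
**standard** and **environmentally constrained** null models.

Classical null-model tests (fixed occurrences, fixed margins) randomize a
community matrix and ask whether the observed segregation — checkerboard
units, the C-score — could arise by chance. They cannot tell competition
apart from habitat filtering: species that prefer different environments
look segregated too. `nichenull` adds niche-aware reference models: a
species distribution model (stepwise-AIC logistic regression or random
forest) is fitted per species with leave-one-out prediction, and
pseudo-communities are drawn from the predicted probabilities either with
each site's richness fixed (`PF`) or cell-wise Bernoulli (`PP`). Comparing
the observed C-score with all six ensembles separates three hypotheses:

| observed C-score vs ensemble | interpretation |
|---|---|
| outside standard, within constrained | habitat filtering explains the pattern |
| below constrained ensembles | aggregation beyond niches (e.g. mass effect) |
| above constrained ensembles | segregation beyond niches (e.g. competition) |

The package also provides NODF nestedness, group-partitioned F-indices
(`CU_model / CU_real` per species-group pair), a NODF-to-C-score regression
across pooled pseudo-communities, distance-based redundancy analysis
(Jaccard + permutation tests + stepwise selection), and a synthetic
metacommunity generator with known niche structure and a tunable
mass-effect mechanism, so every claim is testable without field data.

## Example

```r
library(nichenull)

E <- generate_environment(60, n_gradients = 2, n_vars = 4, seed = 11)
truth <- synthetic_truth(40, paste0("env_", 1:4), mass_effect = 0.5, seed = 12)
world <- generate_metacommunity(E, truth, seed = 13)
M <- filter_rare_species(world$M, 5)

set.seed(14)
P_logit   <- build_prob_matrix(M, E, "logit")
P_randfor <- build_prob_matrix(M, E, "randfor", n_trees = 100)
ens <- run_null_ensembles(M, c("NullModFE", "NullModFF", "LogitPF", "LogitPP",
                               "RandForPF", "RandForPP"), n_replicates = 200,
                          P_logit = P_logit, P_randfor = P_randfor)
run_cscore_comparison(ens, M)[, c("model", "q025", "median", "q975",
                                  "observed", "position")]
```

Output from the shipped workflow run (seed `20160914`, 60×40 world,
mass effect 0.5; see `results/cscore_comparison.csv`):

```
      model     q025   median     q975 observed position
    LogitPF 93.72341 97.76635 100.5900 92.66346    below
    LogitPP 87.30636 91.89360  96.7771 92.66346   within
  NullModFE 91.35412 93.19455  95.1326 92.66346   within
  NullModFF 90.07945 90.27275  90.4866 92.66346    above
  RandForPF 93.46593 97.47470 100.4682 92.66346    below
  RandForPP 88.52072 92.70450  97.0169 92.66346   within
```

The richness-constrained niche ensembles (PF) place the observed C-score
below their central 95% interval: these communities are more aggregated
than habitat filtering predicts — and in this synthetic world we know the
cause is the generator's mass effect. The free-fill PP ensembles absorb the
mass-effect prevalence inflation into the fitted probabilities and do not
flag it at this matrix size (discussed in the vignette).

## Tests

```r
testthat::test_dir("tests/testthat", package = "nichenull",
                   load_package = "installed")
```

The suite checks every statistic against naive definition-level oracles and
against `vegan` (`nestedchecker`, `nestednodf`), verifies margin
conservation and uniformity of the trial-swap sampler over an enumerated
margin class, the PF/PP sampling laws, dbRDA p-value uniformity and inertia
closure, and runs seeded calibration/recovery experiments on synthetic
worlds.

## Vignette

`vignettes/cooccurrence-null-models.Rmd` documents the statistics, the six
null models, the design decisions (trial counting, leave-one-out protocol,
weight floors, inertia conventions), and what the constrained models can and
cannot detect.
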