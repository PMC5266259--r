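# cytopop

Identifying the composition of synthetic bacterial communities from
multiparametric flow cytometry (FCM) data.

Microbial flow cytometry measures every cell of a sample on a panel of
fluorescence and scatter detectors — here the standard 12-parameter panel
(FL1–FL4, FSC, SSC, each as pulse area and height) of SYBR-Green-stained
bacteria. When the member populations of a community have also been measured
separately as axenic (pure) cultures, those single-population measurements
can be aggregated into a labelled single-cell training set — an **in silico
community** — on which a supervised classifier learns to predict the
population of origin of individual cells. Applied to a mixed sample, the
classifier's per-cell labels yield the community's composition by simple
counting. `cytopop` implements this framework end to end for microbial
ecologists working with defined (synthetic) communities:

* **FCS 3.0/3.1 I/O** (`read_events()`, `write_events()`), with a plain CSV
  dialect for diffable fixtures;
* **preprocessing**: arcsinh transformation and reproducible polygon gating
  in the FL1–FL3 bivariate space to remove (in)organic debris and instrument
  noise, with replicate pooling (`transform_arcsinh()`, `polygon_gate()`,
  `apply_gate()`, `pool_replicates()`);
* **community construction**: even communities (default 5,000 cells per
  population, drawn without replacement), stratified 70/30 train/test
  splits, two-population abundance gradients from 1% to 99%, and
  enumeration/sampling of taxon combinations per richness
  (`build_even_community()`, `split_train_test()`, `build_gradient()`,
  `enumerate_communities()`);
* **classification**: `fit_cell_classifier()` returns a classed model
  object (LDA, or a 200-tree Gini random forest with `mtry = floor(sqrt(K))`)
  with `print`/`summary`/`predict` methods and a plug-in composition
  estimator (`estimate_composition()`);
* **evaluation**: accuracy, rank-statistic (Mann–Whitney) binary AUC,
  gradient RMSE and row-normalised confusion matrices;
* **diversity**: the Hill number of order one, `D1 = exp(-Σ p_i ln p_i)`,
  with the 5% instrumental counting error of FCM propagated into its
  variance, `σ²_D1 = D1² Σ (ln p_i + 1)² σ²_p_i` with `σ²_p = 2 ε_I² p²`,
  and 68%/95% confidence intervals (`hill_d1()`, `var_d1()`, `d1_with_ci()`);
* **simulation**: ground-truth-labelled multi-population panels with
  controllable population overlap, replicate drift and debris noise
  (`simulate_panel()`, `preset_pairs()`, `default_panel_models()`), so every
  stage can be exercised against known truth;
* **experiments**: the three standard community experiments as one-call
  runners — pairwise (S = 2) performance scan, richness scan with a 68%
  band, and abundance-gradient recovery with diversity intervals
  (`run_pairwise_scan()`, `run_richness_scan()`, `run_gradient_recovery()`)
  — plus a thin CLI (`inst/cli/cytopop.R`) with `simulate`, `pairwise`,
  `richness` and `gradient` subcommands.

## Worked example

Simulate a medium-overlap two-population panel, gate and pool it, train a
random forest on an even in silico community, and recover a 13-level
abundance gradient:

```r
library(cytopop)

pair    <- preset_pairs()$medium           # two overlapping populations
panel   <- simulate_panel(pair, replicates = 2, seed = 7)
samples <- panel_samples(panel)            # gate + pool replicates
samples$medium_A
#> population_sample 'medium_A': 2 replicate(s), gated counts 9545 + 9513 = 19058 pooled cells

community <- build_even_community(samples, n_per_pop = 5000, seed = 7)
split     <- split_train_test(community, seed = 7)   # stratified 70/30
fit       <- fit_cell_classifier(split, method = "RF", seed = 7)
evaluate_classifier(fit, split)
#> metrics_report: accuracy = 0.916, AUC = 0.9698 (n_test = 3000)
```

91.6% of the 3,000 held-out cells are assigned to the correct population;
the AUC of 0.97 says a random `medium_B` cell outscores a random `medium_A`
cell 97% of the time. Composition recovery along the gradient:

```r
gradient <- run_gradient_recovery(samples$medium_A, samples$medium_B,
                                  experiment_config(seed = 7))
gradient
#> gradient_recovery: 13 levels, trained on 10000 cells
#>  method       rmse
#>     LDA 0.11230862
#>      RF 0.06374092
```

The RMSE is the root mean squared deviation between predicted and target
relative abundances over the 13 gradient communities — the random forest
tracks this medium-difficulty gradient to within ~0.06. Diversity of a
30/70 community with instrument-error bounds:

```r
d1_with_ci(c(0.3, 0.7), epsilon_i = 0.05)
#> diversity_estimate: D1 = 1.842 (sigma = 0.05919, epsilon_i = 0.05)
#>   68% CI: [1.7828, 1.9012]
#>   95% CI: [1.726, 1.958]
```

Real FCS data are analysed the same way: place the files in a directory
with a `manifest.csv` (`taxon_id`, `replicate`, `path`), load with
`load_panel()`, and supply per-culture gates via `read_gates_config()`.

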