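# invasispace

Trait-based analysis of **species invasiveness** and **community
invasibility** for freshwater fish faunas.

Biological invasions have two sides. A species-centred one: which
functional traits let a fish establish outside its native range, where
invasiveness is measured as the number of watersheds in which the species
is recorded as an established non-native? And a community-centred one: what
makes a watershed's fish community easy to invade, where invasibility is
the number of established non-native species it hosts? `invasispace`
implements both analyses end to end, plus a synthetic-data generator with
planted ground truth so the whole pipeline can be verified by recovery
tests.

## The method

1. **Functional space.** Species × trait tables (20 mixed-type traits: 17
   continuous, one binary, one 5-level categorical, one ordinal) are
   compared with the Gower coefficient — `|xi − xj|/range` for continuous
   traits, the same rule on average ranks for ordinal traits, 0/1 mismatch
   for binary/categorical — and embedded by principal coordinates analysis
   (PCoA); the first five axes are retained. Missing trait values are
   imputed beforehand by iterative random-forest imputation (missForest
   algorithm, `ranger` backend), optionally with phylogenetic eigenvectors
   as auxiliary predictors.
2. **Community descriptors.** Per watershed (communities with fewer than
   six species are dropped): six presence/absence functional-diversity
   indices — FRic (convex-hull volume, exact k-d hull in compiled code),
   FEve (minimum-spanning-tree regularity), FDiv, FDis, FSpe, FOri — and
   two native/non-native distances in the same space:

   * `cd` — Euclidean distance between the native and non-native
     assemblage centroids,
   * `md` — mean distance from each non-native species to its nearest
     native neighbour.
3. **Models.** Poisson boosted regression trees (log link, depth-limited
   `rpart` base learners, bagged Newton leaf updates) with the tree count
   chosen by lockstep k-fold cross-validation; performance is CV-D², the
   cross-validated proportion of Poisson deviance explained. The
   invasiveness model uses 18 species-level predictors (14 traits with
   log10 fecundity, the Size_PCA1/Temp_PCA1 composites, the 0–4 human use
   index, invasion type); the invasibility model uses 12 watershed-level
   predictors (the indices, cd, md, and the Area/NPP/GDP/HFI/DOF
   covariates, after excluding NSR and FDis as collinear). Relative
   influence, partial dependence, pairwise interaction strength, multi-seed
   rerun aggregation and Moran's I residual diagnostics are included.

## Worked example

```r
library(invasispace)

sim <- simulate_invasion_study(synthetic_config(n_species = 150,
                                                n_watersheds = 60,
                                                seed = 42))
config <- pipeline_config(
  synthetic = sim$config,
  brt = brt_params(learning_rate = 0.1, max_trees = 120, n_folds = 5,
                   step_size = 15, patience = 4),
  n_reruns = 5, compute_interactions = FALSE,
  imputation = list(num_trees = 50L, max_iter = 5L), seed = 42)

report <- run_invasibility(sim, config)
report
#> Invasion report: invasibility model, 12 predictors, mean CV-D2 = 0.596 over 5 reruns
#> # A tibble: 6 × 3
#>   predictor mean_influence sd_influence
#>   <chr>              <dbl>        <dbl>
#> 1 cd                 42.4         4.56
#> 2 FRic               39.9         4.72
#> 3 FOri                3.31        0.609
#> 4 GDP                 2.88        0.591
#> 5 DOF                 2.22        0.904
#> 6 FDiv                2.03        1.02
glance(report)
#> # A tibble: 1 × 4
#>   model        n_predictors mean_cv_D2 n_runs
#>   <chr>               <int>      <dbl>  <int>
#> 1 invasibility           12      0.596      5
```

This synthetic study plants a negative effect of `cd` and positive effects
of `md`, `FSpe` and `GDP` on the invasibility rate. The report shows the
model recovering the planted structure: `cd` is the most influential
predictor (mean relative influence 42.4%, averaged over 5 reruns) and the
model explains 60% of the held-out Poisson deviance. `FRic` ranks high
because recipient-community richness grows with the response itself — a
feature of computing indices on the invaded community, discussed in the
vignette. `tidy(report)` returns the full influence table,
`plot_influence(report)` and `plot_partial_dependence(report)` the
standard figures, and `write_report(report, dir)` the TSV/JSON artifacts.

`run_invasiveness(sim, config)` fits the species-level model the same way.
A thin command-line wrapper is installed at `inst/cli/invasispace.R`
(`simulate | fit-invasiveness | fit-invasibility | all`).

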