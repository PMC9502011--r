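# micronet

Co-occurrence networks and nitrogen-use statistics for soil amendment
experiments.

## The problem

Slow-release nitrogen fertilisers (e.g. polymer-coated controlled-release
urea, CRU) and organic synergists such as fulvic acid (FA) change how a
soil's bacterial community cycles nitrogen — which taxa co-occur, which
ecological modules track nitrate, ammonium and pH, and ultimately how
much fertiliser N the crop recovers. Analysing such an experiment means
walking a 16S amplicon count table through a long, fiddly chain:
rarefaction and coverage, ordination, correlation-network inference with
a principled threshold, module detection, module–environment
association, guild-level Mantel tests, and agronomic efficiency
statistics with multiple-range letters. micronet packages that chain as
tested, seeded, composable R functions — for microbial ecologists and
agronomists who have a taxon×sample count table (or want a synthetic one
with known ground truth) and need the whole analysis to be reproducible.

## The statistics at the core

* **Rarefaction** subsamples each sample without replacement
  (multivariate hypergeometric) to a common depth; **Good's coverage**
  is 1 − F1/N.
* **Bray–Curtis** dissimilarity d(i,j) = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)
  feeds **PCoA** (Gower-centred eigendecomposition) and **ANOSIM**
  (R = (r̄_between − r̄_within)/(n(n−1)/4), permutation p with the +1
  convention).
* The **co-occurrence network** thresholds pairwise Spearman ρ at a
  cutoff chosen by **random-matrix theory**: the smallest threshold at
  which the nearest-neighbour spacing distribution of the thresholded
  matrix's unfolded eigenvalues fits the Poisson law e^(−s)
  (chi-square), i.e. where random inter-taxon mixing gives way to
  modular structure. Edges additionally require Benjamini–Hochberg
  q ≤ 0.001; signs are kept. Modules come from seeded Louvain
  modularity maximisation on |ρ| weights.
* **Association**: Pearson module–environment correlation tables with
  significance stars, Welch-on-log enrichment calls per taxon
  (Manhattan-plot ready), and simple/partial **Mantel tests** between
  guild community distances and single-factor environmental distances
  (9999 permutations).
* **Agronomy**: NUE (%) = (AN − AN0)/SN × 100,
  NAE = (GN − GN0)/SN, NPE = (YN − YN0)/(AN − AN0), percent changes
  rounded half-up to one decimal, and one-way ANOVA with **Duncan's
  multiple range test** letters (studentized-range quantiles computed
  numerically).
* A **synthetic-data generator** plants a known module structure
  (log-normal module-factor model closed by Dirichlet–multinomial
  counting), environmental covariates coupled to module abundances, and
  agronomic records — so every stage is testable without any download.

See `vignettes/cooccurrence-methods.Rmd` for the full model
descriptions, defaults and design decisions.

## Worked example

```r
library(micronet)

run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> micronet pipeline run
#>  - inputs ready: 300 taxa x 36 samples
#>  - community: mean Good's coverage 0.9992; 35/45 genus-level taxa pass the 0.01 filter
#>  - ordination: PC1 34.39%, PC2 21.48%; ANOSIM(treatment) R = 0.31 p = 0.001
#>  - network: RMT-selected threshold 0.30
#>  - network: 35 nodes, 117 edges, 5 modules, Q = 0.737
#>  - association: focal module Mod 4; 0 enrichment calls; 48 guild-factor Mantel tests
#>  - agronomy: CRU+FA vs CRU yield change 25.1%
```

The log reads top to bottom as the analysis: 36 simulated samples were
rarefied (coverage 99.92%), 35 genera passed the 1% dominance filter
and became network nodes, the RMT scan put the correlation cutoff at
0.30, and the 117-edge network splits into 5 modules at modularity
Q = 0.737 — recovering the 5 planted modules. ANOSIM separates the
treatments (R = 0.31, p = 0.001). Each stage's tables live in the
returned object:

```r
head(run$network$network$edges, 3)
#>                 from             to       rho     sign            q
#> 1 Altererythrobacter       Bacillus 0.8072592 positive 1.583344e-08
#> 2 Altererythrobacter     Haliangium 0.7192689 positive 4.008102e-06
#> 3 Altererythrobacter Hyphomicrobium 0.8337731 positive 1.822797e-09
```

Agronomic efficiency on a noiseless design table (replicates equal to
their treatment means):

```r
agro <- simulate_agronomy(simulation_config(seed = 1), residual_cv = 0)
nitrogen_efficiency(agro)$summary[, c("treatment", "NUE", "NAE", "NPE", "NUE_change")]
#>   treatment      NUE      NAE      NPE NUE_change
#> 1       CRU 35.40881 13.83648 39.07638        0.0
#> 2    CRU+FA 50.00000 19.49686 38.99371       41.2

percent_change(99.6, 81.6)   # CRU+FA vs CRU grain yield, g/pot
#> [1] 22.1
```

NUE rises from 35.4% to 50.0% with the synergist (a 41.2% relative
gain), and the 99.6 vs 81.6 g/pot yield means print as a 22.1%
increase — the half-up one-decimal convention of agronomic tables.

With your own data, point the pipeline at TSV inputs instead of the
simulator (`pipeline_config(stages = c("community", ...), inputs =
list(counts = ..., taxonomy = ..., metadata = ...))`), or call the
stage functions directly. A command-line front end ships in
`inst/scripts/run_pipeline.R`.

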