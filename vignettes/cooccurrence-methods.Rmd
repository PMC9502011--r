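---
title: "Co-occurrence networks and nitrogen-efficiency statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks and nitrogen-efficiency statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

micronet implements the analysis chain used to study how slow-release
nitrogen fertilisation, with and without an organic synergist, reshapes
a soil bacterial community: count-table processing, Bray-Curtis
ordination, signed Spearman co-occurrence networks thresholded by a
random-matrix-theory (RMT) scan, module-environment association, guild
Mantel tests, and nitrogen-efficiency agronomics. This vignette explains
the statistical machinery, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where the methodology left room.

## Count-table processing

The pipeline's root object is an integer taxon-by-sample count matrix.
Samples are equalised by **rarefaction**: true subsampling without
replacement (multivariate hypergeometric) to a common depth, 20,000
reads by default. Samples below the target depth are dropped, not
scaled — scaling would break the integrality that rank-based statistics
downstream rely on. **Good's coverage**, 1 − F1/N with F1 the number of
singleton taxa, estimates how completely each library sampled its
community.

Counts are converted to relative abundances, aggregated at a taxonomic
rank (genus by default; taxa unresolved at that rank are pooled into an
explicit `unclassified` bin so totals are conserved), and filtered to
the dominant fraction: taxa whose mean relative abundance exceeds 1%
within at least one treatment group. The "within different treatments"
phrasing of such filters is ambiguous between a union, an intersection
and a global-mean reading; the default is the **union rule**, because it
keeps the node set comparable when networks or contrasts are compared
across treatments, and both alternatives are available through
`filter_mean_abundance(rule =)`. The default order of operations is
rarefy → aggregate → filter.

## Ordination and ANOSIM

Community dissimilarity uses **Bray-Curtis**,
d(i,j) = Σ|x~ik~ − x~jk~| / Σ(x~ik~ + x~jk~). Principal coordinates
analysis applies Gower double-centering to −d²/2 and eigendecomposes;
coordinates are eigenvectors scaled by √λ. Bray-Curtis is not
Euclidean-embeddable, so negative eigenvalues can occur: they are
retained in the eigenvalue list but excluded from coordinates and from
the proportion-explained denominator, and no Cailliez correction is
applied — the simplest convention, flagged in the result object. A
phylogeny is deliberately not modelled, so phylogenetic distances
(UniFrac) are out of scope; Bray-Curtis is the implemented metric.

**ANOSIM** ranks all pairwise dissimilarities (average ranks for ties)
and computes R = (mean between-group rank − mean within-group rank)
divided by n(n−1)/4, which equals 1 exactly when every between-group
distance exceeds every within-group distance. The permutation p-value
uses the +1 convention, p = (1 + #{R\* ≥ R}) / (1 + n~perm~), so it can
never be 0 and its floor is 1/(n~perm~+1). The default is 999
permutations.

## The co-occurrence network

Networks are inferred from pairwise **Spearman correlations** between
the filtered taxa (average ranks for ties; two-sided p-values from the
t approximation, adequate at n = 36 samples). Taxa with zero variance
have undefined correlations; these pairs are recorded as missing and
can never form edges. P-values over the lower triangle are adjusted by
**Benjamini-Hochberg** with a stringent edge cutoff of q ≤ 0.001; the
adjustment procedure is pluggable through `p.adjust` method names.

The correlation-magnitude cutoff is chosen by an **RMT threshold
scan**. For each candidate threshold t the matrix is hard-thresholded
(|ρ| < t zeroed, unit diagonal kept) and restricted to taxa retaining
at least one connection. Its eigenvalue spectrum is unfolded by fitting
a smoothing polynomial (degree 5 by default) to the empirical cumulative
spectral distribution, enforced monotone; the nearest-neighbour spacing
distribution (NNSD) of the unfolded levels is then tested against the
Poisson law e^−s^ with a chi-square test over ⌈√m⌉ equal-probability
bins. Dense, randomly mixed spectra show Wigner-Dyson level repulsion
and fail this test; once thresholding has isolated genuine modules the
spacings become Poisson. The scan selects the smallest candidate with
chi-square p > 0.05 and reports the full diagnostic table. Degenerate
inputs (an identity matrix, a spectrum too small or too tied to unfold)
yield no Poisson-consistent candidate and an error advising a wider
grid; the pipeline additionally accepts a `fallback_threshold` (default
0.72, a typical genus-level cutoff for soil communities) so an
exploratory run is not derailed. Whether the cutoff applies to |ρ| or
to positive ρ only is a genuine choice; micronet thresholds on
**magnitude** and keeps the sign as an edge attribute, because both
mutualistic (positive) and disrupted (negative) linkages are of
interest.

One network is built from **all samples jointly** — correlation
estimates at n = 36 are already noisy, and halving the sample count per
treatment would push the FDR-controlled edge set toward empty;
per-treatment networks (at the same threshold, for linkage-count
comparisons) are available via `per_treatment_networks`.

**Modules** are found by seeded Louvain modularity maximisation on
|ρ|-weighted edges; the partition covers non-isolated nodes, modules
are ranked by size (ties broken by smallest member identifier) and
named Mod 1…k, and the modularity Q is reported. Per-sample module
abundance is the sum of member relative abundances, so module values
per sample sum to at most 1.

## Module-environment association and guild Mantel tests

`module_env_correlation()` correlates module abundances with each
environmental factor (Pearson, as is conventional for heat-map panels)
and attaches stars at p < 0.05 / 0.01 / 0.001 — strict inequalities, so
a boundary p-value receives the weaker star. The module most positively
associated with the environment is selected by the largest sum of
significant positive correlations.

Per-taxon enrichment between two treatments uses **Welch's t-test on
log-transformed relative abundances**, with a pseudo-fraction equal to
half the smallest nonzero tested abundance added before the log. With
only 3 replicates per treatment-day cell, rank tests cannot reach
FDR-corrected significance at all, which is why a parametric test on
the log scale is the default (the test function is an isolated,
replaceable unit). Calls are BH-adjusted within the tested taxon set at
α = 0.05, and the output table carries −log10 p, status and phylum —
the columns a Manhattan plot needs.

**Mantel tests** correlate vectorised distance matrices; permutations
jointly permute rows and columns of the second matrix, again with the
+1 p-value convention and 9999 permutations by default. The partial
variant residualises both matrices on a conditioning matrix. In a
single-incubator design there is no geographic distance to correct, so
the default conditioning matrix is the **day-difference matrix**
|d~i~ − d~j~|, which removes the shared temporal trend; it is
configurable. Guild community distances are Bray-Curtis on the
sub-community of genera mapped to a guild by an explicit, user-supplied
genus-to-guild table — guild membership of environmental taxa is
contested, so the package only ships an example map
(`default_guild_map()`, `inst/extdata/nitrogen_guilds.tsv`) covering
well-known ammonia-oxidising, nitrifying, denitrifying and N-fixing
genera. Environmental factor distances are Euclidean on the z-scored
factor (population SD, making two samples at the extremes of a
two-sample factor sit at distance 2, and the distance scale-invariant).

## Agronomic statistics

The three nitrogen-efficiency statistics are evaluated exactly:

* NUE (%) = (AN − AN0) / SN × 100 — fertiliser N recovered in the crop;
* NAE (kg kg⁻¹ N) = (GN − GN0) / SN — extra grain per unit fertiliser N;
* NPE (kg kg⁻¹ N) = (YN − YN0) / (AN − AN0) — extra yield per unit extra
  uptake, reported missing when AN = AN0.

AN/GN/YN are treatment values, the 0-suffixed symbols zero-N control
means, SN the fertiliser N dose. Percent changes against a reference
treatment are reported **rounded half away from zero to one decimal**,
the convention of printed agronomic tables, with raw values kept
alongside; note that a percent change computed from already-rounded
table entries can differ in the last digit from one computed on raw
data, which is why both are carried.

Treatment separation uses one-way ANOVA followed by **Duncan's multiple
range test**: groups ordered by mean, critical range for a span of p
means q(α~p~, p, df~e~)·√(MSE/n~h~) with protection level
α~p~ = 1 − (1 − α)^(p−1)^ and n~h~ the harmonic mean group size.
Studentized-range quantiles come from `qtukey()`, not printed tables. A
span that fails its critical range declares every enclosed pair
homogeneous (the classic protection rule), and letters are read off the
maximal homogeneous intervals. Duncan's protection levels make it less
conservative than Tukey's HSD; the test suite checks that every pair
Tukey separates, Duncan separates too.

## The synthetic-data generator

`simulate_community()` emulates the study design: 3 treatments (zero-N
control, controlled-release urea, CRU + fulvic acid) × sampling days
1, 7, 30, 60 × 3 replicates = 36 samples at 20,000 reads, 300 taxa in 5
modules. The latent model is log-normal with a module factor: taxon
log-abundance = baseline (N(0, 1.5²), giving a realistic long-tailed
rank-abundance curve) + √ρ · module factor + √(1−ρ) · idiosyncratic
noise, with ρ = `module_cor` (default 0.8) the latent within-module
correlation. Treatment effects shift whole modules: each fertilised
treatment raises one module and suppresses another by `module_effect`
(natural-log units, default 2 — the magnitude class of the several-fold
abundance contrasts reported for dominant nitrogen-cycle genera),
ramped over days from 0.5× to 1× to mimic a slow-release nutrient
pulse. Latents are closed to proportions, perturbed by a Dirichlet draw
(concentration `dispersion`, default 5000, i.e. mild technical
overdispersion on top of the log-normal biological variation), and
counted with a multinomial of size `depth`, so sample totals equal the
depth exactly.

Genera are **nested inside modules** — each of the 45 catalogue genera
belongs to one module, and taxa draw genus names from their module's
set — so genus-level aggregation preserves the planted structure, as
ecological modules built from co-occurring genera do in real data.
Environmental factors are standardized linear combinations of module
relative abundances plus Gaussian noise whose SD (`env_noise_sd`,
default 0.5) is a noise-to-signal ratio; a factor with zero loadings is
pure noise. Agronomic records draw replicate values around typical
wheat pot-trial means (grain yield 37.6 / 81.6 / 99.6 g pot⁻¹ for
control / CRU / CRU+FA; fertiliser dose 3.18 g N pot⁻¹, i.e. 450 kg N
ha⁻¹ scaled to a 30 cm pot) with a 5% replicate coefficient of
variation. No replicate-level variances are published for such designs,
so the noise scales are free, fixed choices — not calibrations.

What the generator does **not** emulate: sequence-level artefacts
(chimeras, clustering error), phylogenetic signal, taxa belonging to
several guilds, non-linear environment-community coupling, and
temporal autocorrelation beyond the monotone day ramp. Tests passing on
synthetic data therefore demonstrate that the chain recovers structure
it is designed to see under compositional count noise — not that any
particular field result is reproduced.

## Numerical choices and problem sizes

Sub-streams are derived deterministically from one master seed (stage
offsets on the seed), so a full run is bit-reproducible. The unfolding
polynomial degree (5), the ⌈√m⌉ chi-square bins, the 0.05
Poisson-consistency level and the minimum thresholded dimension (10)
are exposed as arguments of `rmt_threshold()` /
`nnsd_poisson_test()`. Louvain is seeded; module relabeling is
deterministic. Mantel permutations are evaluated by index-mapping the
vectorised lower triangle, so 9999 permutations over 36 samples cost
fractions of a second.

The test suite exercises the full study geometry (36 samples × 300 taxa
at depth 20,000) for recovery and reproducibility checks and scaled-down
variants (60 taxa, depth 2,000; 99-permutation tests) elsewhere; these
sizes are the package's own choice of a thorough-but-quick default
verification, and all stated null-calibration checks (uniform p-values,
FDR control) run at 200-500 simulations.

## Known limitations

* Spearman-on-proportions ignores compositional coupling;
  compositional-aware estimators (e.g. SparCC-style) are out of scope,
  so strong negative correlations can be partly closure-induced.
* The RMT chi-square has limited power for spectra under ~50
  eigenvalues; on small genus-level tables the scan may accept the
  smallest grid candidate. The diagnostic table should be inspected, and
  the grid widened, rather than trusting a single number.
* With 3 replicates per cell the enrichment caller's parametric
  assumption (log-normality) is untestable; treat per-day calls as
  screening, not confirmation.
* NPE inherits the instability of its ratio form when uptake
  differences are small; it is reported missing at exact equality but
  can still be large and noisy near it.
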