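# smfnet

Soil multifunctionality and aggregate-scale microbial co-occurrence
network analysis.

## What this package is for

Vegetation restoration reshapes soil microbial communities, and the
open question in restoration ecology is *which* microbial property —
diversity, community composition, or the complexity of the co-occurrence
network — best predicts soil multifunctionality (SMF), and whether the
answer changes across soil aggregate size fractions. `smfnet` implements
that analysis chain end to end for ecologists working with paired
taxa-abundance and soil-chemistry tables from factorial field designs
(vegetation type × aggregate fraction × replicate plot):

- **SMF scoring** — each C/N/P-cycle indicator min–max standardized across
  all samples, `STD = (X − Xmin)/(Xmax − Xmin)`, then averaged per sample
  into SMF and per-cycle C, N, P functions.
- **Community metrics** — Shannon diversity `H = −Σ pᵢ ln pᵢ`, Bray–Curtis
  dissimilarity, nonmetric multidimensional scaling (Kruskal stress-1 with
  isotonic regression and SMACOF-style updates), one-way ANOVA with
  protected LSD tests and compact letter displays.
- **Co-occurrence networks** — per vegetation × fraction stratum: rare-taxa
  filtering (mean relative abundance ≥ 0.01%, prevalence ≥ 3), Spearman
  correlations with an edge iff |ρ| ≥ 0.8 and p < 0.05, the six standard
  topological parameters, and a **network complexity index**: the mean of
  the min–max standardized parameters across an ensemble of networks, with
  average path length entering as 1/L so all metrics point toward "more
  complex".
- **Driver attribution** — fixed-effects hierarchical partitioning of R²
  over the two design factors and their interaction; PLS path modeling
  (mode A, centroid scheme) with GoF = √(mean communality × mean R²) and
  exact direct/indirect/total effect decomposition; ranking of microbial
  predictors of SMF.
- **Synthetic data with planted truth** — a generator that emulates the
  factorial design (7 × 5 × 4 = 140 samples by default) with correlated
  taxa blocks controlling network complexity, evenness effects controlling
  diversity, and a latent fertility chain wiring both to the soil
  variables with known path coefficients, so every stage of the pipeline
  can be validated against ground truth.

## Worked example

Generate a synthetic survey in which fungal network complexity is the
planted primary driver of SMF (standardized path 0.6, versus 0.1 for
bacterial complexity), then run the full pipeline:

```r
library(smfnet)

design  <- simulation_design(replicates = 20, seed = 42)
dataset <- generate_dataset(design)
dataset
#> <synthetic_dataset> 700 samples; bacteria 50 taxa, fungi 50 taxa, 15 soil variables

result <- run_pipeline(dataset)

compute_multifunctionality(dataset$soil)
#> <multifunctionality> 700 samples, 15 variables (C:5 N:6 P:4)
#>   SMF range: 0.104 - 0.936

result$complexity$fungi
#> <complexity_index> 28 networks, 5 metric(s) [minmax]
#>   excluded constant metric(s): n_nodes
```

The fungal complexity index peaks in the small-size fractions of the
restored vegetation types (e.g. `HR.SC` 0.97, `AV.MI` 0.94), as planted.
The pooled driver model recovers the planted hierarchy:

```r
result$ranking
#> <predictor_ranking>
#>  stratum         predictor     total   tie
#>   pooled fungal_complexity 0.7141231 FALSE

result$drivers$pooled
#> <pls_path_model> 5 latent(s), scheme = centroid, 1 iteration(s)
#>   GoF = 0.7288; R2: SMF=0.531
```

Fungal network complexity ranks first with a standardized total effect of
0.71 on SMF; the model explains 53% of SMF variance. Group statistics and
variance partitioning work the same way:

```r
smf <- compute_multifunctionality(dataset$soil)
anova_lsd(smf$scores$SMF, dataset$metadata$vegetation)
#> <group_comparison> F(6, 693) = 31.36, p = 2.005e-33
#>  group   n      mean letters
#>     AL 100 0.3571994       d
#>     NL 100 0.5133352       b
#>     ...
#>     AV 100 0.6130280       a
```

AV (apricot) carries the highest SMF and the reference abandoned cropland
(AL) the lowest, with LSD letters separating them — the planted
restoration gradient. Letters are assigned so that groups sharing none
differ at α = 0.05.

```r
sh <- shannon_table(dataset$bacteria)
hierarchical_partition(sh$shannon, dataset$metadata$vegetation,
                       dataset$metadata$fraction,
                       names = c("vegetation", "fraction"))
#> <variance_partition> full R2 = 0.1131 (n = 700)
#>   vegetation: 45.09%
#>   fraction: 34.63%
#>   vegetation:fraction: 20.28%
```

See `vignettes/methods.Rmd` for the full account of each method, its
assumptions, and the generator's design.

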