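---
title: "Methods: linking aggregate-scale microbial networks to soil multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking aggregate-scale microbial networks to soil multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfnet)
```

`smfnet` implements an aggregate-scale analysis chain for soil microbiome
surveys: a composite soil multifunctionality (SMF) score, community
diversity and ordination statistics, Spearman co-occurrence networks with a
standardized complexity index, variance partitioning over a
vegetation-by-aggregate factorial, and PLS path modeling of SMF drivers.
This vignette is the package's own account of each method, the tunable
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Study design assumed by the pipeline

The pipeline is organized around a two-factor field design: seven
vegetation types — abandoned cropland (AL) as the reference, natural
grassland (NL), *Medicago sativa* (MS), *Hippophae rhamnoides* (HR),
*Caragana korshinskii* (CK), *Populus alba* (PA), *Armeniaca vulgaris*
(AV) — crossed with bulk soil plus four aggregate size fractions: large
macro-aggregates (> 2 mm, LM), small macro-aggregates (0.25–2 mm, SM),
micro-aggregates (0.053–0.25 mm, MI) and silt/clay (< 0.053 mm, SC), with
four replicate plots per cell (7 × 5 × 4 = 140 samples). Bacterial and
fungal communities are profiled separately; the pipeline consumes finished
taxa-abundance tables, not sequence data.

## Soil multifunctionality

Fifteen indicators tied to carbon (5), nitrogen (6) and phosphorus (4)
cycling are each min–max standardized across **all** samples jointly,

$$\mathrm{STD}_{ij} = \frac{X_{ij} - \min_j X_{\cdot j}}{\max_j X_{\cdot j} - \min_j X_{\cdot j}} \in [0, 1],$$

and averaged per sample: the grand mean is the SMF, the per-cycle means are
the C, N and P cycling functions. Two consequences are used as exact test
identities: with the default schema, $\mathrm{SMF} = (5C + 6N + 4P)/15$,
and SMF is invariant under any increasing affine rescaling of any single
indicator (so unit choices cannot matter). Standardization is pooled
across the whole table rather than within strata so that SMF values are
comparable between vegetation types and fractions. The averaging is
unweighted; threshold-style multifunctionality (counting functions above a
quantile) is deliberately out of scope. A constant indicator has an
undefined standardization and is reported as an error naming the variable
(an explicit `degenerate = "zero"` policy exists for pathological inputs).
Masked cells, when supplied, drop out of the relevant sample's mean with
the divisor adjusted — explicit policy rather than silent `NaN`
propagation.

## Diversity, dissimilarity, ordination and group tests

*Shannon diversity* is $H = -\sum_i p_i \ln p_i$ over positive relative
abundances. The logarithm base is natural — the dominant convention in the
soil-ecology literature — and is exposed as an argument. All-zero samples
yield a missing value rather than being dropped; they are flagged at load
time.

*Bray–Curtis dissimilarity* $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i +
y_i)$ is computed through `vegan::vegdist`. It is a semi-metric: the
triangle inequality can fail, which is why the ordination step is
nonmetric. A pair of all-zero samples has an undefined dissimilarity,
returned as `NA` and listed.

*NMDS* minimizes Kruskal's stress-1,
$\sqrt{\sum (\hat d_{ij} - \hat s_{ij})^2 / \sum \hat d_{ij}^2}$, where
$\hat d$ are configuration distances and $\hat s$ their isotonic
(pool-adjacent-violators) fit in the rank order of the input
dissimilarities. Each iteration alternates the isotonic fit with a Guttman
(SMACOF-type) configuration update; a backtracking step guarantees the
reported stress never increases within a run, which the test suite asserts
per iteration. Ties are handled by the primary (Kruskal) approach: tied
dissimilarities may receive unequal fitted values. The default is 20
starts — the first from classical scaling, the rest random under the
recorded seed — with the best configuration returned, centered and rotated
to principal axes (stress is rotation-invariant). The implementation was
cross-checked against `vegan::monoMDS` on exactly embeddable fixtures.

*Group comparisons* use one-way ANOVA followed by Fisher's LSD: pairwise t
tests on group means with the pooled residual mean square and its degrees
of freedom. The LSD test is *protected* by default — pairwise tests run
only when the omnibus F is significant at `alpha` — matching the
conventional usage in agronomy; an override flag exists. No further
multiplicity correction is applied: that is the definition of the LSD
procedure, and it is stated loudly here rather than silently "improved".
Compact letters are assembled by the insert-and-absorb algorithm, so two
groups share no letter exactly when their pairwise test is significant. A
perfectly constant response returns F = 0 and a single shared letter.

## Co-occurrence networks and the complexity index

Per vegetation × fraction stratum (bulk soil excluded from the
aggregate-scale ensemble by default, includable by configuration):

1. **Filter.** Taxa with mean relative abundance below 0.01% across the
   stratum's samples, or present in fewer than 3 samples, are removed.
   The abundance summary is interpreted as the *mean* — the dominant
   convention when none is stated — with `max` and pooled-`overall`
   variants exposed. Filtered tables keep their original-community
   fractions: renormalizing would rescale every sample by a different
   factor and perturb the cross-sample ranks the next step depends on.
2. **Correlate.** Spearman's rank correlation for every taxon pair, with
   two-sided p-values from the t approximation
   $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ df ($|\rho| = 1$ mapped to
   p = 0); an exact permutation p-value is available for $n \le 9$
   (tie-free profiles). Constant taxa have undefined correlations: they are
   flagged and never form edges.
3. **Threshold.** An edge joins two taxa iff $|\rho| \ge 0.8$ (inclusive)
   **and** p < 0.05. No multiple-testing correction is applied by default —
   the conventional raw-p rule for this network family — with an optional
   Benjamini–Hochberg flag. All filtered taxa remain as nodes, so isolated
   nodes are retained.
4. **Summarize.** Six topological parameters per network, computed with
   `igraph`: node count, edge count, average degree $2E/N$, mean local
   clustering coefficient (nodes of degree < 2 contribute 0), average
   shortest path length, and graph density $2E/(N(N-1))$; plus the
   edges-per-node ratio and the negative-edge proportion as reported
   extras. Path lengths ignore signs and weights. On disconnected graphs
   the average path length is taken over connected pairs only (the count
   of unreachable pairs is reported) — stable for the sparse graphs this
   threshold produces — and is undefined when no pair is connected.
5. **Index.** Across the ensemble of a community's networks, each metric
   is min–max standardized (the same 0–1 scheme as the SMF indicators;
   z-scores available by configuration) and averaged into the network
   complexity index. The average path length enters as its reciprocal
   $1/L$ — an inverse in the literal sense — so that every metric points
   in the "more complex" direction. Metrics constant across the ensemble
   carry no information and are excluded (and listed); an undefined path
   length becomes a missing metric with the divisor adjusted. The
   edges-per-node ratio is reported but *not* part of the index, whose
   metric set is the six enumerated parameters.

A consequence worth noting: with the paper-scale four replicates per
stratum, the edge rule essentially cannot fire — the minimal two-sided
exact Spearman p at $|\rho| = 1$, $n = 4$ is $2/4! = 1/12 > 0.05$, and
the t approximation only passes at $|\rho| = 1$ exactly. The sample count
per network and the p-value method are therefore explicit parameters, and
all network-recovery studies in this package use 20 replicates per
stratum.

## Attributing SMF variation

*Variance partitioning* over the two design factors is computed as
fixed-effects hierarchical partitioning of $R^2$: OLS models for every
admissible subset of {vegetation, fraction, interaction} (the interaction
only alongside both mains), each term's contribution averaged over the
orderings of entry that respect that hierarchy, then rescaled to percent
of the full model's explained variance. The shares sum to exactly 100%,
and in a balanced orthogonal design they reduce to the classical ANOVA
sums-of-squares fractions (a test identity). This fixed-effects reading
was chosen deliberately: the two factors are themselves the quantities
being partitioned, and hierarchical partitioning is what the relevant
package family computes; no random-effects structure is estimated.

*PLS path modeling* estimates latent variables as weighted composites of
their manifest blocks (all blocks reflective, mode A) via the classical
Lohmöller/Wold alternating algorithm, with the centroid inner scheme by
default (factorial and path schemes available; these are the package-family
defaults). Convergence requires the largest absolute outer-weight change
to fall below `tol` (default 1e-7, cap 300 iterations; non-convergence is
an error carrying the weight-change trace). Path coefficients are OLS
regressions among the unit-variance latent scores; fit is summarized by
communalities, per-endogenous $R^2$, and
$\mathrm{GoF} = \sqrt{\overline{\mathrm{communality}} \times \overline{R^2}}$,
an identity the tests hold to 1e-12. Effects decompose exactly into
direct + indirect, with totals obtained from powers of the
path-coefficient matrix. With single-indicator blocks the procedure
degenerates to closed-form standardized path analysis, which the tests
verify to 1e-8 — and which is exactly the regime of the driver models
below. Community composition can enter such models as the first
principal-coordinate axis of the Bray–Curtis matrix (classical
double-centered eigen-decomposition); the block composition of any
larger model is user-declared, since no canonical indicator grouping
exists.

*Driver ranking.* The standardized total effects on SMF are collected
across strata (or from a pooled model), sorted by absolute value, and the
top microbial predictor identified; exact ties break lexicographically and
are flagged.

## The synthetic-data generator

The generator exists to give every downstream stage a planted,
recoverable ground truth; it makes no attempt at marginal realism.

- **Abundances** are exponentiated correlated Gaussians: a log-normal
  marginal with a Gaussian copula. Since every network statistic here is
  rank-based, only the copula matters; the log-normal supplies realistic
  skew. Correlation blocks (default 6 taxa at copula correlation 0.9,
  0.95 in recovery tests) are planted per stratum; strata with more
  blocks yield more edges in expectation, monotonically (a tested
  property). A fraction of blocks (default 0.3) carries one
  anti-correlated member, producing negative-edge proportions of a few
  to ~15 percent in the fungal ensembles — the order observed in field
  co-occurrence studies.
- **Abundance ranks are assigned to taxa in seeded random order**, so a
  correlated block spans the whole abundance range. This matters: pinning
  blocks to the most abundant taxa lets compositional closure (per-sample
  division by the total) visibly distort every taxon's relative abundance
  and destroy the planted rank correlations. With permuted assignment, a
  planted 6-taxon block at copula 0.95 and n = 20 passes the edge rule
  for ~97% of its pairs on average.
- **Evenness effects** per vegetation and fraction scale the spread of
  the log-abundance means, planting recoverable Shannon-diversity
  differences (bacterial diversity raised by restoration, most in AV;
  fungal diversity raised in MS/CK, lowered in HR/PA).
- **The causal chain** is: stratum → planted block counts (network
  complexity) and evenness (diversity) → a per-sample latent fertility,
  formed from the standardized per-stratum targets through the design's
  path coefficients (defaults 0.6 fungal complexity, 0.3 bacterial
  diversity, 0.1 each for the other two, latent noise sd 0.5) → fifteen
  soil variables, each a positive loading (uniform on 0.7–1) times the
  latent plus noise (sd 0.5). Positive loadings make min–max averaging
  monotone in the latent, so at zero noise the SMF ranking equals the
  latent ranking exactly; at the default noise the latent–SMF Spearman
  correlation is ~0.99 at n = 140 (a pre-simulated band held by the
  tests).

What passing tests therefore show about real data — and what they do not:
recovery results demonstrate that the pipeline's statistics faithfully
recover the kind of structure they assume (rank-correlation blocks,
monotone latent-driven soil variables, factorial group effects). Real
communities add compositional dependence beyond closure, phylogenetic
structure, sequencing noise and uneven depth, none of which are simulated;
a passing suite does not certify performance under those features.

## Problem sizes and numerical choices

The test and reproduction runs use sizes chosen to make every recovery
statistic stable while keeping a full run on one CPU in minutes: 50 taxa
per community, 20 replicates per stratum (700 samples) for network-scale
studies, the 140-sample field design for diversity/ordination and null
calibration, 50 seeds for the end-to-end recovery rate, 200 replicates for
the type-I-error check, and 200 random graphs for the topology oracles.
Other numerical conventions: average ranks for ties throughout; Spearman
values clipped to [-1, 1] before thresholding; the NMDS improvement
tolerance is 1e-7 on stress with backtracking steps halved down to 1e-4;
PLS-PM latent signs are oriented so each block's mean loading is positive;
complexity indices average only the defined standardized metrics.

## Known limitations

- Co-occurrence edges are plain rank correlations: no compositional
  correction (SparCC/SPIEC-EASI-style methods are out of scope), so
  closure-induced dependence is mitigated only by the breadth of the
  community.
- The hard $|\rho| \ge 0.8$, p < 0.05 rule interacts strongly with the
  per-stratum sample count; networks built at different n are not
  comparable, which is why the complexity index standardizes within an
  ensemble built at a common n.
- The mixed-model phrasing of the contribution analysis is implemented as
  its fixed-effects hierarchical-partitioning counterpart, as discussed
  above.
- PLS-PM composite scores attenuate path coefficients relative to a true
  latent-variable model (mean absolute bias ~0.075 in the three-latent
  recovery setting used by the tests); the package reports what PLS-PM
  estimates, not disattenuated coefficients.
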