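---
title: "Methods: diversity partitioning and community inference in fragbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity partitioning and community inference in fragbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragbeta)
```

This vignette documents the statistical machinery of `fragbeta`: the
models it fits, the assumptions they carry, the numerical and design
choices made where several defensible options existed, and what the
synthetic-data generator does and does not emulate.

## Diversity partitioning

All diversities are Hill numbers of order 1 on natural logarithms: a
site's abundance vector is converted to relative abundances `p`, and
`alpha = exp(-sum(p * log(p)))` is the *effective* number of species —
the count of equally-common species that would produce the observed
entropy. The fragment-level `gamma` pools the counts of all sites in the
fragment column-wise and applies the same estimator. Proportional
turnover is `beta = 1 - alpha/gamma`, the fraction of regional effective
diversity missing locally. We deliberately implement only order q = 1:
richness (q = 0) appears solely as an internal helper, and no additive
partitioning ("regional diversity excess") is provided.

**Bias correction.** `hill_shannon()` optionally replaces the plug-in
entropy with the Chao–Shen coverage-adjusted Horvitz–Thompson estimator:
sample coverage is estimated as `C = 1 - f1/n` (`f1` singletons, `n`
individuals), relative abundances are shrunk to `C * p`, and each term is
inflated by its detection probability `1 - (1 - C p)^n`. We chose
Chao–Shen because it is the standard ecological entropy correction built
from quantities (`f1`, `n`) the data always provide; the toggle defaults
to `"none"` so that the exact identity `beta = 1 - alpha/gamma` on
plug-in quantities — which several invariants and tests rely on — holds
by construction. Corrected estimates may exceed observed richness, and a
site's corrected `alpha` may exceed the pooled corrected `gamma`,
producing negative `beta`. We do not clamp: negative values are reported
with a warning, because truncation would hide exactly the configurations
a user needs to see. When every species is a singleton the coverage
estimate degenerates to zero; we substitute `f1 = n - 1`, the usual
finite-sample guard.

**The null model.** The standardised deviation `beta_dev` asks whether a
site's turnover differs from what random assembly would produce given
the species' prevalences. Our null model holds, for every species, its
*occupancy count* and its *abundance multiset* fixed: the set of occupied
sites is redrawn uniformly among equal-sized subsets and the observed
positive abundances are permuted onto them. This honours "fixed species
occurrence frequencies" literally while conserving column sums and the
grand total, so gamma remains on a comparable scale across
randomisations. A cell-wise shuffle would instead destroy the species
abundance structure. Two toggles cover the remaining ambiguity in how
such nulls are used in practice: `fixed_gamma = TRUE` freezes gamma at
its observed value inside the loop (by default gamma is recomputed per
randomisation, letting pooling effects propagate into the null
distribution), and `incidence_only = TRUE` reduces all matrices to
presence/absence before any diversity computation, in which case alpha
and gamma become site and pooled richness. A randomised site can lose all
its species; its null beta is then set to 1 (no local diversity remains),
the value the limit `alpha -> 1, gamma` large approaches from within the
occupied region and the only choice that keeps the null distribution
defined without discarding randomisations. Sites whose null SD is zero
get `beta_dev = NA` with a warning rather than an infinity.

## Differentiation diversity

Bray–Curtis dissimilarity `sum|x-y| / sum(x+y)` is computed on
square-root transformed abundances by default; the transform damps
dominance so that compositional signal is not monopolised by the few most
abundant species. Although the field convention speaks of a "similarity
matrix", all internal computation uses the dissimilarity `1 - s` — the
conversion is lossless and ordination machinery expects distances.

**PCoA and its negative eigenvalues.** Principal coordinates
double-centre the squared dissimilarities (Gower's matrix) and
eigen-decompose. Bray–Curtis is a semimetric, so negative eigenvalues
occur; they are reported but carry no coordinates. We apply no Lingoes or
Cailliez correction by default — the corrections distort the
interpretable positive part, and every downstream quantity is defined on
the representable embedding. Dispersion-type statistics (multivariate
dispersion of vegetation subplots, functional dispersion) use the
standard real/imaginary split: squared distances to the centroid on
imaginary axes are subtracted from those on real axes and the total is
truncated at zero.

**PERMANOVA.** The total sum of squared dissimilarities is partitioned
via the trace form `tr(H G)` with cumulative hat matrices, which is
algebraically the McArdle–Anderson decomposition; terms are sequential
(Type I) in user order, matching the convention of the permutational
MANOVA implementations this workflow descends from, with a marginal
(`by = "margin"`) alternative. Inference co-permutes rows and columns of
the Gower matrix and recomputes every term's pseudo-F. The p-value counts
the observed statistic in numerator and denominator,
`p = (1 + #{F* >= F}) / (1 + n_perm)`, guaranteeing `p > 0` and validity.
When `n!` does not exceed the requested permutation count the full
permutation group is enumerated instead (a notice is emitted), so tiny
designs get exact p-values. Statistic comparisons use a `1e-12` slack so
that ties arising from permutation symmetry are counted as extreme.

**CAP / db-RDA.** Site coordinates on the positive-eigenvalue axes
(eigenvalue-weighted, so squared distances are preserved) are regressed
on z-standardised predictors. Total inertia is the sum of positive
eigenvalues — the variation the embedding can represent — and each
sequential term's share of it is the "explained variation" reported.
Permutation inference permutes the rows of the coordinate matrix and
recomputes the sequential statistics, the same raw-data scheme as the
PERMANOVA stage; with no covariates outside the tested model this is
exchangeable under the null. Collinear predictor sets are rejected by a
condition-number threshold (`1e8`) with the most-correlated pair named.

**IndVal.** Specificity `A` uses unweighted per-site group means (robust
to unequal group sizes, per the original formulation), fidelity `B` is
the occupied fraction of the group's sites, and the species statistic is
the maximum of `A * B` over groups, tested by permuting site labels (with
exact enumeration on tiny designs, as above). No multiple-testing
correction is applied inside the module — reported probabilities are raw,
as is conventional for indicator listings — and `bh_fdr()` can be applied
across species downstream. The screening stage, by contrast, always
applies table-wise Benjamini–Hochberg control, because there the p-values
are read as a family.

## Environmental predictors

**PCQ forest structure.** Tree density uses Pollard's unbiased
point-centred-quarter estimator `lambda = 4(4n - 1) / (pi * sum(d^2))`
(n points, quarter distances `d` in metres), scaled to trees/ha. The
classical Cottam–Curtis `1/mean(d)^2` form is available via
`estimator = "cottam"` for comparison; Pollard's form is the default
because it is exactly unbiased for a homogeneous Poisson forest — a
property the acceptance suite verifies directly. Basal area per tree is
`pi (dbh/2)^2` in cm²; class cover multiplies class density by the
class's mean basal area (m²/ha). Points missing a quarter are excluded
with a warning rather than patched.

**Landscape metrics.** Habitat diversity is the Shannon index over the
*natural* classes only — forest, reed, grassland — renormalised to sum to
one; water and human-modified classes are excluded because the quantity
is meant to measure the diversity of natural habitat, not of land use.
Edge density divides the boundary length by the buffer area
`pi r^2 / 10^4` ha. The modified-areas fraction sums agriculture and
urban/industrial cover.

**Varimax PCA.** Variables are standardised and the correlation matrix
eigen-decomposed. We use the correlation (not covariance) matrix because
the inputs mix units (trees/ha, m, fractions, indicator scores); a
covariance PCA would be dominated by whichever variable has the largest
numeric range. Axes with eigenvalue strictly greater than 1 are retained
(Kaiser criterion; the strict inequality resolves the borderline case of
uncorrelated unit-variance variables), rotated by normalised varimax
(Kaiser normalisation, convergence `1e-6`), and scores extracted by the
regression method (`Z R^{-1} L`), the common default among rotated-PCA
implementations; Bartlett scores differ only in weighting and were not
needed. Rotation is checked to preserve communalities to `1e-8` and total
retained variance exactly. Because rotated axes are sign-indeterminate, a
deterministic convention — the variable with the largest absolute loading
is made positive — keeps scores reproducible across runs and platforms.
Axis *names* ("humidity–nutrient gradient", …) are user metadata supplied
via `axis_names`; the package never infers them from loadings.

**Other derivations.** Ellenberg means are unweighted over the species
present at a site, per index, skipping missing scores. Functional
dispersion uses Gower distances over the mixed trait table
(`cluster::daisy`) and equal species weights, because the vegetation data
are incidences; abundance weighting is exposed for other data.

## Univariate models

Variable screening uses a hand-implemented Mann–Whitney U with the
tie-corrected normal approximation and continuity correction (the signed
z value is part of the reported table, which `stats::wilcox.test` does
not expose); it is cross-checked against `wilcox.test` exactly and
against the exact permutation distribution to within 0.02. The β_dev
models are ordinary least squares: no grouping structure below the
fragment exists in the design, so mixed-effects machinery would add a
random effect with nothing to estimate; a fragment fixed effect can be
added through the candidate set. Model search is bidirectional stepwise
on AIC (`MASS::stepAIC`, k = 2, Gaussian likelihood with the constant
included) starting from the full additive model; standardised
beta-coefficients (`b * sd(x)/sd(y)`) are reported alongside raw ones so
effect sizes are comparable across axes.

## The synthetic generator

`generate_scenario()` realises a two-fragment design: expected counts are
`effort * base_k * fragment_multiplier_k * prod_g exp(-(x_i - opt_k)^2 /
(2 tol_k^2))`, Poisson-sampled (negative binomial via the
`overdispersion` toggle). Latent gradients are standard normal across
sites; observed proxy variables are linear in them with stated loadings
and unit total variance, which makes PCA-axis recovery well-posed.
Defaults emulate the targeted field design: 30 sites per fragment, a
392-species pool, log-normal base abundances with `meanlog = log(0.21)`,
`sdlog = 2.2` and niche tolerances in `[0.5, 1.5]` — chosen once so that
a default realisation yields roughly 400 individuals per site, about 15%
pooled singletons, and a between-fragment composition shift (multiplier 4
on 30% of species, half up and half down) whose PERMANOVA R² is near
0.12, the magnitudes reported for the source system. With
`fragment_effect = 1` the fragments are exchangeable by construction,
which makes the generator the null oracle for every permutation test in
the pipeline.

What the generator does **not** emulate: spatial autocorrelation and site
coordinates, seasonal or between-year phenology, detection covariates
(moonlight, weather), and the evenness profile of the field data — the
heavy log-normal tail that reproduces the singleton fraction also
produces stronger dominance, so realised effective diversities (α ≈
15–35, γ ≈ 30–40) run below the field values (α ≈ 40, γ ≈ 75), and
realised mean proportional β varies more across seeds than a real
resampled community would. Passing tests therefore certify the
statistical machinery — calibration, conservation laws, recovery of
planted structure — not that any particular field value is reproduced.

## Problem sizes and tolerances in the test suite

The suite chooses sizes that make each property measurable rather than
large: exhaustive oracles run at 6 sites (720 permutations / 20
labelings); null calibration uses 500 scenarios of 12 sites × 30 species
at 199 permutations, judged against the exact binomial 95% band around
0.05; β_dev standardisation uses 50 null matrices at 199 randomisations
with the grand mean required inside ±0.15 and the SD inside [0.7, 1.3];
planted-structure recovery uses 200 stepwise-AIC simulations (retention
≥ 95% for the planted axis, < 50% for each noise axis), 50 CAP scenarios
(strongest proxy ranked first ≥ 90%), and factor congruence > 0.95; the
PCQ estimator must reach a median relative error below 10% on 100
simulated 300 trees/ha forests of 200 points. Numerical equality against
the independent cross-checks (vegan's `vegdist`, `adonis2`,
`capscale`, `betadisper`; exact enumeration oracles) is asserted at
`1e-8`–`1e-12`.

## Known limitations

Sequential CAP percentages depend on predictor entry order (use
`by = "margin"` for order-free shares). The null model treats sites as
exchangeable within a fragment; spatially structured occupancy would need
a restricted randomisation the package does not provide. The Chao–Shen
correction, applied to both α and γ, can push `beta` negative for
well-sampled, even sites; the warning is the intended behaviour, not an
error. Season splitting (early vs late assemblages) is left to the user:
every analysis treats one community matrix.
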