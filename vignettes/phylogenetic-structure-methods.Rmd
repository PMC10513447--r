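---
title: "Methods: phylogenetic structure of alien communities across invasion stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic structure of alien communities across invasion stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimator

Alien plant species arrive, naturalize, and some become invasive. If
ecological niches are phylogenetically conserved, environmental filtering
should assemble communities of closely related species, and the strength of
that clustering may differ between invasion stages and between spatial
scales. `phyloinvasion` quantifies this with the two standard community
phylogenetics indices:

* **MPD**, the mean pairwise patristic distance among an assemblage's
  species, and **NRI** = −SES(MPD), its standardized effect size against a
  null model, sign-flipped so positive values mean clustering;
* **MNTD**, the mean distance from each species to its nearest co-occurring
  relative, and **NTI** = −SES(MNTD), sensitive to structure near the tips.

Both indices come in a presence (unweighted) and an abundance-weighted form.
The abundance-weighted MPD uses pair-product weights,

$$\mathrm{MPD}_w = \frac{\sum_{i<j} a_i a_j d_{ij}}{\sum_{i<j} a_i a_j},$$

and the weighted MNTD weights each species' nearest-neighbour distance by
its abundance. The pair-product form excludes the zero-distance diagonal
terms $a_i^2 d_{ii}$; some other implementations keep them in the
denominator, which rescales the statistic by
$((\sum a)^2 - \sum a^2)/(\sum a)^2$. Our tests cross-check against such an
implementation with that conversion made explicit.

### The null model

The null model shuffles species names across **all** tips of the supplied
phylogeny and recomputes the statistic for the relabelled assemblage with
its original abundances. Because the permutation acts on the whole tree,
each replicate is equivalent to mapping the assemblage onto a uniform random
set of distinct tips — which is how `null_distribution()` implements it.
The null pool is deliberately the whole phylogeny, not the per-scale species
pool: the community-size and abundance structure are preserved while
phylogenetic position is randomized.

SES uses the population (denominator-$N$) standard deviation of the
replicates. When the null standard deviation is zero (e.g. the assemblage
is the entire pool) the SES is reported as undefined and flagged, never
as 0, so downstream means are not silently biased.

For small trees `ses_exhaustive()` enumerates all $\binom{n}{k}$ subsets and
returns the exact null moments; the test suite uses it as the oracle for the
Monte-Carlo null. On the four-tip tree `((A:1,B:1):1,(C:1,D:1):1);` the
two-species null support is {2, 4} with probabilities 1/3 and 2/3, giving
mean 10/3, sd $2\sqrt2/3$, and an exact NRI of $\sqrt2$ for the pair {A, B}
— a closed form the Monte-Carlo estimate must approach at rate
$O(1/\sqrt{R})$.

### Anomalies

The *phylogenetic anomaly* contrasts the all-status community of a spatial
unit against each status-defined subset of the same unit:
`anomaly = metric(All) − metric(subset)` under the default
`all_minus_subset` convention. The verbal definition of this quantity in the
literature is ambiguous about sign — narrative statements about "negative
anomalies when invasives are included" read more naturally with the opposite
orientation — so both conventions are implemented behind a flag and the
convention is recorded in every output row.

## Community construction

Occurrence records (species, lon, lat, invasion status) are deduplicated
exactly per (species, lon, lat), then spatially thinned: walking the records
of each species in a fixed (species, lon, lat) sort order, a record is kept
iff it lies ≥ 5 km (haversine, sphere radius fixed at 6371 km for
bit-reproducibility) from every previously kept record of that species.
Greedy input-order thinning is not the globally optimal rarefaction, but
with the fixed presort it is deterministic, idempotent, and guarantees the
postcondition (no retained intra-species pair closer than the threshold).
Thinning is per species, matching the common species-distribution-modelling
default; the 5 km default matches a 2.5-arcminute climate grid. Both are
configurable.

Thinned records are assigned to the rectangular units of each spatial scale
(closed bounds; a point on a shared edge goes to the lexicographically
smallest unit id, for determinism; points outside every unit are dropped and
counted — the analog of discarding points that fall in the sea). Within each
unit, seven assemblages are built by status subsetting: Inv, Nat, Int, the
pairwise unions InvNat, InvInt, NatInt, and All. "Occurring alone" is
interpreted as status-subsetting within the unit, not as units exclusively
occupied by one status — only subsetting yields the same number of units for
every community type at a scale, which is what the downstream balanced
comparisons require. Assemblages with fewer than two species are emitted but
flagged unusable.

## Mega-tree grafting

Species absent from a backbone phylogeny are attached at genus level,
preserving ultrametricity:

* genus with ≥ 2 backbone tips — the new tip joins, as a polytomy, the crown
  node of the genus' **largest monophyletic cluster** (most tips; ties go to
  the shallower crown), with pendant length equal to that node's height;
* genus with one tip — the pendant branch is bisected at its midpoint;
* genus absent — the tip is attached at a user-supplied family node by the
  same polytomy rule. Attaching at interior fractions of family branches
  (as some grafting tools do) is deliberately not emulated: the family-node
  polytomy is a simpler, documented stand-in, isolated in one operation and
  logged when used.

Genus is inferred from the `Genus_epithet` tip-label prefix unless an
explicit genus→tips map is supplied. Grafting never alters distances among
pre-existing tips, which the tests verify by graft-then-prune round trips.

## The synthetic world

The generator produces every input the pipeline needs, with the statistical
structure the analysis assumes:

* **Tree** — a pure-birth (Yule) tree (`ape::rphylo` with zero extinction):
  ultrametric, one parameter. Defaults emulate a national alien flora of
  706 species.
* **Climate niches** — a per-species temperature optimum evolved by Brownian
  motion along the tree. The rate is scaled by tree height so tip optima
  have standard deviation ≈ √sigma2 (default sigma2 = 25, i.e. ≈ 5 °C-like
  units) regardless of tree size; close relatives therefore share similar
  niches (niche conservatism).
* **Climate grid** — a lattice whose temperature surrogate (BIO1) is linear
  in latitude (default −0.55 units per degree, a temperate lapse) and whose
  precipitation surrogate (BIO12) is linear in longitude, each plus iid
  Gaussian noise (sd 0.5).
* **Statuses** — introduced/naturalized/invasive in proportions
  165/222/319 of 706 with largest-remainder rounding. In the default
  `clade_biased` mode the invasive labels are placed inside the smallest
  clade that can hold them (ties broken at random), emulating a
  lineage-restricted invasive pool; `random` mode is the neutral control.
* **Regions** — four independent rectangular lattices of 7, 16, 34 and 47
  units tiling a China-like extent (73–135°E, 18–53°N), mirroring
  habitat-type, climate-class, province and ecoregion tiers. The lattice
  construction (rows = ⌊√m⌋, columns split by largest remainder) is fully
  deterministic, so the region generator takes no seed.
* **Occurrences** — each species' points land in grid cells with probability
  ∝ Gaussian(cell BIO1; optimum, tolerance), uniformly within the cell
  (default tolerance 3, default 124 points per species — the
  occurrences-per-species density of a cleaned national dataset). Cell
  weights are computed in log space and normalized, so distant optima never
  underflow to a zero placement probability. Filtering acts on temperature
  only by default (temperature dominates precipitation as a filter in the
  motivating system); BIO12 is carried for the regression layer.

With conserved niches and a smooth gradient this construction guarantees
environmental filtering: nearby cells host closely related species, so
per-unit assemblages are phylogenetically clustered — the property the
end-to-end tests assert. What the generator does **not** emulate: realistic
species-range geometry, spatially autocorrelated sampling effort, dispersal
limitation, biotic interactions, coastlines or irregular region polygons.
Passing tests therefore demonstrate that the estimator recovers structure a
filtering process put in, not that any real flora behaves this way.

### A known scale effect

Standardized effect sizes grow roughly with the square root of assemblage
richness for a fixed ecological signal, and coarser spatial units always
contain more species. In lattice worlds this richness effect generally
dominates the scale contrast, so mean NRI at the coarsest scale often
exceeds that at the finest scale — the corresponding directional test in the
acceptance suite documents this honestly rather than asserting around it.
Comparisons of NRI across scales should always be read jointly with the
per-scale richness distributions.

## The statistics layer

* **AICc** = AIC + 2k(k+1)/(n−k−1), with k counting intercept, slopes and
  the Gaussian residual-variance parameter; undefined (NA) when n ≤ k+1.
* **Data-mode selection** fits the same model (default
  `metric ~ community_type`) to the presence and abundance results for both
  NRI and NTI and picks the mode with the lower summed AICc; ties go to
  abundance and are flagged. The responses are unbounded, so the comparison
  models are Gaussian GLMs; a binomial family would be undefined here.
* **Two-way ANOVA** (community type × scale) uses Type-II sums of squares
  (via `car::Anova`), the main-effect-focused convention; Type-II equals
  Type-I in balanced designs, which the tests exploit. A zero residual sum
  of squares is flagged degenerate with all F reported as 0 rather than
  infinite.
* **Post hocs** are all pairwise Welch t tests (unequal variances; pooled t
  available) with step-down Holm adjustment.
* **Spearman correlations** use mid-ranks and the asymptotic t
  approximation for p.
* **Climate regressions** fit `metric ~ BIO1` and `metric ~ BIO12`
  separately within each (community type, scale, metric) stratum; strata
  with n ≤ 4 or a constant covariate are skipped with a logged message.

## Numerical and reproducibility choices

* Every stochastic function takes an integer seed and restores the caller's
  RNG state; pipeline stage seeds are derived from one master seed by a
  fixed 32-bit-safe recurrence. Identical configurations give byte-identical
  output files (manifest timestamps are omitted for this reason).
* Null-model replicates default to 9999; the test suite and worked examples
  use 99–999. The calibration checks in the acceptance suite use a 100-tip
  tree, 500 communities of 10 species and 999 replicates; the end-to-end
  world uses 120 species, 40 points per species, scales of 7 and 47 units
  and 199 replicates.
* Ultrametricity is tested with an absolute tolerance on root-to-tip depths
  (default 1e-8 in branch-length units), not a relative criterion.
* Missing newick branch lengths parse as 0 with a warning; duplicate tip
  labels are an error.

## Worked example

```{r, eval = FALSE}
library(phyloinvasion)

ds <- simulate_invasion_dataset(n_species = 60, points_per_species = 30,
                                region_counts = c(pro = 9), seed = 42)
occ <- thin_occurrences(dedupe_occurrences(ds$occurrences), 5)
mat <- assign_to_regions(occ, ds$regions$pro)
asm <- build_assemblages(mat, ds$statuses)

fit <- phylo_structure(ds$tree, asm, data_mode = "both",
                       replicates = 999, seed = 1)
fit
summary(fit)
plot(fit)

anomalies(fit)
select_data_mode(fit)$mode
```

## Limitations

* The tip-shuffle null conditions on the whole supplied phylogeny; per-pool
  nulls (e.g. per-scale pools) are out of scope.
* Regions are axis-aligned rectangles; irregular polygons must be converted
  to a lattice upstream.
* No correction for spatial autocorrelation beyond thinning, no
  phylogenetic uncertainty propagation, and no beta-diversity or
  Faith-PD metrics.
* The family-node attachment for genera absent from a backbone is a
  simplification of fractional-branch placement used by some grafting
  tools.
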