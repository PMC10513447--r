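# phyloinvasion

Community phylogenetics of alien floras along the invasion continuum.

Alien plant species pass through stages — introduced, naturalized, invasive —
and if climate niches are phylogenetically conserved, environmental filtering
should assemble communities of close relatives. `phyloinvasion` is for
ecologists who want to ask, at several spatial scales at once, *how
phylogenetically clustered are the alien assemblages of each invasion stage,
and what does climate do to that clustering?*

## What it computes

For an assemblage of species on a dated phylogeny with patristic distances
$d_{ij}$ and abundances $a_i$:

* **MPD** — mean pairwise distance; abundance-weighted form
  $\mathrm{MPD}_w = \sum_{i<j} a_i a_j d_{ij} / \sum_{i<j} a_i a_j$.
* **MNTD** — mean distance to the nearest co-occurring relative,
  abundance-weighted as $\sum_i a_i \min_{j \ne i} d_{ij} / \sum_i a_i$.
* **NRI / NTI** — standardized effect sizes of MPD / MNTD against a null
  that shuffles species names across *all* tips of the phylogeny
  ($R$ = 9999 by default), sign-flipped so positive = clustering:
  $\mathrm{NRI} = -(\mathrm{MPD}_\mathrm{obs} -
  \overline{\mathrm{MPD}}_\mathrm{null}) / \sigma_\mathrm{null}$.
* **Phylogenetic anomalies** — metric(All statuses) − metric(status subset)
  per spatial unit, under a recorded sign convention.
* A downstream layer: AICc choice between presence- and abundance-based
  metrics, two-way ANOVA (community type × scale, Type-II SS) with
  Holm-adjusted Welch post hocs, per-stratum climate regressions on
  BIO1/BIO12 surrogates, and Spearman correlations between community types.

Everything upstream is included: newick I/O and validation, mega-tree
grafting of species missing from a backbone (genus polytomies that preserve
ultrametricity), exact deduplication, 5-km haversine spatial thinning,
point-to-region assignment, and the seven status-defined assemblages (Inv,
Nat, Int, InvNat, InvInt, NatInt, All) per spatial unit. A seeded generator
builds a full synthetic world — Yule tree, Brownian climate optima,
rectangular region lattices at four scales (7/16/34/47 units), a smooth
climate grid, and climate-filtered occurrences — so the entire pipeline runs
and is testable without any external downloads.

## Worked example

```r
library(phyloinvasion)

ds  <- simulate_invasion_dataset(n_species = 60, points_per_species = 30,
                                 region_counts = c(pro = 9), seed = 42)
occ <- thin_occurrences(dedupe_occurrences(ds$occurrences), 5)
mat <- assign_to_regions(occ, ds$regions$pro)
asm <- build_assemblages(mat, ds$statuses)

fit <- phylo_structure(ds$tree, asm, data_mode = "abundance",
                       replicates = 999, seed = 1)
fit
#> Phylogenetic community structure (NRI/NTI, tip-shuffle null)
#>   null pool: 60 tips; replicates: 999; seed: 1
#>   assemblages: 63 (63 usable) across 1 scale(s), modes: abundance
#>   mean NRI: 6.150   mean NTI: 1.723

summary(fit, by = "community_type")
#>   community_type n NRI_mean NRI_se NTI_mean NTI_se
#> 1            All 9     2.95  1.226     1.02  0.433
#> 2            Int 9     6.56  1.049     1.90  0.108
#> 3            Inv 9    12.25  1.698     2.88  0.270
#> ...
```

The positive mean NRI (6.15) says the synthetic world's environmental
filtering produced assemblages of closer relatives than the tip-shuffle null
expects; the invasive communities (NRI 12.25 ± 1.70) are markedly more
clustered than the others, as they should be — the generator placed the
invasive pool inside one clade. `anomalies(fit)` then contrasts each status
subset against the unit's full community:

```r
head(anomalies(fit), 3)
#>   scale    unit community_type data_mode metric anomaly  sign_convention
#> 1   pro pro_u01            Int abundance    NRI -2.4916 all_minus_subset
#> 2   pro pro_u01            Int abundance    NTI -0.2210 all_minus_subset
#> 3   pro pro_u01            Inv abundance    NRI -6.1243 all_minus_subset
```

`run_all()` chains the whole pipeline (simulate/load → validate → dedupe →
thin → communities → metrics → anomalies → statistics) from one YAML config
and writes CSVs plus a JSON manifest; `inst/cli/phyloinvasion.R` exposes
`simulate`, `run-all` and `validate` subcommands for shell use.

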