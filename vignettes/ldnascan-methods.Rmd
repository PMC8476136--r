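---
title: "Methods: LD-network scans for parallel marine–freshwater selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-network scans for parallel marine-freshwater selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldnascan)
```

# The problem

Marine sticklebacks (and many other euryhaline fishes) have repeatedly
colonized freshwater, and freshwater-adapted alleles are often identical by
descent across independently colonized populations — parallel evolution from
standing genetic variation. Detecting the genomic regions involved from
low-coverage data poses three coupled problems:

1. **Complexity reduction.** Millions of SNPs, many of them tagging the same
   haplotype, make single-SNP tests both redundant and brutally multiplicity-
   penalized. `ldnascan` clusters loci by linkage disequilibrium into
   networks and tests one synthetic variable per cluster.
2. **Confounding by population structure.** Ecotype (marine = 0,
   freshwater = 1) is a population-level attribute, so any genome-wide
   structure inflates association statistics. The package combines a
   relatedness random effect, a lineage covariate, genomic control, and
   max-statistic permutation into four correction regimes.
3. **Parameter sensitivity.** Cluster definitions depend on tuning
   parameters with no single correct value. Rather than picking one setting,
   the pipeline runs a grid of 36 cluster-parameter combinations crossed
   with the 4 correction regimes (144 tests) and scores each candidate
   region by the proportion of tests that recover it (the consistency score
   C).

A final diagnostic asks whether a significant region reflects selection on
an *ancient* haplotype: such haplotypes have deeply coalescing histories and
show excess absolute divergence (d~XY~) between marine and freshwater
populations relative to what their diversity predicts (Δd~XY~).

# Nested LD-network clustering and SMLAs

Pairwise LD is the squared Pearson correlation r² of posterior-mean dosages
E[g] = GL~1~ + 2·GL~2~ computed from normalized genotype likelihoods (the
package consumes beagle-format files as emitted by ANGSD-style callers).
Clustering proceeds in three nested stages so that the genome-wide stage
operates on a few hundred objects rather than on all SNPs:

* **Level 1** — within non-overlapping windows (default 100 kb), edges with
  r² ≥ `edge_floor` (default 0.3) are scanned in decreasing r² order while
  connected components are tracked; a component is emitted as a cluster the
  first time it contains |E|~min~ internal edges, and its loci are then
  frozen. This single-parameter birth rule replaces threshold-picking: ties
  are broken by locus coordinate, so the output is deterministic and
  independent of edge ordering (a brute-force re-derivation after every edge
  addition is used as the test oracle).
* **Level 2** — per chromosome, the same extraction runs on a graph whose
  nodes are level-1 clusters and whose edges are r² between their SMLA
  coordinate vectors.
* **Level 3** — genome-wide single linkage over SMLA r², cut so the weakest
  within-cluster link is at least Cor~th~; level-1 clusters with more than
  SNP~min~ loci that were not absorbed at level 2 also enter. Raising
  Cor~th~ can only split clusters (monotone refinement), and no locus ever
  belongs to two final clusters.

The **SMLA** (synthetic multi-locus allele) of a cluster is the leading
eigenvector of the individual × individual covariance of column-centered
dosages: one coordinate per individual, sign-fixed to correlate positively
with mean dosage so results do not depend on the linear-algebra backend. On
tight clusters PC1 typically explains > 90% of the variance (the acceptance
script recomputes this, landing near 92% under the default simulation), so
the coordinate behaves like the dosage of one multi-locus allele.

Because the paper's exact cluster-extraction algorithm is described only in
inaccessible supplementary material, the decreasing-threshold "birth at
|E|~min~ edges, then freeze" rule above is this package's normative
definition; likewise the dosage-correlation LD estimator stands in for
ngsLD's composite-likelihood estimator (a documented dialect difference).

# Mixed-model association and the four regimes

Each SMLA is regressed on binary ecotype with lineage (WL / EL / ADMIXED) as
a covariate where it varies. With the relatedness matrix **A** (standardized
genomic relationship matrix from dosages, small diagonal ridge), variance
components are estimated once by REML under the null model on the
eigendecomposition of **A**, and each cluster is then tested by generalized
least squares on the whitened data — the EMMAX approximation. The binary
trait is treated as Gaussian, exactly as EMMAX does. An exact-GLS
implementation (full covariance inversion) is kept in the test suite as an
oracle; the two agree to 10⁻⁸.

Effect sizes are reported as plain correlations: `cor_unrl` (SMLA vs
ecotype, individuals assumed unrelated) and `cor_A` (correlation of
whitened, covariate-residualized SMLA and ecotype; we interpret the paper's
relatedness-adjusted effect size this way since the construction is not
spelled out there).

Inflation λ is the least-squares slope through the origin of observed on
expected −log₁₀(P) order statistics. The four regimes are:

| regime | model | multiplicity |
|--------|-------|--------------|
| `A_FDR`  | relatedness random effect | iterative GC + Benjamini–Hochberg |
| `A_perm` | relatedness random effect | max-statistic permutation |
| `GC_FDR` | unrelated | iterative GC + Benjamini–Hochberg |
| `perm`   | unrelated | max-statistic permutation |

Iterative GC estimates λ as the median of per-grid-cell slopes over clusters
not yet significant, divides all −log₁₀(P) by λ whenever λ > 1, applies the
BH step-up per cell, removes the significant set, and repeats until the set
stabilizes (cap 25 iterations). Permutation permutes ecotype within lineage
strata, records the maximum |statistic| over all clusters per permutation,
and reports (1 + #{max ≥ observed}) / (1 + n~perm~); with **A** the
statistics are computed on whitened data with variance components fixed at
their null values, which reduces the whole permutation pass to one matrix
product.

**Calibration and a known limitation.** On simulated structured null data
where genome-wide relatedness is the only confounder, the median post-fit λ
with **A** is 1.16 (without **A**: 1.73). When local genealogical
heterogeneity is added (the generator's block-noise component, below), some
inflation survives the relatedness correction — the same behaviour as the
nine-spined stickleback data in the source study — and the GC step exists
precisely to absorb it. Permutation controls the family-wise error rate
(measured 0.035 at α = 0.05 over 200 structured null data sets) when
ecotype is exchangeable across individuals under the null. When ecotype is
constant within demes and only a handful of demes are sampled, *no*
individual-level permutation scheme is valid — the trait is then maximally
confounded with structure rather than null. At the study's scale (dozens of
populations) this distinction softens; at desk scale it does not, and the
package's validation treats the deme-confounded configuration through the λ
calibration rather than through FWER.

# Outlier regions, consistency and regional parallelism

Unique loci of all significant clusters from every grid cell are pooled and
chained per chromosome by single linkage with a 500-kb gap threshold (a gap
of exactly 500 kb merges); chains with at least 10 unique loci become
regions. Note that parallel loci on different chromosomes routinely merge
into one genome-wide LD cluster — their SMLAs share the marine/freshwater
contrast — and region calling is what separates them again by position.

The consistency score C of a region is the proportion of the 144 cells in
which at least one significant cluster contributes at least one locus inside
the region's span ("found significant" is not defined at region level in the
source; this operationalization is ours). Regions with C < 0.05 are flagged
as too parameter-sensitive and dropped.

Regional parallelism contrasts all marine samples against the freshwater
samples of one geographic region at a time, recomputing the region SMLA from
the significant loci and reporting `cor_unrl` / `cor_A` per region. The
related parallelism score for a freshwater population pair counts the
proportion of all loci belonging to ecotype-associated clusters
(−log₁₀ P > 2) whose SMLA groups the pair; "grouping" uses a deterministic
one-dimensional 2-means split of the SMLA, the in-group being the side with
the higher freshwater fraction — the simplest operationalization of an
in-group, flagged here because the source does not define one.

# Diversity, differentiation and isolation by distance

Diversity statistics work on hard calls (argmax GL with a 0.9 confidence
mask) — a deliberate simplification of full genotype-likelihood SFS
machinery: H is the proportion of heterozygous calls per individual, π the
unbiased pairwise diversity Σ [n/(n−1)]·2p(1−p)/L, and Watterson's
θ~W~ = S/(a~n~L) with expectation 4N~e~μ. F~ST~ is the Weir–Cockerham
ratio-of-sums estimator from per-locus variance components a, b, c; negative
estimates are reported as computed. Its confidence interval resamples one
third of the markers and one third of the samples per replicate (without
replacement by default — the literal reading of "each resample consisted of
one-third"; a flag switches to with-replacement).

Isolation by distance regresses linearized F~ST~ = F~ST~/(1 − F~ST~) on
great-circle distance (haversine, radius 6371.0088 km; a user-supplied
distance matrix can replace it, e.g. for least-cost marine paths, which are
out of scope). The MLPE correlation structure — two pairs correlate ρ when
they share exactly one population — is fitted by profiled REML (ML
available behind a flag; which one the source used is unstated). The
implementation matches a dense grid search over ρ to 10⁻⁶ in the slope, and
recovers a planted slope of 10⁻⁴ within 5% with 96% CI coverage across 200
replicates. The same machinery fits the divergence-time versus parallelism
regression, divergence times being consumed as an input table.

# The synthetic-data generator

No sequencing data ships with the package; the generator produces the
statistical structure the analysis assumes and a truth table for validation.

* **Sites** are drawn from the neutral frequency spectrum (intensity θ/x for
  derived-allele frequency x, truncated at x~min~ = 0.05/n), which makes the
  expected number of sites segregating in a sample of n chromosomes equal to
  θLa~n~ — the coalescent expectation, so Watterson's θ recovers 4N~e~μ by
  construction rather than by tuning.
* **Structure** is applied as Balding–Nichols drift: a WL/EL lineage split
  (F = 1 − e^(−t/2Ne)), stepping-stone marine chains anchored in each
  lineage and mixed along an admixture cline, and freshwater demes founded
  from their nearest marine deme with founder-strength drift
  (F = 1/(1 + 8N~e~m)). We use this hierarchical frequency model rather
  than an explicit coalescent with recombination: it reproduces the moments
  the validation tests measure (θ, F~ST~, IBD) at a tiny fraction of the
  cost, and gives exact control over planted haplotypes.
* **Block noise**: sites within a linkage block (default 20 kb) share one
  per-deme drift deviate of variance `F_block` (default 0.04). This emulates
  the shared coalescent history of physically linked sites — the dominant
  source of window-to-window variance in real divergence scans. Without it,
  the d~XY~ ~ π regression fits the genome almost perfectly and the neutral
  Δd~XY~ interval collapses to nothing a real genome would show.
* **Planted haplotypes** are overlaid post hoc: each individual draws a
  carrier dosage at the block's target frequency (high in targeted
  freshwater demes, low-to-moderate elsewhere) and all block loci equal it —
  perfect co-inheritance, exact frequency control. Ancient mode adds
  carrier-exclusive derived variants (default 1/kb) across the span,
  reproducing the excess-divergence signature of old haplotypes; young mode
  adds none.

What the generator does *not* emulate: background LD beyond deme structure
(background sites are conditionally independent), forward-time selection,
read-level artifacts beyond Poisson depth and a constant error rate, or
RAD-versus-WGS coverage heterogeneity. Passing tests therefore demonstrate
that the statistical machinery behaves as designed under its assumptions,
not that the pipeline is robust to every property of real sequencing data.
A target-locus-count downsampling to equalize marker numbers between data
sets (mentioned but not specified in the source study) is not implemented.

# Study conditions used by the validation suite

Two canonical scenarios are frozen as package functions so tests and the
acceptance script share one definition:

* `scenario_parallel_regions()` — 4 marine + 4 freshwater demes, 12
  diploids each (96 individuals), ~5k background SNPs over four 5-Mb
  chromosomes; three shared and one region-private haplotype block, each 50
  loci over 200 kb at frequency 0.9 versus 0.05. The full 144-cell grid with
  300 permutations recovers a median of ≥ 3 of the 4 truth regions at
  C ≥ 0.25 with zero regions outside truth spans (10 seeds, ~4 s per seed).
* `scenario_ancient_young()` — a denser-marker genome (four 6-Mb
  chromosomes at θ = 5·10⁻⁴, ~45k SNPs) with one ancient block (0.9 vs
  0.05 — rare marine standing variation, hence high divergence per unit
  diversity) and one young block (0.9 vs 0.65 — common marine standing
  variation). Over 20 seeds the ancient block exceeds the 95% neutral
  Δd~XY~ interval in ≥ 18 and the young one stays inside in ≥ 16.

Numerical and procedural choices worth knowing: the Δd~XY~ regression line
is anchored on windows outside all candidate regions (at desk scale the few
planted windows are extreme-leverage points and would otherwise pull the
fit through themselves); neutral regions are size-matched runs of free
windows drawn without overlap; d~XY~ windows default to 20 kb; GL triples
with zero reads are uninformative (1/3, 1/3, 1/3); monomorphic dosages are
dropped from LD and GRM construction; and every stochastic function takes a
seed and is bit-reproducible given it.

# Worked example

```{r example, eval = FALSE}
sc <- scenario_parallel_regions(seed = 1)
ag <- run_association_grid(sc$gl, sc$sim$samples, n_perm = 300, seed = 101)
regions <- call_outlier_regions(ag)
regions[!regions$dropped, ]

fr <- freq_by_pop(hard_calls(sc$gl), sc$sim$samples$population)$freq
pairs <- expand.grid(pop1 = paste0("M", 1:4), pop2 = paste0("F", 1:4),
                     stringsAsFactors = FALSE)
delta_dxy(sc$sim$sites, fr, pairs, regions[1, ],
          c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6, chr4 = 5e6),
          exclude = regions, seed = 1)
```

# Known limitations

* The LD estimator and cluster-extraction rule are this package's normative
  definitions of loosely specified steps; numbers will differ from analyses
  built on ngsLD + the original LDna code.
* Permutation p-values are invalid when the trait is constant within a
  handful of demes (see above).
* Diversity statistics use hard calls, so they inherit a mild depth-dependent
  bias at very low coverage that GL-based SFS estimators would avoid.
* The generator's background sites are in linkage equilibrium given
  structure; analyses that depend on realistic background LD decay (e.g.
  window-size sensitivity) need external data.
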