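# phagehostnet

Analysis of binary phage–bacterium cross-infection matrices sampled across
sites and regions — the kind of dataset produced by spotting every isolated
phage on a lawn of every isolated bacterial strain and scoring lysis.  The
package was built around surveys of *Rhizobium* and their phages collected
from common-bean fields in two regions, but it applies to any complete binary
host-range matrix with per-entity site/region metadata.

It answers four questions about such a matrix:

1. **Network structure.** Is the bipartite infection network nested
   (generalist-to-specialist spectrum) or modular (preferentially interacting
   subsets)?  Metrics: connectance, NODF, nestedness temperature, and Barber
   bipartite modularity Qb maximized by an adaptive BRIM optimizer, each
   tested against an equiprobable Bernoulli null model.
2. **Local adaptation.** Do phages infect sympatric (same-site) hosts at a
   higher rate than allopatric hosts?  Statistics: per-entity sympatric and
   allopatric rates, the local-adaptation index S − A (mean sympatric minus
   mean allopatric rate), and a quasi-binomial GLM F-test on the
   two-observations-per-entity design.
3. **Typing.** Group strains into sequence types (exact marker identity),
   phage genomes into genomic types (single-linkage components of the
   pairwise ANI ≥ 80% ∧ coverage ≥ 60% graph), and either side of the matrix
   into phenotype groups (hierarchical clustering of interaction profiles at
   Bray–Curtis dissimilarity < 0.2).
4. **Community composition.** Compare per-sample type count tables across
   sites/regions with Jaccard and Bray–Curtis distances, PCoA, PERMANOVA,
   Mantel tests, PCNM spatial eigenvectors and ordination vector fitting.

A synthetic-data generator produces study-shaped datasets from a logistic
latent-trait model, so every stage is testable without field data, and a
parameter-recovery harness verifies that the local-adaptation analysis
recovers planted sympatric advantages.

## The core quantities

For a binary matrix `A` (rows = strains, columns = phages) with `m` ones,
row degrees `k_i` and column degrees `d_j`:

- connectance `C = m / (n_rows * n_cols)`;
- NODF: for every pair of rows (and columns) with strictly decreasing,
  non-zero fills, the shared ones divided by the smaller fill, averaged over
  all pairs (reported on [0, 1]);
- nestedness temperature `T ∈ [0, 100]`: squared normalized distances of
  unexpected presences/absences from the isocline of perfect nestedness in
  the packed matrix, scaled by the conventional constant; reported alongside
  the nestedness score `(100 − T)/100`;
- Barber modularity
  `Qb = (1/m) Σ_ij [A_ij − k_i d_j / m] δ(g_i, h_j)`,
  maximized over bipartite partitions by alternating optimal label
  assignments (BRIM) with an adaptive module-count schedule;
- local-adaptation index `S − A`, with significance from a logit-link
  quasi-binomial GLM: `F = Δdeviance / φ` on (1, 2n − 2) df, dispersion
  `φ` estimated by Pearson χ²/df;
- cell model of the generator:
  `P(A_ij = 1) = logistic(μ + a_j − b_i + δ·1[site match] + γ·1[block match])`
  with `a_j ~ N(0, σ_a²)`, `b_i ~ N(0, σ_b²)`.

## Worked example

```r
library(phagehostnet)

cfg <- sim_config()                     # 4 sites, 2 regions, 196 x 229, fill 0.43
sim <- simulate_matrix(cfg, seed = 2026)
sim$matrix
#> Infection matrix: 229 strains x 196 phages, fill = 0.431

net <- network_structure(sim$matrix, null_replicates = 0, seed = 1)
net
#> Connectance 0.431 | NODF 0.631 | NTC nestedness 0.650 | Qb 0.072 (4 modules)

pr <- entity_rates(sim$matrix, sim$metadata, "phage")
round(local_adaptation(pr)[, c("mean_S", "mean_A", "la_index")], 3)
#>   mean_S mean_A la_index
#> 1  0.547  0.392    0.156

quasibinomial_f_test(pr)
#> Quasi-binomial GLM: F(1, 390) = 50.47, p = 5.79e-12 (dispersion 0.190)
```

The matrix is strongly nested (NODF 0.63; `null_test()` places it far above
the equiprobable null) because phages vary in infectivity and strains in
resistance; modularity is weak because no block structure was planted
(`gamma = 0`).  Phages infect sympatric strains at 0.547 versus
0.392 for allopatric strains: the planted sympatric advantage (δ = 0.9 on
the logit scale, an implied rate difference of 0.16) is recovered, and the
GLM rejects the no-advantage null at F(1, 390) = 50.5.

`run_all(sim$matrix, sim$metadata, out_dir = "results/run")` executes every
stage and writes result CSVs, sorted-matrix exports, a JSON manifest and a
plain-text summary.

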