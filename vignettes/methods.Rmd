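---
title: "Methods: cross-infection network structure, local adaptation, and community composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-infection network structure, local adaptation, and community composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`phagehostnet`, the assumptions behind them, the numerical choices made
where conventions diverge, and what the synthetic-data generator does and
does not emulate.

## Data model

The central object is a complete binary infection matrix: rows are
bacterial strains, columns are phages, and cell (i, j) records whether
phage j lyses strain i in a spot assay.  The orientation is fixed
package-wide.  Completeness is an assumption, not a convenience: every
downstream statistic (connectance, NODF, rates, the GLM) treats absence of
lysis as an observed 0, so an untested pair is unrepresentable and a
missing cell is a hard error rather than an imputed value.

Replicated spot assays are collapsed by `consensus_call()`: full and
partial lysis both count as lytic (translucent spots are biologically
lysis at lower efficiency), and the call is the majority outcome — at
least 2 of 3 in the standard design.  An even split is indeterminate and
raises an error; silently imputing either outcome would bias the rate
statistics by an unknowable amount, and the correct remedy is re-assaying
the pair.  For more than three replicates the majority rule is the natural
extension of the 2-of-3 threshold; ties remain errors.

Site-to-region mapping comes only from the metadata table (site determines
region, checked at read time); identifiers are opaque strings and never
parsed, because encoding site codes in names is a brittleness we chose not
to inherit.

## Network structure

**Connectance** is the fraction of realized interactions.  All-zero rows
and columns are retained here and in modularity: a strain resisting every
phage is data, not a defect.

**NODF** follows the overlap-and-decreasing-fill definition: a pair of
rows contributes the shared ones divided by the smaller fill when fills
strictly decrease and the smaller is non-zero, and contributes zero on
ties; likewise for columns; the average over all pairs is reported on
[0, 1].  Because the decreasing-fill condition is evaluated on fills
rather than positions, the statistic is permutation invariant, and the
test suite pins it to a brute-force pair-enumeration oracle and to vegan's
fill-sorted implementation.

**Nestedness temperature** quantifies disorder relative to an isocline of
perfect nestedness in the packed matrix, on [0, 100] (0 = perfectly
nested).  Conventions differ among published calculators; ours is: pack
rows and columns by decreasing marginal totals; fit the isocline family
`y = (1 − (1 − x)^φ)^{1/φ}` on the unit square with φ solved numerically
so the presence region above the curve equals the observed fill; score
each unexpected cell (a 1 beyond the isocline or a 0 inside it) by its
squared distance from the isocline along the diagonal through the cell,
normalized by that diagonal's length; and scale the mean by the
conventional constant 100/0.04145.  Ties in packing are broken
lexicographically on the line's interaction pattern over the other axis's
packed order, iterated to a fixed point — this makes the packing (and
hence the temperature) invariant under permutation of the input, which an
original-index tie-break would not be.  All-zero lines carry no packing
information and are dropped with a warning before the computation (only
here; they are kept everywhere else).  Because published temperature
implementations differ in isocline and scaling details, temperatures from
different software should be compared only qualitatively; the derived
nestedness score (100 − T)/100 is the quantity we report alongside NODF.

**Barber modularity** `Qb = (1/m) Σ_ij [A_ij − k_i d_j/m] δ(g_i, h_j)` is
maximized by BRIM: given column labels, the optimal row labels are the
per-row argmax of `B C`, and vice versa, alternating until Qb stops
improving.  The adaptive schedule raises the candidate module count
geometrically (2, 4, 8, ... capped at the smaller dimension), runs 20
random restarts per count, and additionally refines the incumbent at each
larger count; the best partition over all runs is returned with compact
module labels numbered by decreasing size.  The restart count is a
default, not a convention: more restarts can only raise the reported
maximum.  Fixed seeds give identical partitions; argmax ties break to the
lowest module index.

**Null model.**  Significance uses the equiprobable null: same-shape
matrices with i.i.d. Bernoulli cells at the observed connectance,
1000 replicates by default (100 in smoke mode), with the add-one rule
`p = (#{null ≥ observed} + 1)/(replicates + 1)` so p is never zero, plus a
z-score against the null distribution.  Replicates that come out entirely
empty are redrawn, since the metrics are undefined on an empty network;
at realistic fills this is a measure-zero event.  Degree-preserving
(fixed-margin) nulls are deliberately out of scope.

## Typing rules

- **Sequence types**: exact string identity of concatenated marker genes
  after uppercasing.  No alignment, no distance threshold — identity is
  the definition.
- **Genomic types**: a graph on genomes with an edge when ANI ≥ 80% and
  alignment coverage of the smaller genome ≥ 60% (both inclusive);
  genomic types are its connected components.  Single linkage is the
  deliberate reading: pairwise ANI within a multi-member type may fall
  below the threshold as long as a qualifying chain connects the pair,
  which matches how ANI demarcation behaves in practice.  The package
  consumes a pairwise ANI/coverage table; computing ANI from sequence is
  out of scope.
- **Phenotype groups**: hierarchical clustering of interaction profiles
  (matrix rows for strains, columns for phages) on binary Bray–Curtis
  dissimilarity `1 − 2·shared/(fill_x + fill_y)`, tree cut at 0.2
  (">80% similarity").  UPGMA (average linkage) is the default because it
  tracks mean within-group dissimilarity, the quantity the threshold is
  phrased in; complete linkage is available via the `linkage` argument for
  a stricter reading.  All-zero profiles are excluded with a warning (their
  dissimilarity to anything is undefined); they are retained everywhere
  else.  Group labels are numbered by decreasing size, ties by first
  member, for determinism.

## Local adaptation

Per-entity rates are success fractions over partner sets: sympatric
partners share the entity's site, allopatric partners are all others.
Sympatry is defined at the site (bean-field) level; region-level
contrasts are obtained by restricting both entities and partners to one
region's sites (`entity_sites`/`partner_sites`), not by redefining
sympatry.  Phages enriched through a standard laboratory collection carry
the site of the soil filtrate used for their isolation and otherwise
participate identically; a `collection` filter reproduces
standard-vs-local subset analyses.

The local-adaptation index is `S − A`, the mean sympatric minus the mean
allopatric rate over the entities in scope.  From the phage perspective a
positive index indicates phage local adaptation; from the strain
perspective higher sympatric susceptibility indicates host maladaptation.

The significance test is a logit-link quasi-binomial GLM on two
observations per entity (its sympatric and its allopatric rate) with a
binary sympatry predictor, unweighted, giving residual df `2n − 2`
(390 for 196 phages).  Weighting each observation by its partner count is
available via a flag but is not the default: the unweighted design is
what reproduces the stated residual df, and partner counts are nearly
balanced in the four-site design anyway.  The F statistic is the deviance
drop over the Pearson-χ²/df dispersion.

Two calibration facts, both established by the test suite and worth
knowing before interpreting p-values:

- under the test's own null model (no latent heterogeneity, no sympatric
  effect) the type-I error is nominal (asserted within 0.05 ± 0.03 at
  α = 0.05 over 500 simulations);
- under latent entity heterogeneity (trait sds at their defaults) the
  unpaired design is **conservative** — the shared entity effect inflates
  the dispersion estimate, and the rejection rate at δ = 0 falls to or
  below the nominal level (asserted ≤ α; far below it in practice).  Significant results are therefore trustworthy,
  but the test's power is lower than a paired analysis would achieve; a
  mixed model with an entity random effect would be the more powerful
  alternative and is intentionally outside this package's scope, which
  mirrors the quasi-binomial convention of the field.

## Community composition

Per-sample type count tables (by default 3 soil samples per site) are
compared with Jaccard distances on presence/absence and Bray–Curtis
distances on relative abundances.  PCoA is the eigendecomposition of the
double-centred Gower matrix; coordinates are returned for positive
eigenvalues only, negative eigenvalues are reported.  PERMANOVA uses
McArdle–Anderson partitioning with sequential (Type I) sums of squares in
caller-given term order and raw-data permutation (999 by default), via
`vegan::adonis2(by = "terms")`; the one-way pseudo-F on Euclidean
univariate distances is pinned to the classical ANOVA F in the tests.
Mantel tests (999 permutations) and vector fitting on ordinations
(9999 permutations) delegate to vegan, wrapped so a fixed seed gives
bit-reproducible p-values.  PCNM spatial eigenvectors come from the
truncated geographic distance matrix with the standard
longest-MST-edge threshold.  Note that fitting a variable on *all* axes
of a full-rank ordination is saturated by construction; restrict axes
with `choices` (the first axis is the usual proxy for the between-region
contrast).

## The synthetic-data generator

Cells are independent Bernoulli draws from
`logistic(μ + a_j − b_i + δ·1[site_i = site_j] + γ·1[block match])`, with
phage infectivity `a_j ~ N(0, σ_a²)` and strain resistance
`b_i ~ N(0, σ_b²)`.  This model was chosen because its three structural
ingredients map one-to-one onto the three phenomena the pipeline
measures: trait heterogeneity generates nestedness, δ generates local
adaptation, γ generates modularity — with interpretable logit-scale
parameters.

Defaults emulate the motivating survey design: 4 sites in 2 regions,
49 phages per site (196), strains 58/57/57/57 (229), 3 soil samples per
site for community tables, and `target_fill = 0.43`.  The intercept μ is
calibrated by numeric integration so the expected fill equals the target.
The default sympatric advantage δ = 0.9 was chosen by solving the model
so its implied allopatric/sympatric marginal rates are 0.39/0.55 at fill
0.43 — the three observed rate values are mutually consistent
(0.75·0.39 + 0.25·0.55 = 0.43), so one δ reproduces all of them.  Trait
sds default to σ_a = 1.2 and σ_b = 0.8: phage host range varies more than
strain susceptibility in such surveys (infection rates spanning ~2–93%
versus ~10–74%).  `implied_la()` integrates the model exactly, so the
estimated index can be checked against its population target; a per-site
δ vector reproduces asymmetric adaptation (one community adapted, others
not).  Modular structure is off by default (`n_blocks = 1, γ = 0`)
because block membership is not an observable of the emulated design;
planting it is a one-argument change.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data:

- profile redundancy: real strains share resistance mechanisms, so
  interaction profiles cluster into a few dozen phenotype groups; under
  the continuous latent-trait model nearly every profile is unique and
  phenotype groups are mostly singletons.  Phenotype-group *counts* on
  synthetic data are not comparable to field values; the clustering rule
  itself is verified on planted-block constructions instead;
- phylogenetic correlation among strains and among phages (traits are
  i.i.d.);
- coevolutionary dynamics: generation is cross-sectional, no arms race or
  fluctuating selection;
- the dependence structure of real community tables (types are drawn
  multinomially from site frequency vectors; no zero inflation, no
  sequencing noise).

ANI tables are generated with planted clusters whose within-cluster draws
lie inside the qualifying region (ANI 85.8–99.7%, coverage 64.1–100%,
the ranges typical of conspecific phage genomes) and between-cluster
draws below the ANI threshold, so recovery must be exact.

## Problem sizes and tolerances

The test suite runs the full-size (229 × 196) design only where a single
evaluation is cheap (metrics, rates, GLM); optimization- and
replication-heavy checks use reduced designs — 6 × 6 to 12 × 10 matrices
for oracle comparisons and null-model calibration (200 matrices,
99 replicates each), 40 × 48 matrices for the recovery harness (100
replicates for unbiasedness, 500 for type-I calibration, 50 per grid
point for monotonicity).  These sizes were chosen so the whole suite
completes in about a minute and a half while keeping Monte-Carlo error
well inside the asserted tolerances.  Oracle comparisons are exact to
1e-10 or better; stochastic calibration checks use 3-standard-error
bands.  The acceptance script's null tests run in 100-replicate smoke
mode; the package default remains 1000.

## Known limitations

- Only the equiprobable null model is provided; fixed-degree and swap
  nulls are out of scope, and equiprobable nulls are liberal for
  nestedness on matrices with strong degree heterogeneity.
- Temperature values are convention-dependent across software; compare
  trends, not digits.
- The GLM's conservatism under entity heterogeneity (above) means its
  p-values understate evidence when traits vary strongly.
- `adaptive_brim` is a stochastic maximizer; the reported Qb is a lower
  bound on the true maximum, tightening with `restarts`.
- Jaccard distances are computed on presence/absence and Bray–Curtis on
  relative abundances; raw-count Bray–Curtis is intentionally not offered
  for community tables, since sample depths are arbitrary.
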