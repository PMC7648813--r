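---
title: "Methods: SNP-based species delimitation, hybrid detection and morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based species delimitation, hybrid detection and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, assumptions, parameter
choices and numerical conventions behind every analysis stage in
`snpdelim`, and the scope of the synthetic-data generator used to validate
them. The package implements an integrated workflow for splitting a set of
sampled populations into candidate species (diagnosable operational
taxonomic units, OTUs) from reduced-representation SNP genotypes, with
supporting hybrid-class assignment, kinship screening, genetic-diversity
comparison, ordination and morphometric analysis.

## Data model

A `genotype_matrix` stores diploid SNP genotypes as alternate-allele
dosages: 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
alternate), `NA` (missing call). Rows are individuals, columns are loci.
Per-locus metadata follow the reduced-representation (DArTseq-style)
deliverable: sequence-tag identity (`clone_id`), SNP position within the
tag, repeatability (`rep_avg`, the fraction of technical-replicate pairs
scored identically), call rate and mean read depth. Individuals carry a
population (sampling-site) label.

Assumptions: loci are biallelic; individuals are diploid; populations are
the sampling unit for all frequency-based statistics. No use is made of
linkage phase, genomic position beyond the tag, or genotype likelihoods —
hard calls only.

## Quality filtering

`run_filter_pipeline()` applies six stages in a fixed order; the order
matters because later thresholds are recomputed on the surviving data:

1. **One SNP per tag** — among loci sharing a `clone_id`, keep the one with
   the highest repeatability (ties: lowest SNP position, then input order).
   Removes non-independent calls from the same sequence fragment.
2. **Read depth** — keep loci with mean depth in [5, 100], inclusive. Low
   depth under-calls heterozygotes; extreme depth suggests repetitive
   sequence.
3. **Individual call rate** — remove individuals with fewer than 50% of
   loci called.
4. **Monomorphic loci** — remove loci with no evidence of both alleles
   among the retained individuals.
5. **Repeatability** — remove loci with `rep_avg` below 0.99.
6. **Locus call rate** — remove loci with call rate below 0.95, recomputed
   on the retained individuals (a locus missing mostly in removed
   individuals is thereby rescued).

All thresholds are strict in the documented direction and boundary values
are retained where the rule is inclusive. Each stage is idempotent, and the
staged report reconciles exactly: planted violations (via
`inject_artifacts()`) are removed by their intended stage and no other.

## Genetic distance and ordination

`genetic_distance()` is the Euclidean distance between genotype rows scaled
to allele dosage (`genotypes / 2`); missing values are handled
pairwise-complete with proportional rescaling (the `stats::dist`
convention), equivalent to scaling each pair's distance by
`sqrt(L / L_shared)`. `pcoa()` is classical multidimensional scaling
(`stats::cmdscale`): double-centring of −D²/2 and eigendecomposition. On
complete data this reproduces principal component analysis of the dosage
matrix exactly (a tested property). Numerical conventions: negative
eigenvalues (possible for non-Euclidean inputs) are reported but excluded
from the variance denominator, so axis percentages are shares of the
positive eigenvalue mass; axis signs are fixed deterministically by making
the largest-magnitude coordinate of each axis positive. `scree()` tabulates
the eigenvalue spectrum.

## Fixed differences and OTU amalgamation

The delimitation criterion is diagnosability: two units are candidate
species when one or more loci are fixed for different alleles in the two
units. `allele_frequencies()` computes per-population alternate-allele
frequencies over called individuals; `count_fixed_differences()` counts
loci, among those callable in both units, with frequencies on strictly
opposite boundaries (tolerance 0 by default — fixation means fixation; a
`tolerance` argument relaxes this symmetrically).

Small samples can show spurious fixed differences. `false_positive_rate()`
simulates the null: allele frequencies are pooled per locus across the two
samples, and each replicate redraws both samples' genotypes binomially from
the pooled frequency at the observed per-locus sample sizes (respecting
missingness), counting spuriously fixed loci. Implementation note: the
per-locus indicator of an apparent fixed difference under this null is
Bernoulli with probability
`P(pA ≤ tol) P(pB ≥ 1−tol) + P(pA ≥ 1−tol) P(pB ≤ tol)` under binomial
sampling of the allele copies, so replicates draw these indicators directly
(via `pbinom`) rather than every genotype — distributionally identical and
O(loci × replicates). The smallest-sample two-unit case with one diploid
per sample and pooled frequency ½ gives the closed form 2·(¼)·(¼) = 0.125
expected false positives per locus, which the simulation must match.

`amalgamate_otus()` merges populations progressively: first all pairs with
zero observed fixed differences (smallest pair first, recomputing after
every merge, since pooling can dissolve apparent fixation); then any pair
whose count is statistically indistinguishable from the sampling-error
expectation (false-positive test p > α = 0.05), smallest observed count
first. The procedure stops when every remaining pair is diagnosably
distinct. Tie-breaks are lexicographic, making the procedure deterministic
given the random seed of the false-positive simulations. Putative hybrids
should be excluded (`exclude =`) since an F1 dissolves fixation between its
parental units by construction.

`count_private_alleles()` counts, per direction, alleles present in one
unit and absent in the other; each fixed difference contributes one private
allele to each direction, so the private-allele count is bounded below by
the fixed-difference count (a tested invariant).

## Expected heterozygosity

`expected_heterozygosity()` is the mean over callable loci of 2p(1−p)
(Hardy–Weinberg expected heterozygosity), optionally with the small-sample
factor 2n/(2n−1). It is a relative diversity measure: no correction is
attempted for the ascertainment of the SNP panel.
`heterozygosity_randomization_test()` tests a difference between two
populations by re-randomization: individuals (not alleles — the individual
is the sampling unit, preserving within-individual structure) are
repeatedly reassigned to two groups of the original sizes and |ΔHe|
recomputed. The p-value uses the add-one rule (1 + #{null ≥ observed}) /
(reps + 1): never exactly zero, and exactly calibrated under the null
(tested at ≈5% type-I error). Default 10,000 replicates.

## Hybrid-class assignment

`classify_hybrids()` assigns each individual to one of six
genotype-frequency classes without pre-specifying which individuals are
parental: P0, P1 (pure members of two parental gene pools), F1, F2, and the
two first-generation backcrosses F1×P0, F1×P1. Each class is a triple of
gene-pair weights (w00, w01, w11) — the probabilities that a random locus
carries both gene copies from pool 0, one from each, or both from pool 1 —
and its genotype distribution at a locus is the corresponding mixture of
Hardy–Weinberg products of the two pools' allele frequencies.

Inference is a Gibbs sampler over: individual class labels (categorical,
given mixing proportions and per-locus likelihoods), per-locus pool allele
frequencies (Beta, via latent gene-pair-source augmentation that allocates
each individual's two gene copies to pools conditional on its class), and
mixing proportions (Dirichlet). Priors are Jeffreys throughout:
Beta(½, ½) per locus per pool and Dirichlet(½, …, ½) over the six classes.
Missing genotypes contribute likelihood 1. Posterior class probabilities
are label frequencies over post-burn-in sweeps; defaults are 10,000
burn-in + 10,000 retained sweeps. The model assumes the sample is drawn
from (at most) two parental gene pools plus their first- and
second-generation combinations; loci are treated as unlinked.

Pool labels are unidentifiable a priori (label switching). They are
anchored deterministically after sampling: pool 0 is the first individual's
maximum-a-posteriori parental pool, swapping P0↔P1 and F1×P0↔F1×P1 columns
when needed. The sampler runs on all supplied loci (monomorphic loci are
uninformative but harmless; fully monomorphic input is an error).
Reproducibility follows the R convention: call `set.seed()` before the
sampler; the compiled core uses R's RNG stream.

## Kinship screening (opposing homozygotes)

A parent and its offspring can never be opposing homozygotes (0 vs 2) at
any locus, barring genotyping error. `pairwise_inconsistency_null()` counts
opposing homozygotes for every pair of individuals and normalizes by the
pairwise-callable locus count. `detect_parent_offspring()` flags pairs
whose rate falls below `median − k·MAD` of the all-pairs distribution
(k = 5 by default; MAD with the 1.4826 normal-consistency constant). The
all-pairs distribution is dominated by unrelated pairs, making it a robust
null; a zero MAD (degenerate distribution) yields a warning and no flags.
This is a screening rule, not a likelihood-based relatedness estimator:
full siblings and other close kin can also be depressed, and the threshold
k trades sensitivity against false flags.

## Morphometrics

`morph_table()` validates an individuals × traits table (eight traits:
body mass, head length, head width, body length, tail length, knee-to-heel,
ear length, ear width), maps sampling sites to regions, and keeps adults.
Analyses assume approximately normal within-group trait distributions and a
shared within-group variance for the pooled tests.

- `sex_effect_screen()` fits `trait ~ region * sex` per trait and removes
  the least significant term by backward elimination (interaction before
  main effects, respecting marginality) until all retained terms have
  p ≤ 0.05 — a screen for whether sexes must be analysed separately.
- `tukey_kramer()` compares all region pairs per trait with the
  Tukey–Kramer studentized-range test: pooled within-group variance across
  all groups, SE = √(s²(1/nᵢ + 1/nⱼ)) for unequal sizes, p-values from
  `ptukey`. It agrees with `TukeyHSD` on balanced and unbalanced data (a
  tested equivalence). Differences are signed first-listed minus
  second-listed in canonical region order (Northern, Central, Southern).
- `cva()` is canonical variate analysis via linear discriminant analysis
  (`MASS::lda`): axes maximize between-group relative to within-group
  variance; axis percentages are shares of the discriminant eigenvalues;
  a singular within-group scatter (e.g. a constant trait) is an error, not
  a silent pseudo-inverse.
- `pca_morph()` is principal component analysis on the trait correlation
  matrix (traits have heterogeneous units, so correlation, not covariance),
  complete cases only.

Axis signs in CVA and PCA are fixed by the same largest-magnitude-positive
convention as the PCoA.

## The synthetic-data generator

All validation rests on generators with planted, recoverable truth; the
package ships no empirical data and its tests assert nothing about any real
organism.

`simulate_populations(sim_config())` draws, per group, background per-locus
alternate-allele frequencies from a symmetric Beta(a, a) with
a = He/(1 − 2He), whose expected heterozygosity E[2p(1−p)] = a/(2a+1)
equals the group's target. A configured fraction of loci is planted as
fixed inter-group differences; with three groups, each planted locus fixes
one "odd" group for one allele and the others for the alternate, and the
per-pair fractions d(A,B) = x_A + x_B are decomposed exactly from the
pairwise targets (infeasible triangles are an error). Sites within a group
get Balding–Nichols drift noise (Beta with F = 0.002) around the group
frequency at background loci. Genotypes are Hardy–Weinberg binomial draws.
Hybrid individuals are built by Mendelian gamete draws from their class's
gene-pair weights, optionally linked to a named parent (the planted
backcross is simultaneously an F1×P0 and a parent–offspring pair).
Genotyping error replaces a call with one of the other two genotypes
(probability 0.002 per call); missingness is 2% per call. Locus metadata
are drawn so a clean simulation passes the default filters.

Default configuration (the reference study design of the test suite): five
sites in three groups — Northern (18 + 15 individuals, He 0.04), Central
(18, He 0.10), Southern (9 + 6, He 0.11); planted fixed-difference
fractions Northern–Central 0.25, Northern–Southern 0.35, Central–Southern
0.15; 1,000 loci; one F1 (Northern × Central) plus its backcross offspring
with a Northern parent. The 1,000-locus panel is a deliberately scaled-down
stand-in for a full reduced-representation panel (tens of thousands of
loci): it keeps the acceptance runs fast while leaving all planted signals
comfortably recoverable, and all rates are per-locus so results scale.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), coalescent genealogy or mutation processes (frequencies come
from a parametric law, not a demographic history), allele-dropout-style
asymmetric error, depth-dependent call quality, or ascertainment bias of
SNP discovery. Claims verified against it are claims about the estimators
under its sampling assumptions, not about any empirical dataset.

`simulate_morphology()` draws independent normal traits per region at
reference means/SDs (with an optional additive sex effect);
`exact = TRUE` rescales each region's draws so sample moments equal the
parameters exactly, giving a deterministic reference dataset for the
morphometric arithmetic. `simulate_parent_offspring()` and
`inject_artifacts()` plant kinship and filter-stage truth respectively.

## Pipeline and reproducibility

`run_full_analysis()` orchestrates the stages (filter, PCoA, hybrid
classification, delimitation, diversity, kinship, morphometrics) from a
YAML or list configuration over either simulated or file-based input
(DArT-style CSV + population map, or VCF). Individuals whose non-parental
posterior mass exceeds 0.5 are excluded from delimitation as putative
hybrids. A mandatory master seed is forked into per-stage seeds; outputs
are plain CSVs plus a JSON manifest with MD5 checksums, and identical
configuration + seed reproduces byte-identical outputs.

## Limitations and scope notes

- Delimitation by fixed differences is a diagnosability criterion; it does
  not model gene flow, divergence time, or population structure within
  units, and its resolution is bounded by sample sizes (small samples merge
  conservatively via the false-positive test).
- The hybrid model covers two parental pools and two generations; later
  backcross generations are absorbed into the nearest class.
- The kinship screen detects strong pedigree signal only; it is not a
  relatedness coefficient estimator.
- The heterozygosity comparison is relative to the shared SNP panel.
- The test suite computes every reported quantity from generated data with
  planted truth or from closed-form arithmetic; no test asserts an
  empirical result that the package does not itself compute.
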