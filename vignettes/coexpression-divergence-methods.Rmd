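---
title: "Methods: coexpression network divergence across developmental stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression network divergence across developmental stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coexdiv` asks how gene coexpression relates to a binary ecological contrast —
benthic (deep-bodied, bottom-dwelling) versus limnetic (elongated, open-water)
ecomorphs — at two developmental stages, and how much of the coexpression
architecture itself is shared between those stages. This vignette explains the
models and procedures, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Preprocessing

Raw inputs are a transcripts × samples matrix of read counts and per-sample
metadata (stage, morph, species, lake).

**Count filter.** A transcript is retained only if its total count across all
samples is at least 100 *and* its summed count within every stage is at least
50. The two clauses are combined conjunctively for retention — the stricter
and more common reading — and "within a stage" means the sum over that stage's
samples. Both thresholds are configurable (`total_min`, `per_stage_min`).

**Variance-stabilizing transform.** Size factors are computed by the
median-of-ratios method over genes with all-positive counts, and abundances
are `log2(count / size_factor + 1)`. This is a deliberate, documented
approximation with the same intent as dispersion-trend VSTs — abundances
comparable across samples and stages, variance roughly free of the mean — and
it is monotone within a sample and finite everywhere. Any externally computed
transformed matrix can be used instead: every downstream function accepts a
samples × genes `ExpressionMatrix` directly. This is also the one place the
orientation flips from the on-disk genes × samples convention to the
samples × genes convention used by all network code.

**Sample outlier removal.** Samples are screened iteratively by standardized
connectivity: the sample–sample network with signed-square adjacency
`A_ij = ((1 + r_ij)/2)^2` (Pearson over genes) gives connectivities
`k_i = Σ_{j≠i} A_ij`, standardized to `Z.k`; samples with `Z.k < −2` are
removed and the computation repeated until none fall below the threshold.
When `sd(k) = 0` (e.g. identical samples) all `Z.k` are defined as 0 and
nothing is removed. The procedure terminates in at most `n` iterations and
its output is a fixed point of itself.

## Signed network and modules

**Biweight midcorrelation.** All gene–gene similarity uses the biweight
midcorrelation: observations are weighted by Tukey biweights around the median
with scale `9·MAD`, and the weighted, median-centered vectors are correlated.
A cap (`max_p_outliers = 0.1`) limits the fraction of either tail that can
receive zero weight, implemented by rescaling each side so the bounding
quantile maps onto ±1. A vector with zero MAD falls back to Pearson centering,
flagged in the output. For correlations against the binary morph trait the
robust weighting is disabled on the trait side (robust estimation is
inappropriate for a 0/1 predictor); the hybrid reduces to a point-biserial
style correlation with biweights on the expression margin.

**Soft threshold.** The signed adjacency is `a_ij = ((1 + c_ij)/2)^β`. Powers
1–30 are scanned and the smallest power whose scale-free fit reaches signed
R² ≥ 0.9 is chosen; when none qualifies, β = 20 is used with a warning. The
fit discretizes connectivity into 10 equal-width bins and regresses the log10
bin frequency on the bins' mean log10 connectivity; the signed index is
`−sign(slope)·R²`, positive only for the decreasing connectivity distributions
scale-free topology requires. A power is eligible only while the mean
connectivity stays at least `min_mean_k = 1`: at very high powers the network
is essentially empty and the surviving handful of edges produces spuriously
power-law-looking connectivity even on pure noise, so fits there carry no
evidence of scale-free structure.

**Topological overlap.** `t_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) /
(min(k_i, k_j) + 1 − a_ij)`, `t_ii = 1`; clustering uses the dissimilarity
`1 − t`.

**Module detection.** Genes are clustered by average linkage on TOM
dissimilarity. Instead of a fixed cut height, the dendrogram is walked from the
root: a node of at least `min_module_size = 30` genes is accepted as a module
when it is *coherent*, meaning its leading eigenvalue fraction exceeds
`coherence_factor = 1.25` times the random-matrix baseline
`(1 + sqrt(q/n))²/q` while its second eigenvalue fraction stays below that
bound. A mixture of two distinct modules fails the second condition and is
split further down; unstructured gene sets fail the first and dissolve. This
makes detection cut-height free and deterministic (no hidden randomness).
Members whose signed module membership falls below `trim_frac = 0.5` times the
module's median kME are released; unassigned genes are attached to the module
whose eigengene they correlate with above `pam_kme = 0.5`; modules whose
eigengene correlation dissimilarity is below `merge_cut_height = 0.25` are
merged iteratively; and modules whose final membership falls below the minimum
size are dissolved. Remaining genes are labeled `"grey"`. Labels are color
names assigned by decreasing size from the conventional palette (largest =
"turquoise"). The exact tie-breaking of the reference dynamic tree cut
implementation is *not* reproduced; the package's tests validate detection by
planted-truth recovery (adjusted Rand index), not label-for-label parity.

**Eigengenes.** A module's eigengene is the first principal component of its
standardized samples × genes submatrix, scaled to unit variance and oriented to
correlate positively with the module's average standardized expression.
The per-module explained-variance fraction `λ1/Σλ` and every gene's module
membership (kME, biweight midcorrelation with each eigengene) are returned.
Constant genes are dropped from the PCA with a warning.

## Module–trait association and candidates

Morph is coded benthic = 0, limnetic = 1, so positive correlations mean
limnetic overexpression. Each eigengene is correlated with the trait using the
hybrid correlation above; two-sided p-values use the Student-t approximation
with n − 2 degrees of freedom, and the Benjamini–Hochberg procedure is applied
across modules, selecting modules at q ≤ 0.05. Within selected modules,
candidate genes are those with *both* |kME| > 0.7 and |GS| > 0.7 (strict
inequalities; GS is the gene's hybrid correlation with the trait). Enrichment
of externally supplied differential-expression calls in a selected module is
tested with a two-sided Fisher exact test contrasting the module against genes
outside any selected module; the sample odds ratio is reported.

## Two permutation tests for selected modules

**First-eigenvalue test** (in the spirit of parallel analysis): the observed
statistic is the fraction of variance on the leading eigenvalue of the
module's correlation matrix (Pearson and biweight variants, 1,000 permutations
by default). The null permutes each gene's values independently across
samples, destroying inter-gene association while preserving marginals. One
published description of this scheme speaks of permuting rows; permuting whole
rows jointly cannot change any correlation matrix, so the implementation
follows the stated *intent* (independent per-column permutation, as in
parallel analysis), and a `permute_rows` switch demonstrates the invariance.

**Escoufier RV test**: RV between the module's expression matrix and the trait
as a single centered column, `RV = trace(Sxy·Syx)/sqrt(trace(Sxx²)·trace(Syy²))`,
with the null obtained by permuting morph labels (100 permutations by
default).

Both tests report `p = #(null ≥ observed)/n_perm` — the observed value is
*not* added to numerator or denominator, so p = 0 is attainable; a `plus_one`
option gives the (b+1)/(m+1) estimator. On null data both tests hold their
nominal type-I error (checked against exact binomial bands in the test suite).

## Cross-stage analyses

**Module preservation.** Reference modules are scored in a test dataset on the
shared gene universe. Density statistics (computed in the test data): mean
within-module adjacency, mean within-module correlation, eigengene
explained-variance fraction. Connectivity statistics (reference–test
agreement): correlations of intramodular connectivity, of kME (absolute, since
eigengene sign is arbitrary per dataset), and of the within-module gene–gene
correlation vectors. Each statistic is standardized against permutations of
module labels at fixed module size; `Z_density` and `Z_connectivity` are the
medians of their triplets and `Z_summary` their mean, with the usual evidence
classes: < 2 none, 2–10 weak-to-moderate, > 10 strong. A statistic whose
permutation null has zero spread (e.g. any reference–test correlation when the
test data are an exact copy of the reference) is uninformative and excluded.
The exact statistic set behind the reference implementation of `Z_summary` is
not printed anywhere authoritative; the set above is this package's
definition, and its tests are threshold-behavioral (self-copies score strong,
scrambled modules score none), not numeric parity with other software.

**Module overlap.** A cross-tabulation of two stages' module assignments over
the common gene universe, with a two-sided Fisher exact test per (non-grey)
cell and BH adjustment across cells.

**Consensus modules.** Per-dataset TOMs (same parameters as within stages) are
calibrated by power-transforming each so its 95th percentile matches the first
dataset's — a power map preserves [0, 1], unlike linear scaling — and combined
by elementwise minimum, so only coexpression supported in every dataset
survives. Detection then proceeds as above with coherence required in every
dataset, attachment requiring the kME threshold in every dataset, and merging
driven by the maximum (worst-case) eigengene dissimilarity across datasets.
Eigengenes of consensus modules are computed separately per dataset, so trait
association can agree or disagree between stages.

## Global trajectories

Starting from the *original* counts (before filtering and outlier removal),
pooled across stages under a common transform: Euclidean distances between the
four stage × morph group centroids (unweighted means; the choice is
configurable) quantify whether benthic–limnetic divergence differs between
stages. For ordination, Euclidean distances among individuals are mapped by
principal coordinates analysis (Gower double-centering; scores equal centered
PCA scores for Euclidean input, and all eigenvalues are reported), and a
between-group PCA is computed in that space: PCA of the group-centroid matrix
with all individuals projected onto the centroid axes. Axis variance is
reported as a fraction of the total among-individual variance in
principal-coordinate space (the denominator choice is recorded here as this
package's reading of "% of original variation"); at most g − 1 axes are
nonzero for g groups, and axis signs are fixed by making the
largest-magnitude loading positive.

## Genomic overlap of modules and QTL

Transcript positions and QTL intervals are 0-based half-open intervals on
named linkage groups with known lengths. The overlap count is the number of
query intervals sharing ≥ 1 bp with any subject interval. Significance comes
from a linkage-group-restricted randomization: each permutation re-places
every query interval uniformly at random within its own linkage group, length
preserved, so the null respects genome size and linkage-group structure
(1,000 permutations by default; one-sided for enrichment). A battery runs
every (gene set × QTL set) pair — plus the union of QTL sets — and adjusts
p-values by BH. The randomization substream is keyed to the query's content,
so identical gene sets receive identical placements wherever they appear in
the battery.

## The synthetic-data generator

`simulate_two_stage_counts()` emulates the study design the package targets:
two stages with 6 benthic and 6 limnetic samples each (a deliberately small-n
regime), six 50-gene modules plus 100 background genes by default, gene
loadings uniform on (0.6, 0.9), and negative-binomial counts
(Var = μ + μ²·d, d = 0.1 — the standard RNA-seq noise assumption) around
library sizes of 0.5–1 million reads. Each module has one latent
standard-normal score per sample, shifted by Δ for limnetic samples (default
Δ = 2 for two modules, 0 elsewhere; per-stage Δ vectors are supported);
gene g's log-scale mean is `b_g + a_g·s + ε` with unit total latent variance.
Stage 2 keeps the first `preserved_fraction` (default one half) of the modules
and reshuffles the remaining modules' genes onto new, independent latent
scores. `simulate_genome()` places transcripts uniformly on equal-length
linkage groups, with optional planted enrichment of one module's transcripts
inside QTL intervals.

What the generator does *not* emulate: species- or lake-level phylogenetic
structure, pooling of individuals within libraries, gene-length or GC biases,
dispersion trends across the mean, and compositional artifacts beyond what the
relative-abundance scaling induces. Passing tests therefore demonstrate that
the machinery recovers the structures it is designed to see under an honest
noise model — not that any particular biological dataset will show them.

One consequence of the relative-abundance scaling is worth naming: because a
sample's counts are normalized by the sample's total expected expression,
background genes share a weak common factor and acquire mild correlations
(~0.1) with each other and with modules. This is a real phenomenon in
sequencing data, and it is the main reason module recovery on the generator is
good rather than perfect.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to exercise every
code path while keeping a full run comfortable on a single CPU: matrices of a
few hundred genes and 12–24 samples, 100–1,000 permutations per test
(module preservation is validated at 200 permutations in tests and 500 in the
acceptance script; the pipeline default remains 1,000), and 10–100 replicate
simulations for calibration and power properties. Further numerical
conventions: correlations are clamped to [−1, 1] before powering; eigengene
and bgPCA axis signs follow the conventions above; permutation p-values have
resolution 1/n_perm; all randomized stages draw their seeds deterministically
from one global seed, so every result is bit-reproducible; and file writes go
through a write-then-rename step so interrupted runs never leave half-written
artifacts.

## Known limitations

- The VST approximation ignores dispersion trends; for data with strong
  mean-dispersion structure, supply an externally transformed matrix.
- Module detection validates candidate nodes with an eigenvalue criterion
  calibrated for `n` in the tens; for very large sample sizes the
  random-matrix baseline becomes loose (conservative).
- `Z_summary` here is this package's definition of a density/connectivity
  composite, suitable for threshold-based evidence classes; its numeric values
  are not interchangeable with other implementations'.
- The consensus construction supports any number of datasets, but per-dataset
  trait association is reported for the two-stage design only.
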