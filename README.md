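# coexdiv

Signed weighted gene-coexpression analysis of benthic–limnetic ecomorph
divergence across two developmental stages.

Benthic (deep-bodied, bottom-dwelling) and limnetic (elongated, open-water)
ecomorphs are a classic axis of adaptive divergence in fishes. Given bulk
RNA-seq read counts from both ecomorphs sampled at two developmental stages,
`coexdiv` answers three questions:

1. **Which coexpression modules track the ecomorph contrast at each stage?**
   Signed weighted networks are built from the biweight midcorrelation
   (`bicor`), with signed adjacency `a_ij = ((1 + c_ij)/2)^β` and topological
   overlap; modules come from average-linkage clustering with an
   eigenvalue-based coherence cut (minimum module size 30, eigengene merge
   height 0.25). Each module's eigengene (first principal component of its
   standardized expression) is correlated with the trait coding
   benthic = 0 / limnetic = 1, with BH FDR control at 0.05 across modules.
   Selected modules are validated by two permutation tests — the variance
   explained by the first eigenvalue against per-gene permutations (in the
   spirit of parallel analysis, 1,000 permutations), and the Escoufier RV
   coefficient `RV = tr(S_xy S_yx)/√(tr(S_xx²) tr(S_yy²))` against trait-label
   permutations (100 permutations) — and candidate genes are those with both
   |kME| > 0.7 and |GS| > 0.7.
2. **Is the module architecture itself preserved between stages?** Module
   preservation is scored by `Z_summary` (mean of the median density-statistic
   Z and median connectivity-statistic Z against module-label permutations;
   < 2 no evidence, > 10 strong evidence), modules are cross-tabulated between
   stages with Fisher exact tests, and consensus modules are built from the
   elementwise minimum of calibrated per-stage TOMs.
3. **Do trait-associated modules sit in known QTL regions, and do global
   expression profiles diverge more at one stage?** Module/QTL overlap is
   tested by linkage-group-restricted randomization of transcript positions,
   and global profiles are explored by group-centroid Euclidean distances and
   between-group PCA on principal coordinates.

A synthetic-data generator with planted modules, trait effects, partial
cross-stage preservation, and a toy genome with QTL intervals makes the whole
pipeline testable end to end without any external data; every statistical
claim in the test suite is checked against planted truth or an independent
brute-force oracle.

## Worked example

```r
library(coexdiv)

sim  <- simulate_two_stage_counts(sim_config(seed = 1))
expr <- vst_counts(sim$counts1)                      # samples x genes
net  <- detect_modules(expr, network_config(beta = 6))
net$modules
#> module_set: 400 genes, 3 modules (+145 grey)
#> turquoise      grey      blue     brown
#>       150       145        53        52

assoc <- eigengene_trait_association(
  net$eigengenes, trait_vector(sim$meta1$morph), expr = expr
)
assoc$table
#>      module      r       p       q selected
#> 1 turquoise -0.489 0.10699 0.10699    FALSE
#> 2      blue  0.776 0.00301 0.00902     TRUE
#> 3     brown  0.537 0.07170 0.10699    FALSE

sub <- expr[, net$modules$labels == "blue"]
eigenvalue_permutation_test(sub, n_perm = 1000, cor_type = "bicor", seed = 2)
#> first-eigenvalue explained variance (bicor): observed = 0.5064, p = 0 (1000 permutations)
rv_permutation_test(sub, trait_vector(sim$meta1$morph), n_perm = 100, seed = 3)
#> Escoufier RV (trait association): observed = 0.6305, p = 0.02 (100 permutations)

nrow(select_candidates(assoc, net$modules)$blue)
#> [1] 6
```

The generator planted a trait effect of Δ = 2 on two modules; with only six
samples per morph one of them ("blue") is recovered and selected at FDR 0.05:
its eigengene explains 51% of the module's variance (more than any of 1,000
per-gene permutations produce, p = 0), its multivariate association with the
ecomorph contrast survives label permutation (RV p = 0.02), and six genes pass
the joint |kME|, |GS| > 0.7 candidate rule. `run_pipeline()` chains all stages
(preprocessing, networks, trait association, permutation tests, preservation,
consensus, trajectory, QTL overlap) and writes TSV/JSON artifacts plus a
deterministic `report.json` into a run directory; a thin command-line wrapper
is provided in `inst/scripts/coexdiv.R`.

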