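---
title: "Estimating continental ancestry from compact microsatellite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating continental ancestry from compact microsatellite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aimtools)
library(dplyr)
```

## The problem

Genetic association studies are confounded by population stratification:
allele-frequency structure that tracks ancestry rather than phenotype.
Self-declared race is an unreliable proxy for genetic ancestry, especially
in admixed groups such as African-American and Hispanic cohorts. A small
panel of ancestry-informative markers (AIMs) — here multi-allelic
microsatellites (MSATs) — offers a cheap way to measure each subject's
continental admixture proportions directly, using a reference panel of
individuals of known ancestry to anchor the inference.

aimtools implements the complete workflow around such panels:

1. rank candidate loci by the multi-allelic Weir–Cockerham F_st estimator
   and reduce a large candidate set step-wise to a compact panel;
2. estimate individual admixture proportions with a Bayesian clustering
   model fitted by Gibbs sampling, run unsupervised on references and
   query samples jointly;
3. choose the number of ancestral clusters K by the rate-of-change
   (delta-K) criterion over replicate runs;
4. resolve label switching across replicates and average their
   membership matrices;
5. corroborate the clustering with a PCA of presence/absence
   ("false SNP") re-coded genotypes;
6. summarize cohort-level ancestry proportions, compare groups, and flag
   samples whose genetic ancestry contradicts their declared group.

A Balding–Nichols genotype simulator generates reference-plus-cohort
datasets with known truth, so every stage is testable without any
repository download.

## The F_st estimator

For each locus and each allele `u`, with `r` populations of per-locus
non-missing sample sizes `n_i`, sample allele frequencies `p_i` and
frequencies `h_i` of heterozygotes carrying `u`, the method-of-moments
variance components are

- `a` — among populations,
- `b` — among individuals within populations,
- `c = h_bar / 2` — within individuals,

built from the weighted mean `p_bar`, weighted variance `s2` and the
sample-size correction `n_c`. The estimate for any collection of loci is
the ratio of sums `theta = sum(a) / sum(a + b + c)` over all (locus,
allele) pairs — never an average of per-locus ratios, so loci with more
data weigh more. Properties worth knowing:

- the estimator is unbiased, not range-constrained: identical
  populations give estimates at or slightly below zero, which are
  reported as computed;
- loci monomorphic across the grouped populations carry no information
  (the components are 0/0) and are flagged and excluded from the sums;
- pairwise F_st between two populations is the same computation
  restricted to that pair, so a locus monomorphic within a pair drops
  out of that pair only.

The per-allele heterozygote frequency (`h_i` above is the frequency of
heterozygotes *carrying allele u*, not the overall heterozygote
frequency) is what the cited moment estimator specifies for multi-allelic
loci; at a biallelic locus both coincide.

```{r fst}
d <- sim_dataset(sim_config(k = 3, loci = 24, alleles = 8, fst = 0.25,
                            n_ref = 30, seed = 5))
fst_global(d$genotypes)
```

## The admixture model and its sampler

Each individual `i` has ancestry proportions `q_i` over K clusters
(rows sum to 1); each cluster `k` has allele-frequency vectors
`p_{k,l}` per locus; each of the two gene copies an individual carries
at a locus descends from cluster `k` with probability `q_{i,k}` and is
then an allele drawn from `p_{k,l}`. Priors: `q_i ~ Dirichlet(alpha)`
with `alpha` inferred (one per cluster by default), and
`p_{k,l} ~ Dirichlet(lambda, ..., lambda)` with `lambda = 1`.

The Gibbs sweep cycles:

1. `z` — each gene copy's cluster assignment, sampled proportional to
   `q_{i,k} * p_{k,l,j}` for its observed allele `j`;
2. `P` — `Dirichlet(lambda + counts)` given the assignments;
3. `Q` — `Dirichlet(alpha + copy counts)` per individual;
4. `alpha` — a Metropolis step with a normal proposal (sd 0.025 by
   default) and a uniform prior on `(0, 10]`.

Missing genotypes are simply absent from every update (skipped, not
imputed). Initialization draws `z` uniformly at random and then `P` and
`Q` from their full conditionals; `alpha` starts at 1. The model score
`lnP(D)` is estimated from the kept assignment-integrated log-likelihoods
as `mean - variance / 2`, the standard harmonic-style estimator this
score's users expect, and is what delta-K consumes.

The sweep kernels are implemented in C++ (Rcpp) and use R's RNG, so a
run is bit-reproducible given its seed; each kernel is also exposed to R
(`admix_update_z()` and friends) and unit-tested against closed-form
conditional distributions. Desk-scale defaults are 5,000 + 5,000 sweeps,
which recover simulated ancestry on panels of a few dozen loci; analyses
of real panels conventionally use chains two orders of magnitude longer
(e.g. 400,000 burn-in + 350,000 iterations), available through
`admixture_config()`.

```{r admixture}
fit <- run_admixture(d$genotypes, k = 3, burn_in = 1000,
                     iterations = 1000, seed = 2)
glance(fit)
label_clusters_by_reference(fit, sample_metadata(d$genotypes))
```

## Choosing K

`run_k_sweep()` fits every K in a contiguous range with several
replicate chains (seeds derived deterministically from a master seed as
`seed + 10007 K + 101 r`), and `delta_k()` computes, at each interior K,
`deltaK = |L''(K)| / sd(L(K))` from the replicate mean and standard
deviation of `lnP(D)`. The selected K is the argmax; the criterion
cannot judge the endpoints of the sweep. Three policy decisions are
deliberate:

- ties break toward the **larger** K and are flagged — the criterion is
  read as "the uppermost K that is clearly resolved";
- a sweep whose mean scores are exactly linear (no curvature) is
  reported `unresolved` rather than picking an arbitrary K;
- an interior K with zero replicate variance leaves deltaK undefined
  there (flagged with a warning) instead of dividing by zero.

Sweeps may start at K = 1; the K = 1 score is then only the left
neighbour for deltaK at K = 2.

## Label switching and replicate averaging

Cluster labels are exchangeable, so replicate runs disagree by a column
permutation. `align_runs()` permutes every run to best match the first
(the reference), maximizing the similarity
`G = 1 - ||Qa - Qb||_F / sqrt(2N)`, and averages the aligned matrices.
Maximizing G is a linear assignment problem on `crossprod(Qref, Qrun)`;
it is solved exhaustively for K <= 8 and by the Hungarian algorithm for
larger K — the two provably coincide, which the tests confirm
instance-by-instance. Heavier strategies (searching over all run pairs)
are unnecessary for averaging same-K replicates and are omitted.

## False-SNP PCA

Multi-allelic genotypes are re-coded as one binary column per
(locus, allele) scoring presence/absence of the allele in the diploid
genotype — this keeps the standard SNP-PCA machinery applicable to
MSATs. A missing call masks all of that locus's columns for the
individual; masked entries are imputed to the column mean before
centering, the conventional choice for this analysis when data are
missing. Dosage coding (0/1/2 copies) is available behind a flag for
sensitivity checks, and optional binomial-variance column scaling
(`normalize = TRUE`) drops monomorphic columns. Variance fractions are
eigenvalues over the trace of the processed matrix, so they sum to 1
over all PCs.

```{r pca}
pc <- run_pca(recode_false_snp(d$genotypes))
glance(pc)
```

## Panel selection

`threshold_filter()` keeps loci with per-locus theta at or above a
cutoff (0.1 by default, inclusive). `stepwise_reduce()` then shrinks the
panel to successive target sizes, at each step recomputing per-locus
theta on the surviving data and keeping the top-N (ties broken by locus
name for determinism). F_st-informativeness is the only ranking
criterion implemented — it is the documented, reproducible default, and
a user-supplied ranking can be substituted by passing a reordered panel.
Wet-lab practicality (fragment-size ranges, multiplex compatibility) is
out of scope.

## The simulator

`sim_dataset()` draws, per locus, an ancestral frequency vector
`Dirichlet(gamma, ..., gamma)` and population vectors
`Dirichlet(p_anc (1 - F_k) / F_k)` — the multi-allelic Balding–Nichols
model, whose per-allele variance `p (1 - p) F_k` makes `F_k` the
population's expected F_st against the ancestral pool. Individuals then
follow exactly the admixture model above: reference panels have one-hot
ancestry; cohorts carry a label and either a fixed `q` or per-individual
`Dirichlet(alpha_sim)` draws. Allele codes are emitted as
fragment-size-like integers (`100 + 2 index`) with no semantic content —
no mutation model, no linkage, no genealogy. Passing tests on this
generator therefore demonstrates correctness of the estimators and
sampler under the model they assume, not robustness to real-data
artefacts such as allele-binning errors, stepwise-mutation homoplasy or
linked loci.

The default configuration mirrors a compact continental panel: 5
ancestral populations, 36 loci of 10 alleles, divergence 0.2, 50
references per population. Desk-scale study conditions used by the
acceptance checks (chosen once, from the sampler's convergence behaviour
on well-separated simulations): F_st calibration at F = 0.15 with 2
populations x 100 individuals x 36 loci over 20 replicates; admixture
recovery at K = 3, F = 0.25, 150 references + 30 admixed, 5,000 + 5,000
sweeps; K selection on 3 populations x 30 references, 24 loci, K = 1..6,
3 replicates of 1,000 + 1,000 sweeps, 5 master seeds; cohort recovery
with a `Dirichlet(3.2, 0.8)` cohort (mean ancestry 0.8/0.2) of 60
individuals.

## Cohort reporting

`labelled_proportions()` converts a fit's Q into ancestry-labelled
proportions using the reference-anchored cluster map (each cluster takes
the reference group with the largest mean membership; ties go to the
lexicographically first group and are flagged). `summarize_groups()`
reports mean, sd, median, interquartile range and 10th/90th percentiles
per (declared group, ancestry) — the box-plot statistics of cohort-level
admixture reporting. `compare_groups()` uses the Welch (unequal
variance) two-sample t-test, the safer default when an unspecified
"t-test" is called for; two constant equal groups return `p = 1` with a
`degenerate` flag rather than erroring. `flag_discordant()` raises a
flag only when a sample's dominant inferred ancestry is both confident
(>= 0.95 by default) and inconsistent with the declared group's expected
ancestry — the pattern of a mislabelled biospecimen.

```{r pipeline}
cfg <- sim_config(k = 2, loci = 24, alleles = 8, fst = 0.2, n_ref = 30,
                  cohorts = list(cohort("admixed_grp", 20,
                                        alpha = c(3.2, 0.8))),
                  seed = 11)
res <- run_pipeline(cfg, k_fixed = 2, replicates = 2,
                    burn_in = 1000, iterations = 1000, master_seed = 3)
res$summary |> filter(group == "admixed_grp")
```

## Numerical choices and limitations

- All Dirichlet draws clamp zero gamma variates at `1e-300` so simplex
  points never carry exact zeros and log-densities stay finite.
- `lnP(D)` uses the sample variance of kept log-likelihoods; with a
  single kept sample the variance term is 0.
- The delta-K denominator is the replicate standard deviation, so at
  least 2 replicates per K and 3 consecutive K values are required.
- Negative F_st estimates and negative eigenvalue round-off are left
  visible (eigenvalues are clamped at 0 only for variance fractions).
- The sampler assumes unlinked loci and no correlation between cluster
  allele frequencies; supervised mode and the linkage model are
  deliberately out of scope.
- Exact reproduction of any published panel's member list is not a goal:
  the reduction criterion here is F_st rank alone, and published
  reductions typically also weighed assay practicality.
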