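---
title: "Linking gene-family evolutionary rates to morphology with phylogenetic mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene-family evolutionary rates to morphology with phylogenetic mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratemorph)
```

## The scientific problem

Olfactory receptor (OR) genes form the largest gene family in mammalian
genomes, organized into subfamilies (Class I: OR51, OR52, OR55, OR56; and
the Class II groups OR1/3/7, OR2/13, OR4, OR5/8/9, OR6, OR10, OR11, OR12,
OR14). In bats, the evolution of plant-visiting diets raises the question of
whether dietary ecology drives diversification of the olfactory system at
two levels at once: the molecular level (rates of OR sequence evolution) and
the anatomical level (the total surface area of olfactory epithelium
distributed over the nasal turbinates). `ratemorph` implements the
comparative machinery for that question as a reusable, tested pipeline:

1. **Rate extraction.** For each OR gene, a codon-model tree and a
   nucleotide-model tree are inferred upstream from the same alignment
   (tree inference itself is out of scope; trees are inputs). The per-tip
   statistic is the cumulative root-to-tip branch length, obtained as the
   diagonal of the tree's phylogenetic variance–covariance (vcv) matrix.
   Comparing codon-scale to nucleotide-scale cumulative lengths acts as a
   selection-regime proxy in the spirit of dN/dS, while sidestepping
   orthology assignment, which is impractical in large tandemly duplicated
   families.
2. **Hierarchical Bayesian mixed models** (a purpose-built Gibbs sampler)
   for three suites of analyses: allometry of epithelium surface area on
   body mass, regression of codon on nucleotide branch lengths, and a
   two-trait multiresponse model coupling rates and morphology.
3. **A synthetic-data generator** that emulates the statistical structure
   of such a study, so every estimator in the package can be validated by
   parameter-recovery simulation.

## Tree statistics

For a rooted tree with branch lengths, entry $(i,j)$ of the vcv matrix is
the shared root-to-MRCA path length of tips $i$ and $j$; the diagonal holds
root-to-tip depths. `root_to_tip()` recomputes depths by independent edge
traversal, and the test suite checks `diag(phylo_vcv(T)) == root_to_tip(T)`
on hundreds of random trees, together with a brute-force MRCA path-sum
oracle. `relatedness_matrix()` rescales the species-tree vcv so the maximum
diagonal is 1 (the source scaling is not fixed by convention; a unit
diagonal makes the phylogenetic variance component directly comparable to
the residual variance) and returns its inverse, adding a ridge of
`1e-8 * max(diag)` with a warning if the matrix is singular (e.g. two tips
separated by zero-length branches). `prune_tips()` preserves root-to-tip
depths and pairwise covariances of the kept tips — when pruning strands the
old root, the lost basal path is retained as a root stem — which is what
taxa-exclusion reruns require.

Newick dialect: unquoted and single-quoted labels, square-bracket comments
ignored, branch lengths required on all edges (a root edge is ignored),
zero lengths allowed, negative lengths rejected. Polytomies are permitted,
including at the root; input trees are taken as rooted where written, since
gene-tree rooting choices happen upstream.

## The model engine

All three suites are Gaussian mixed models fit by Gibbs sampling:

$$y = X\beta + \sum_r Z_r u_r + e,$$

with $u_r \sim N(0,\, G_r \otimes A_r)$ for each random block. `us()`
blocks estimate the full covariance $G_r$ among the block's design columns
(e.g. intercept and slope); `idh()` blocks constrain $G_r$ to be diagonal.
$A_r$ is an optional relatedness matrix — supplying the species-tree vcv
makes the block an animal-model effect. The residual is either iid or, for
two-trait multiresponse stacks, an unstructured $2\times 2$ covariance per
unit (`us(trait):units`). Full conditionals are standard: a joint
multivariate-normal draw for $(\beta, u)$, inverse-Wishart draws for each
$G_r$ and for the residual covariance (inverse-gamma in one dimension), and
conditional-normal data augmentation for missing responses, so species with
molecular data but no morphology contribute to the fit rather than being
deleted.

**Priors.** Published analyses of this kind rarely report their priors, so
defaults are weakly informative and configurable: fixed effects $N(0, 10^8)$; each variance
block inverse-Wishart with $\nu = \dim + 0.002$ and a diagonal scale in
which each design column gets half the variance of the responses that
column touches. The per-column rule matters for multiresponse stacks: codon
root-to-tip lengths and log surface areas live on different scales, and a
pooled-variance scale (the obvious alternative) is large enough relative to
a 30-species sum of squares to visibly attenuate the species-block
covariance — we measured attenuation of the derived coefficient by a factor
of about 0.6 on seeded replicates before adopting the per-column scale. For
single-response models the rule reduces to the pooled choice. The conjugate
checks in the test suite pass under two different prior settings, and a
`list(fixed = ...)` residual prior pins the residual variance where a
closed-form comparison requires it.

**DIC.** The deviance is $-2$ times the Gaussian log-likelihood of the
observed responses conditional on the location effects (random effects
plugged in), recorded per retained iteration;
$\mathrm{DIC} = 2\bar{D} - D(\hat\theta)$ with $\hat\theta$ the posterior
means of location and dispersion parameters, and $p_D = \bar{D} -
D(\hat\theta)$. This is the conditional convention of the animal-model
software family; a marginal DIC would integrate the random effects and is
not implemented. With augmented (missing) responses the deviance sums over
observed entries only, using the appropriate marginal variance for a unit
with one observed trait.

**Summaries and diagnostics.** Every parameter gets a posterior mean, a 95%
highest-posterior-density interval (empirical shortest interval),
effective sample size (Geyer initial positive sequence), and a Geweke
z-score (first 10% vs last 50%, AR-spectrum variance estimates). The
reporting layer flags parameters with ESS below 200.

## The three suites

**Allometry** (`run_allometry_suite`): log surface area on log body mass
with an animal-model species effect, in three nested candidates — M0 with a
single intercept and slope, M1 adding diet-specific intercepts, M2 adding
diet-specific intercepts and slopes through a `us(1 + log mass):diet`
block. The diet classes come from a continuous dietary index: negative
values are plant-visiting, positive values animal-feeding; an index of
exactly zero (undefined under that convention) goes to "animal" with a
warning. DIC selects among candidates, with ties (within `1e-6`) broken
toward fewer variance parameters.

**Rates** (`run_rates_suite`): codon root-to-tip length on nucleotide
root-to-tip length across gene records, with candidates partitioning
intercept and slope by nothing, plant diet, multiple diet categories (an
arbitrary user-supplied factor, since no canonical category set exists),
OR subfamily, or species — each partition a `us(1 + nucleotide):factor`
block. Partition levels with fewer than 3 records are dropped with a
warning. Per-level slopes are reported as the fixed slope plus the level's
deviation.

**Multiresponse** (`run_multiresponse_suite`): each gene record becomes a
two-trait unit — its codon root-to-tip length, and the log surface area of
its species (repeated across the species' gene records, imputed where
morphology is missing). Fixed effects: trait intercepts, subfamily-specific
nucleotide slopes on the codon trait, and diet intercept plus log-mass-by-
diet slopes on the surface-area trait. The residual is `us(trait):units`.
Two candidate species-block structures are fit and compared by DIC:
`idh(trait):species` (independent per-trait variances) and
`us(trait):species` (full between-trait covariance), both phylogenetically
structured. The headline quantity — the species-level coupling between
codon rates and surface area — is the derived covariance-ratio coefficient
$G_{12}/G_{22}$ (and $G_{12}/G_{11}$ for the reverse direction) computed
per iteration from the `us(trait):species` block, the only structure able
to carry that covariance; with surface area constant within species, the
unit-level residual covariance is structurally uninformative about
species-level coupling (we verified that its ratio centers on zero even
under strongly correlated species effects), so the residual-level ratio is
reported only as a secondary quantity. There is no standardized
group-specific structure for multiresponse models of this kind; the one
implemented here is the package's own, stated openly.

All suites accept an `exclude_mormoopids` flag: mormoopid bats (flagged in
the species table) have hypervariable skull morphology, and reruns without
them are produced as paired results alongside — never silently replacing —
the full-data fit.

## The synthetic-data generator

`sim_config()` defaults define the emulated study conditions: a Yule
species tree with about 30 tips; half the species plant-visiting; body mass
lognormal (log-mean 3, log-sd 0.8, i.e. ~20 g typical); log surface area
affine in log mass per diet class (plant: intercept 2.0, slope 0.6; animal:
1.8, 0.4 — allometric slopes around 0.5 with a plant-visiting elevation)
plus a Brownian species effect (`phylo_var = 0.05` at unit depth) and iid
noise (`resid_var = 0.05`); 13 OR subfamilies with codon-on-nucleotide
slopes spread over 0.7–1.3 and lognormal rate noise (sd 0.3); and partial
gene detection at 55%, the midpoint of the 50–60% recovery reported for
olfactory-epithelium transcriptomes. Genes with fewer than two surviving
tips are dropped, and the species-removal filter
(`filter_low_detection`, default threshold 2) mirrors the removal of a
species represented by a single intact gene.

Joint species effects on (codon-rate level, log surface area) are drawn as
correlated Brownian motions on the tree, so their tip covariance is
`species_covariance` $\otimes$ relatedness — exactly the structure the
multiresponse animal model assumes. We first drew them iid per species and
found the model's phylogenetic whitening amplified the mismatch enough to
break the null-case calibration of the derived coefficient; matching the
generative and model covariance structures restored nominal coverage.
Moreover, the draws are conditioned (whitened and orthonormalized before
mixing) so every dataset realizes the configured covariance exactly: a
recovery experiment "under correlation −0.7" then actually embodies that
correlation in each replicate, rather than a sample correlation anywhere
between −0.3 and −0.9 at 30 species. The default `species_covariance` uses
sd 0.3 per trait and correlation −0.7, the inverse rate–morphology coupling
the multiresponse suite exists to detect.

Design choices a user should know:

- Gene trees reuse the species topology with thinned tips; duplication
  topology is irrelevant because the downstream statistic only consumes
  root-to-tip lengths.
- Nucleotide edge lengths are the species edges times one lognormal
  multiplier per gene (mean 1); codon edges multiply those by the
  subfamily slope and per-edge lognormal noise. Noise is multiplicative so
  lengths stay non-negative.
- The subfamily `codon_intercept` and the per-species codon offsets are
  added to terminal edges only, so each tip's root-to-tip length gains them
  exactly once; terminal edges are clamped at zero, which mildly censors
  extreme negative offsets on short terminal branches (a positive
  `codon_intercept` buffers this when the offsets matter).
- RNA Integrity Numbers are drawn independently of detection; the QC
  regression operation exists, but an RIN-dependent detection mechanism is
  not emulated.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show: real OR alignments (sequence-level processes,
alignment error), gene duplication/loss topology, pseudogenization,
body-mass measurement error, non-Gaussian trait distributions, and
RIN-linked detection bias. Recovery results validate the estimators under
the assumed statistical structure; they are not evidence about any real
dataset.

## Numerical choices and problem sizes

- Relatedness matrices are inverted by Cholesky; singular matrices get a
  `1e-8 * max(diag)` ridge with a warning.
- If the location-effect conditional precision is not positive definite, a
  single jittered retry (`1e-8` relative) is attempted before aborting
  with diagnostics.
- Determinism: every simulation and fit is reproducible from integer seeds;
  the pipeline derives per-stage sub-seeds from one global seed via
  `derive_seed()` (a documented affine counter scheme below $2^{31}$).
- Default chains are 13000 iterations, 3000 burn-in, thinning 10. The
  package's own validation batteries use shorter chains (600–6000
  iterations at 30–50 species, 130–260 genes), sizes at which the
  replicate-level recovery rates they measure are already stable; ESS for
  headline parameters in those runs is typically in the hundreds, and the
  reporting layer warns below 200.

## Known limitations

- Gaussian responses only; all modeled quantities are rates or log-scale
  measurements, for which this matches the source analyses.
- One residual structure per model (iid or `us(trait):units`); candidate
  sets vary random-effect structure only.
- The multiresponse stack supports exactly two traits.
- The package does not attempt to reproduce any published coefficient
  values: those depend on field-collected data and analysis settings not
  available here. It validates its implementations by property-based and
  recovery-based testing instead.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
ds <- simulate_dataset(cfg)
rt <- build_rate_table(ds$gene_tree_pairs)
rt <- filter_low_detection(rt)$table

mc <- mcmc_config(5000, 1000, 4, seed = 1)
allo <- run_allometry_suite(ds$species_table, ds$species_tree,
                            suite_config(mcmc = mc))
rates <- run_rates_suite(rt, ds$species_table,
                         suite_config(partitions = c("none", "plant_diet",
                                                     "subfamily"),
                                      mcmc = mc))
multi <- run_multiresponse_suite(rt, ds$species_table, ds$species_tree,
                                 suite_config(mcmc = mc))
report(list(allo, rates, multi))
```
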