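---
title: "Genomic selection for F1 hybrid breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for F1 hybrid breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The breeding problem

An F1 hybrid breeding program on inbred parent lines faces a combinatorial
wall: a panel of $n$ candidate parents defines $n(n-1)/2$ possible crosses
(5,460 for 105 parents), far more than can be made and phenotyped. Because
the parents are (near-)homozygous, however, the genotype of every F1 is
*predictable* locus by locus, so a genomic prediction model trained on
phenotyped material can score the whole candidate space in silico. This
package implements that workflow — genotype QC, expected-F1 synthesis,
kinship construction, model fitting, accuracy estimation and class
selection — together with a seeded simulator that generates populations with
the same structure and known ground truth.

`hybridgs` assumes diploid (or diploidized) biallelic SNPs coded
$\{-1, 0, 1\} = \{aa, Aa, AA\}$. For allopolyploids such as octoploid
strawberry, this presumes markers restricted to subgenome-specific loci that
segregate disomically; the heterozygote-excess filter (default threshold
0.25) is the guard that removes loci that do not behave this way. The
orientation of the coding (which homozygote is $+1$) is the alt-allele
dosage convention; it is arbitrary but consistent across modules, and it
cancels in every downstream statistic.

## Expected F1 genotypes

The F1 of two homozygous parents is deterministic: identical homozygotes
transmit their genotype, opposite homozygotes produce a heterozygote. When a
parent is heterozygous the offspring locus is segregating; the package codes
it as the heterozygous *expectation class* rather than sampling a gamete.
This keeps hybrid synthesis deterministic — the same cross always yields the
same expected genotype — and matches how near-inbred panels are handled in
practice, where residual heterozygosity is low (about $1/16$ of loci after
four selfing generations). Stochastic gamete sampling exists only in the
simulator, where it belongs.

## Relationship matrices

Additive kinship uses VanRaden's first method,
$A = WW^\top / 2\sum_m p_m(1-p_m)$, with $W$ the dosage matrix
column-centered by $2p_m$. Dominance kinship uses the classical
dominance-deviation coding $\{aa, Aa, AA\} \to \{-2p^2, 2pq, -2q^2\}$ with
denominator $\sum_m (2p_mq_m)^2$. These are the standard parameterizations
behind the mixed-model software this field uses; since different A/D
variants exist, the allele-frequency source is recorded on every matrix, and
kinships for across-population prediction are always built over the combined
individual set with *training-population* frequencies, so that test
individuals never leak information into the model scale.

One consequence worth knowing: on a highly inbred panel the mean diagonal of
$A$ approaches $1+f \approx 2$, so the model-scale $\sigma^2_A$ is roughly
half the genetic variance expressed in the population, and
$h^2_A = \sigma^2_A/(\sigma^2_A+\sigma^2_e)$ is correspondingly lower than
the realized fraction of variance that is genetic. This is a property of the
definition, not an estimation artifact; it is why inbred panels show lower
$h^2$ than F1 populations built from them. Relatedly, dominance kinship on a
near-homozygous panel is ill-posed — the dominance term can absorb noise and
inflate $h^2_{AD}$ — so additive-plus-dominance heritability is best
estimated on populations with real heterozygosity (the F1s).

## Prediction models

Eight model variants are supported: `GBLUP-A`, `GBLUP-AD`, `BB-A`, `BB-AD`,
`BL-A`, `BL-AD`, `RKHS`, `RF`.

**GBLUP.** $y = 1\mu + g_A (+\, g_D) + e$ with
$g_A \sim N(0, A\sigma^2_A)$, $g_D \sim N(0, D\sigma^2_D)$. The default
engine is REML: the single-kinship model is profiled over the variance ratio
on the eigenbasis of $A$ (one eigendecomposition, then a 1-D search on
$\log\lambda \in [-25, 25]$, wide enough that the noiseless limit
$\sigma^2_e \to 0$ is representable); the two-kinship model maximizes the
REML log-likelihood directly over log-variances with L-BFGS-B (with a
Nelder-Mead fallback), each evaluation one Cholesky factorization — at the
population sizes this package targets (a few hundred individuals) this is
more robust than EM-REML iteration and fast enough. A Gibbs engine samples
the same model in the kinship eigenbases, where orthonormal loadings make
every full conditional diagonal; variance components carry scaled
inverse-$\chi^2$ priors (df 5, scales from an even $R^2 = 0.5$ split of the
phenotypic variance). Under the Gibbs engine heritability is computed per
posterior draw and averaged, not as a ratio of posterior means. Predictions
for new genotypes are the mixed-model conditional mean
$\hat g = C V^{-1}(y - \hat\mu)$; a ridge of $10^{-8}$ times the mean
diagonal is added inside the solve only, never to stored matrices.

**Bayes B and Bayesian Lasso.** Whole-genome regression
$y = 1\mu + X_a\beta + X_h\delta + e$, where $X_a$ is the coded genotype
matrix and $X_h$ the $\{0,1\}$ heterozygosity design (the dominance term;
column-centered before concatenation so $\mu$ stays at the population mean —
whether to center is genuinely open, and centering was chosen for
identifiability). Bayes B places a point mass at zero (prior probability
$\pi = 0.95$, optionally updated under a flat Beta hyperprior) and a
scaled-$t$ slab implemented as a per-marker variance with a scaled
inverse-$\chi^2$ prior (df 5, scale set from the phenotypic variance so the
prior genetic variance matches an $R^2 = 0.5$ guess). The Bayesian Lasso
uses the exponential scale mixture of normals with a gamma hyperprior on
$\lambda^2$. Chain defaults are 12,000 iterations, 2,000 burn-in, thinning 5
(the common defaults of this software class; the package's own tests use
shorter chains on smaller designs). Both samplers are compiled (Rcpp),
single-site with residual updating, and draw from R's RNG, so a seed makes
chains bit-reproducible.

**RKHS.** Gaussian kernel
$K_{ij} = \exp(-\theta\, d^2_{ij}/\mathrm{median}(d^2))$ on coded-genotype
squared Euclidean distances, treated as the covariance in the single-kinship
REML path. The bandwidth is not something the data pin down well; the median
heuristic with $\theta = 1$ is the default and $\theta$ is exposed.
Cross-kernels for prediction reuse the *training* median so that test
points cannot shift the scale.

**Random forest** delegates to the `randomForest` package; trees split on
raw codes, so heterozygote-specific effects are representable without an
explicit dominance design. RKHS and RF accept no `-AD` variant for the same
reason: the nonlinearity is already in the model class.

## Accuracy estimation

Cross-validation is replicated $k$-fold (default $2 \times 50$). The fold
partition is a function of `(seed, replicate)` only — replicate $i$ uses
seed $+\,i$ — so every model and trait evaluated at one seed shares
identical folds (paired comparisons), and adding replicates never changes
earlier ones. Accuracy is the Pearson correlation between pooled out-of-fold
predictions and observations, one value per replicate, reported as mean
(SD); pooling is the common convention and yields exactly one value per
replicate (per-fold averaging is available as an option). Undefined
correlations (constant predictions or phenotypes within a replicate) are
recorded as missing with a warning and excluded from the summary.

Across-population prediction trains in one population and correlates
predictions with phenotypes in another, with kinships over the union and
frequencies from training. PCA overlay (`prcomp` on centered codes) is the
diagnostic for whether a training population spans the candidate space.

## Hybrid selection

`predict_all_hybrids()` scores every cross in a plan with per-trait fitted
models; `select_classes()` draws disjoint classes — high and low tails
beyond an outer quantile (default 0.9) and an intermediate band (default the
0.4–0.6 quantiles) — with quotas, lexicographic tie-breaking, and an
explicit excluded-pairs list for crosses that cannot be made (e.g.
flowering-time gaps). The class geometry (outer deciles, middle band,
quotas) is configuration, not dogma: the motivating use case selected about
twenty hybrids across five classes without publishing numeric cutoffs, so
the defaults are chosen to reproduce that geometry and are all exposed.
Note that correlations between predicted and observed values computed *on a
selected set* are inflated for the traits selection acted on, because the
set spans those traits' extremes; `evaluate_selection()` documents this
caveat rather than hiding the number.

## The simulator

The generator mirrors the breeding scheme the analysis assumes: outbred
founders (allele frequencies uniform on $[0.1, 0.9]$, Hardy–Weinberg
heterozygosity; default 22 founders — cosmetic, matching the order of
magnitude of ancestor cultivars in such programs), recurrent random
intercrossing (default 3 cycles), and single seed descent (default 4
generations), with meiosis modeled as independent assortment between
chromosomes plus Poisson crossovers within (default map length 1 Morgan per
chromosome). The recombination model is the minimal standard one; it exists
to give LD structure for the pruning and kinship code to exercise, not to
match a real strawberry map. A `retained_het_fraction` option makes a
chosen fraction of loci immune to fixation, a phenomenological stand-in for
loci kept heterozygous by inbreeding depression: it reproduces the
empirical observation that real inbred panels sit *below* the
$1-(1/2)^t$ homozygosity expectation, without modeling fitness selection.

Trait architectures sample QTL uniformly, draw additive effects from a
normal distribution, set dominance effects as degree-of-dominance times
$|a|$ (degree $\sim N(0.5, 0.25)$ by default, i.e. partial dominance), and
rescale each effect vector so the realized $\sigma^2_A$ and $\sigma^2_D$ in
the reference population equal their targets exactly. Phenotypes add
$N(0, \sigma^2_e)$ noise; an optional environment term draws
environment-specific random marker effects (`env = list(id, sigma2)`),
genetic *within* an environment but uncorrelated *across* environments.
This is deliberately a genotype-by-environment interaction, not a constant
shift: a constant cannot change a correlation, whereas uncorrelated G×E is
exactly the mechanism that makes a trait predictable within a population yet
untransferable across years — the failure mode unstable traits (e.g. sugar
content) show in across-population prediction. Derived-trait helpers
(`leaf_area_index`, `pericarp_color_index`) implement the standard ellipse
approximation ($\text{length}\times\text{width}\times 3.14$) and colorimeter
index ($L^* b^*/a^*$).

What the simulator does **not** emulate: octoploid subgenome structure
(markers are born diploid), selection during line development, pedigree
errors, genotyping error, non-Gaussian residuals, multi-year replicated
trials. Tests passing on synthetic data therefore validate the *machinery*
(coding, algebra, estimators, harness) and the qualitative patterns
(dominance raises $h^2_{AD}$, G×E erodes transfer), not real-data accuracy
levels.

## Numerical choices and degenerate inputs

- LD pruning keeps the earlier-positioned marker of a high-LD pair
  (scan order is reproducible; the upstream tool convention is unspecified).
  $r^2$ uses pairwise-complete observations; pairs with fewer than 3
  complete observations count as $r^2 = 0$.
- Imputation is per-marker mode (ties toward the smaller code) or rounded
  marker mean — deterministic, dependency-light, and adequate under the
  $\le 10\%$ per-marker missingness the QC enforces; a random-forest imputer
  would be the natural upgrade if missingness were heavy. All-missing
  markers are an error naming the marker.
- Filter order is fixed: missingness → MAF → heterozygote excess → LD
  pruning → imputation, and the report records per-rule removals
  sequentially.
- Monomorphic marker sets make kinships undefined (error); fully homozygous
  reference populations make dominance variance targets unachievable
  (error); selection quotas that exclusions render unsatisfiable raise an
  error listing the shortfall.
- Hybrid IDs canonicalize as `"P1xP2"` with sorted parent names, so
  reciprocal crosses collide by construction.

## Problem sizes in the test suite

The package's own checks run at the study geometry where it matters —
105 parents / 5,460 crosses for counting identities, 105 inbreds + 275 F1s
at 2,000 markers for heritability recovery and cross-validation — and at
reduced sizes (tens of parents, hundreds of markers, shortened MCMC chains)
for the many property checks, chosen so the full suite completes in a few
minutes on one CPU. Replicate counts per experiment (10–50) follow the
corresponding analysis conventions. `scripts/acceptance.R --seed S --out F`
reruns the main quantities end to end; all randomness derives from the one
seed.

## Known limitations

- REML variance components on small, highly related panels are noisy;
  single-replicate heritability estimates can miss the truth by 0.2 or
  more, and the package reports them without standard errors (use the Gibbs
  engine's draws for posterior spread).
- The joint A+D fit reports both $\sigma^2_A$ and $\sigma^2_D$, but their
  split is poorly identified when $A$ and $D$ are correlated (same markers);
  their sum, and $h^2_{AD}$, are the stable quantities.
- No multi-trait models, no explicit G×E fitting, no epistasis, no
  mate-allocation optimization — the package predicts and ranks crosses,
  and stops there.
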