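# hybridgs

Genomic selection for F1 hybrid breeding programs built on inbred parent
lines, as used in seed-propagated strawberry breeding: instead of phenotyping
thousands of candidate crosses, a prediction model trained on genotyped and
phenotyped material scores the *expected* genotype of every possible hybrid,
and parental combinations are chosen from the predictions.

The package covers the whole workflow:

- **Genotype QC** — read a VCF (or coded TSV) of biallelic SNPs into a
  `{-1, 0, 1}` = `{aa, Aa, AA}` matrix; filter on missingness, minor allele
  frequency, heterozygote excess (subgenome-specific loci in diploidized
  polyploids) and windowed LD; impute; per-line homozygosity against the
  `1 - (1/2)^t` selfing expectation.
- **In-silico hybrids** — deterministic Mendelian expectation coding of every
  F1: identical homozygote parents transmit their genotype, opposite
  homozygotes give a heterozygote, and any heterozygous parent yields the
  heterozygous expectation class. `all_pairs()` enumerates the n(n−1)/2
  candidate crosses (5,460 for 105 parents).
- **Relationship matrices** — additive kinship `A = WW'/2Σp(1−p)`
  (VanRaden method 1) and dominance kinship `D` from the classical
  dominance-deviation coding `{−2p², 2pq, −2q²}`, plus the `{0,1,0}`
  heterozygosity design for marker-effect dominance models.
- **Prediction models** — GBLUP-A and GBLUP-AD
  (`y = 1μ + g_A (+ g_D) + e`, `g_A ~ N(0, A σ²_A)`, `g_D ~ N(0, D σ²_D)`)
  with REML (eigendecomposition profile likelihood / direct REML) or a Gibbs
  engine; Bayes B (spike-and-slab) and Bayesian Lasso whole-genome
  regression via compiled Gibbs samplers; Gaussian-kernel RKHS regression;
  random forest.
- **Heritability** — `h²_A = σ²_A/(σ²_A+σ²_e)` and
  `h²_AD = (σ²_A+σ²_D)/(σ²_A+σ²_D+σ²_e)`.
- **Evaluation** — replicated k-fold cross-validation with folds shared
  across models and traits (Pearson accuracy, reported as mean (SD)),
  across-population prediction (inbreds → hybrids and vice versa), PCA
  overlay of populations.
- **Selection** — score all candidate hybrids per trait and draw disjoint
  high / low / intermediate classes from the predicted distribution,
  honoring excluded parent pairs.
- **Simulator** — seeded breeding populations (outbred founders → recurrent
  intercrossing → single seed descent) and additive + dominance trait
  architectures with full ground truth, so every stage is testable.

## Worked example

```r
library(hybridgs)

# a synthetic panel standing in for genotyped inbred candidate parents
panel <- simulate_inbred_panel(n_lines = 105, n_markers = 2000, seed = 1)$lines
mean(homozygosity(panel))        # ~0.97 (4 selfing generations from outbred founders)
expected_homozygosity(4)         # 0.9375 for a fully heterozygous start

# 275 training crosses and a trait with additive + dominance architecture
plan  <- sample_plan(individuals(panel), 275, seed = 2)
f1s   <- synthesize_hybrids(panel, plan)
truth <- assign_trait_architecture(f1s, n_qtl = 300, sigma2_A = 2,
                                   sigma2_D = 1, seed = 3)
y     <- simulate_phenotypes(truth, f1s, sigma2_e = 1, seed = 4)

# heritability with and without the dominance term (true h2_AD here is 0.75;
# single-replicate REML estimates are noisy — the acceptance script averages
# replicates, landing near 0.65)
A <- additive_kinship(f1s); D <- dominance_kinship(f1s)
h2_additive(fit_gblup(y, A)$vc)              # 0.487
h2_additive_dominant(fit_gblup(y, A, D)$vc)  # 0.478

# two-fold cross-validation with folds shared across models and traits
crossvalidate(y, f1s, gs_model("GBLUP-AD"), k = 2, reps = 5, seed = 7)
#> GBLUP-AD: 2-fold x 5 reps, accuracy 0.395 (0.030)

# score all 5,460 candidate hybrids and pick selection classes
fit  <- gs_train(y, f1s, gs_model("GBLUP-AD"))
pred <- predict_all_hybrids(list(hardness = fit), panel,
                            all_pairs(individuals(panel)))
sel  <- select_classes(pred, list(
  selection_class("high_hardness", "hardness", "high"),
  selection_class("low_hardness",  "hardness", "low")
), n_per_class = 5)
```

The cross-validated accuracy is the Pearson correlation between pooled
out-of-fold predictions and observed phenotypes (one value per replicate;
mean and SD over replicates). `select_classes` returns the chosen parental
combinations with their predictions and class labels; classes are disjoint
and excluded pairs (e.g. crosses impossible due to flowering-time gaps) are
skipped.

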