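---
title: "Methods: sample-specific pathway enrichment and multi-task integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific pathway enrichment and multi-task integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given matched gene-expression and genotype data for samples in two
phenotype classes (for example estrogen-receptor positive versus negative
tumors), `pathmtl` asks which biological pathways separate the classes
when evidence from both data types is considered simultaneously, and how
well pathway-level features predict class.  Both data types are first
converted into the same representation -- a sample-by-pathway matrix of
enrichment scores -- and the predictive models operate entirely in that
space.  This is what lets a continuous expression matrix and a discrete
SNP dosage matrix be integrated symmetrically.

# From raw data to enrichment scores

## Gene-level genotypes

SNP dosages are collapsed to genes before scoring.  For each gene we take
the SNPs lying between 1,000 bases upstream of the transcription start
site (strand-aware) and the end of the transcribed region, drop those
with minor allele frequency at or below 0.05, and keep the single SNP
with the largest Pearson chi-square association with the phenotype --
its dosage row then represents the gene (`snps_in_gene_window()`,
`select_representative_snps()`, `collapse_to_gene_level()`).  Ties in the
chi-square are broken by genomic position and then by SNP identifier, so
the mapping is deterministic.  Genes with no eligible SNP are dropped;
downstream gene sets simply see them as unmapped.

## Correlation statistics

For each sample `i` and gene `j` a correlation statistic `s_ij` measures
whether the sample's value looks more like class C1 or class C2:

* expression: the Gaussian log-likelihood ratio
  `log f_C1(x_ij) - log f_C2(x_ij)` with class means and standard
  deviations estimated per gene.  Standard deviations are floored at
  `max(sd, 0.2 |mean|, 1e-8)` so a constant gene cannot produce an
  infinite statistic;
* genotype: `log(p1/p2)`, where `p_k` is the fraction of class-k samples
  carrying the sample's genotype at that gene.  If either class has zero
  carriers, both counts and both denominators gain a pseudo-count of 1.

Both statistics are estimated leave-self-out by default: a cohort
sample's own class parameters (or carrier counts) exclude that sample.
The reason is exchangeability.  An external sample scored against the
cohort's class profiles never contributes to them; if cohort samples
self-contribute, every cohort sample receives a coherent own-class shift
at all genes simultaneously, and a classifier trained on such features
learns a signature that external samples cannot have.  With
leave-self-out, the statistic of a cohort sample and of an external
sample drawn from the same population have the same expectation.  The
flag `leave_self_out = FALSE` restores self-inclusion for comparison.

## The enrichment score

Within one sample, all genes are ranked by decreasing `s_ij` (ties keep
the stable input gene order).  Walking down the ranking, member genes of
a set add `|s|^p / sum_set |s|^p` and non-members subtract `1/(G - m)`;
the enrichment score is the signed maximal deviation of this running sum
from zero, a weighted Kolmogorov--Smirnov statistic in `[-1, 1]`.  The
weight exponent defaults to `p = 1`; `p = 0` gives the classical
unweighted KS walk.  If every member statistic is exactly zero (possible
for genotype data when a set's genes are monomorphic) the member weights
fall back to uniform rather than dividing by zero.  When the positive and
negative extremes of the walk tie in absolute value, the value at the
earliest rank position is returned, which keeps the score deterministic.

One caveat worth knowing: the weighted score is not monotone in a single
member's statistic.  Raising a late member's `|s|` increases the
normalizing mass `sum_set |s|^p` and can lower an early member's peak.
The unweighted walk (`p = 0`) is monotone under rank improvements; the
property tests cover both facts.

Optional normalization (`normalize_enrichment()`) permutes the class
labels (preserving class sizes), recomputes background scores, and
divides each positive score by the mean positive background and each
negative score by the absolute mean negative background for that
(sample, set) cell.  Backgrounds are per-cell rather than pooled across
samples.  Normalization is off in the simulation experiments and
intended for cross-set comparisons of predictive weights.

# Predictive models

All six models are linear soft-margin SVMs over enrichment-score
features, fit by an in-package SMO dual solver (`train_svm()`) with
second-order working-set selection.  Class C1 is coded `+1`; a decision
value of exactly zero predicts C1.

* **single-task** -- one SVM per data type;
* **concatenated** -- all tasks' samples stacked in the shared gene-set
  feature space, one SVM;
* **multi-task** -- one SVM over the stacked samples with the coupling
  kernel `K[s,t] = (1/mu + [same task]) <x_s, x_t>`.  Task-specific
  effects are `v_t = sum_{i in t} alpha_i y_i x_i`, the common effect is
  `w0 = (1/(mu T)) sum_t v_t`, and the per-task weight is `w0 + v_t`.
  Small `mu` ties tasks tightly; as `mu` grows the kernel tends to the
  block-diagonal single-task Gram.  Even in that limit the joint dual
  keeps a single `sum(alpha y) = 0` constraint and one bias for all
  tasks, so per-task decision functions agree with independently fitted
  single-task models up to an intercept allocation; predicted classes
  coincide in practice and exactly for symmetric tasks;
* **summed prediction** -- per-task single SVMs whose real-valued
  decisions are summed per matched sample;
* **summed enrichment score** -- per-set scores summed across data types
  before a single fit (identically zero sums are rejected as degenerate);
* **merged** -- per-task scores concatenated along gene sets into one
  feature vector; the fitted weights split back into per-task blocks and
  the per-set ranking weight is the block sum.

Gene sets are ranked by decreasing `|w|` (ties by set name); the sign of
a weight only encodes class direction.  Any constant factor in the weight
expressions rescales all weights equally and cannot change a ranking,
which is why the solver's weight normalization needs no further
convention.  `C` and `mu` both default to 1 and are recorded in the
fitted object.

The dual solver targets a KKT tolerance of `1e-6`.  On ill-conditioned
Gram matrices SMO can cycle in double precision slightly above such a
tight target; the solver detects stalled progress at exact-gradient
checkpoints and stops at the best achievable gap, erroring only if that
gap is large relative to the kernel scale.  Box and equality feasibility
of the duals hold to `1e-6` after every fit and are asserted in the test
suite, alongside a cross-check of the solver against an independent SVM
implementation.

Leave-one-out evaluation (`loo_matched()`) refits per fold and, in the
default strict mode, recomputes class profiles and enrichment scores
without the held-out sample so its label never touches the statistics.
The fast mode reuses full-cohort scores; it is cheaper but its statistics
leak the held-out label and it exists for exploration only.  Reported
metrics are overall accuracy, positive predictive value TP/(TP+FP) and
negative predictive value TN/(TN+FN), with C1 as the positive class and
`NA` when a denominator is zero.

# The synthetic-data generator

`build_scenario()` emulates matched case-control data with four gene-set
types, ten genes per set: type 1 sets are differentially expressed *and*
genetically associated, type 2 only differentially expressed, type 3
only genetically associated, type 4 background.  Mechanistically each
gene is linked to one SNP: type-1 and type-3 SNPs enter an additive
liability, type-2 genes draw their expression effect from private SNPs
outside the liability (so their genotype rows are noise with respect to
phenotype), and type-4 genes pair with background SNPs.

* genotypes: Hardy--Weinberg dosages, `Binomial(2, f)` per SNP and
  sample; linked-SNP frequencies `U[0.05, 0.5]`, background frequencies
  `Beta(0.1, 0.1)`;
* disease model: heterozygote odds ratios `U[1.1, 1.3]`, `beta = log OR`
  per liability SNP, liability
  `eta_i = eta0 + sum_j beta_j g_ij + e_i` with standard-normal error
  and `P(C1) = plogis(eta)` (probit behind a flag).  The intercept is
  calibrated by root-finding so the mean class-1 probability over the
  generated pool is 0.5, and samples are drawn until each class reaches
  its quota, giving exactly balanced cohorts.  The nominal prevalence of
  0.02 is recorded in `sim_params()` as part of the disease-model
  parameterization;
* expression: per-set multivariate-normal baselines (mean 0, unit
  variance, exchangeable correlation 0.2) plus an additive genotype
  effect `gamma * g` with `gamma ~ U[1.0, 1.5]` for differentially
  expressed genes; background genes are `N(0, 1)`.  The baseline
  moments and frequency samplers are configurable substitutes for values
  that would be estimated from a reference tumor cohort, so users with
  access to such data can restore cohort-derived settings;
* matched emission: the identical dosage matrix feeds the expression
  effects and the gene-level genotype task, so no window mapping is
  involved in simulations.

`build_task_collection()` generates families of related single-data-type
tasks: per task, 100 sets of which sets 1--30 are associated and 31--50
background everywhere, while a random 30 of sets 51--100 are associated
per task -- half the feature space shared, half task-specific.

Everything is deterministic given a seed.  What the generator does *not*
emulate: linkage disequilibrium (SNPs are independent), population
structure, missing genotypes, platform normalization artifacts, and
realistic expression covariance beyond the exchangeable within-set
baseline.  Passing tests on this generator therefore validate the
pipeline's mechanics and statistical calibration, not performance on any
particular real cohort.

# Experiments, problem sizes and what the defaults can show

The experiment harness reruns generate-enrich-fit-predict cycles and
aggregates accuracies or target-set ranks with standard errors computed
over replicate means.  Test enrichment is always computed against the
training cohort's class profiles: test labels never touch the
statistics.  The packaged studies use scaled replicate counts -- 50
replicates for the accuracy studies and 100 for the rank study in the
test suite, 40/25 in the acceptance script -- chosen so the full suite
runs comfortably on a laptop; flags restore larger counts.

Two properties of the default generative conditions deserve emphasis,
because they bound what any leakage-free analysis of these simulations
can achieve.

First, polygenic dilution.  With `N` causal SNPs in the liability, the
marginal class gap of each SNP's dosage behaves like
`2 beta var(g) E[logistic']`, and the logistic derivative shrinks as the
liability variance grows with `N`.  At the packaged compositions
(60--200 causal SNPs) the per-SNP gap is about 0.05 dosage units and
stays in that range even for much larger odds ratios -- each SNP's
marginal association is capped by the crowd of the others.

Second, out-of-sample transfer.  The enrichment score compresses a
1,000-gene ranking into one number per 10-gene set, which preserves
strong coordinated shifts but attenuates weak distributed ones.  Under
the default conditions the class separation that survives in
out-of-sample enrichment features is small, so all six models sit near
chance accuracy, statistical ties dominate the model orderings, and
per-replicate target-set ranks are highly variable.  The acceptance
script reports exactly these computed values.  Substantially higher
absolute accuracies from this pipeline would require either much larger
per-SNP effects than the stated odds-ratio range can produce or scoring
schemes in which a test sample's own label enters its statistics, which
the package deliberately rules out.  The model machinery itself is
validated separately on constructed strong-signal instances, where
separable cohorts are classified perfectly and planted informative sets
rank first.

# Numerical choices collected

* variance floor `max(sd, 0.2 |mean|, 1e-8)` for expression class
  profiles; zero-variance leave-one-out folds floor the same way;
* pseudo-count of 1 on both classes whenever a genotype carrier count is
  zero on either side;
* ranking ties in `s` broken by stable gene order; running-sum extremes
  tied in absolute value resolved to the earliest rank position;
* all-zero member weights fall back to uniform;
* dosage coding counts the empirically rarer allele, ties broken toward
  the lexicographically smaller allele; missing genotype calls are
  rejected rather than imputed;
* gene-set size bounds are inclusive (`[15, 100]` mapped genes by
  default);
* SVM: `C = 1`, `mu = 1`, tolerance `1e-6` with stall detection, bias
  included, decision ties to C1;
* coordinates are 1-based inclusive; 0-based BED input is shifted at
  parse time.
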