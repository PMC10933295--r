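---
title: "Multi-omics subtyping and fracture-risk modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics subtyping and fracture-risk modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

osteomix implements an integrative analysis of osteoporosis cohorts profiled
on three molecular modalities — CpG methylation (beta values), serum
metabolites (positive abundances) and gut microbiota (relative abundances) —
together with genotypes and clinical phenotypes. This vignette explains the
statistical machinery, the choices we made where the design was genuinely
open, and what the synthetic cohort generator does and does not emulate.

## Data model and transforms

All molecular containers are features × samples. Each modality carries value
semantics that are validated on construction and mapped to an *analysis
scale* before any linear or correlation-based computation:

* methylation beta values → logit (M-value-like), clamped away from 0/1;
* metabolite abundances → natural log;
* microbiota relative abundances → centred log-ratio (CLR) with a
  pseudocount of half the smallest positive value, because compositional
  vectors live on the simplex and raw proportions induce spurious negative
  correlation.

Rank-based procedures (Wilcoxon screens, Spearman networks) are invariant to
these monotone transforms feature-wise; the transforms matter for the
autoencoders, the QTL linear models and the one-class regression.

## DLSF: deep latent space fusion

Each modality $m$ is standardized feature-wise and passed through a small
autoencoder (tanh hidden layers, width 128 capped at the feature count,
linear 32-dimensional latent). Writing $\hat X_m = \mathrm{Dec}_m(Z_m)$, the
training objective is

$$\sum_m \lambda_{rec}\,\lVert X_m - \hat X_m\rVert_F^2 / n
      + \lambda_{se}\,\lVert \hat X_m - \hat X_m C_m\rVert_F^2 / n
      + \lambda_{reg}\,\lVert C_m\rVert_F^2,
      \qquad \operatorname{diag}(C_m) = 0,$$

optimized full-batch with Adam in two phases: reconstruction-only
pretraining (200 epochs), then a joint phase (300 epochs) in which each
self-expression matrix $C_m$ is periodically reset to its exact
zero-diagonal ridge minimizer while the network weights follow the combined
gradient. The closed-form solve works through whichever Gram matrix is
smaller and imposes the zero diagonal by a per-column Lagrange correction,
so it is exact, cheap and deterministic.

Two design points deserve emphasis, because both were decided by measurement
on synthetic cohorts:

1. **Self-expression lives in the decoder's reconstruction space, not in
   the raw latent coordinates.** The latent code of an autoencoder is
   identified only up to an invertible mixing; that mixing scrambles the
   Gram matrix from which the affinity is built. In our experiments the
   latent code linearly contained the leading principal components
   (R² ≈ 0.9) yet latent-space self-expression produced affinities with no
   cluster contrast, while the decoder image — which inherits the data's
   variance structure through the reconstruction loss — produced
   essentially perfect ones.
2. **The fused affinity uses the positive part of $C_m$, not its absolute
   value**: $S = \tfrac1M \sum_m \mathrm{normalize}\!\left(\mathrm{relu}(C_m)
   + \mathrm{relu}(C_m)^\top\right)$. Clusters that differ by a mean shift
   are antipodal after standardization, so cross-cluster self-expression
   coefficients are *negative*; folding them in by absolute value wires the
   two clusters together and destroys the cut. A negative coefficient is
   evidence of opposition, not similarity.

The coefficient ridge defaults to $\lambda_{reg} = 20$ (effective ridge
$\alpha = n\lambda_{reg}/\lambda_{se}$). Small ridges whiten the latent Gram
matrix, which suppresses exactly the high-variance direction that separates
subtypes; large ridges approach a plain inner-product kernel, which keeps
it. Results are insensitive across $\alpha$ within two orders of magnitude
of the default.

Clustering is normalized-cut spectral clustering: symmetric-normalized
affinity, top-$k$ eigenvectors, row normalization, then k-means with 50
restarts under a fixed seed. The cluster count is selected over $k \in
\{2,3,4\}$ by maximizing the number of clinical phenotypes associated with
the labels (Wilcoxon for continuous phenotypes at $k=2$, Kruskal–Wallis
beyond, chi-squared for binary ones; raw $P < 0.05$, deliberately not
multiplicity-corrected because the criterion is a count at a fixed
screening level) subject to a normalized-entropy balance floor of 0.25,
with ties to the smaller $k$. Either the osteoporosis samples alone
(default) or the full cohort can be clustered.

## Cluster evaluation

Balance is the normalized entropy $H(p)/\log k$ of the cluster proportions.
Stability re-runs the entire training on 80% subsamples (10 resamples) and
reports the mean pairwise adjusted Rand index over shared samples. Label
agreement uses the contingency-table ARI (via mclust), which the test suite
checks against a brute-force pair-counting oracle.

## DAM and M3S

Stratum-specific association matrices are pairwise Spearman correlations
with asymptotic t-approximation p-values, computed within each subtype.
Rewiring between strata is tested pairwise with the Fisher-z statistic
$z = (\operatorname{atanh}\rho_1 - \operatorname{atanh}\rho_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$; discovery lists are BH-corrected, and a pair
is flagged a *sign flip* when the correlations have opposite signs with
$|\rho| \ge 0.3$ in both strata (the magnitude bar is our choice; sign flips
are the biologically interesting rewiring mode but tiny opposite
correlations are noise).

The stemness-like signature weights are a one-class least-squares ridge
regression (OCLR-style): on the standardized reference stratum, $w =
(ZZ^\top + \lambda I)^{-1} Z\mathbf 1$ scaled to unit norm, with $\lambda$
defaulting to the reference size so neither the penalty nor the reference
covariance dominates. Per-sample indices are Spearman correlations between
$w$ and the standardized sample profile, making the index invariant to
per-feature scaling. M3S is, per modality, the intersection of the top-q
features by $|w|$ with the Wilcoxon-significant features, ordered by
weight; an empty intersection falls back to top-q by weight with a warning.
The reference stratum is configurable (default: the subtype being
characterized), since the upstream definition of the reference population
is not fixed by any single convention.

## Genotype QC and xQTL

Variants are kept when call rate ≥ 95%, minor allele frequency ≥ 5%
(computed on non-missing calls) and the *exact* Hardy–Weinberg test
p-value ≥ 1e-5. The exact test conditions on the allele counts, evaluates
every feasible heterozygote configuration by the standard recurrence, and
sums the probabilities of configurations no more likely than the observed
one; the suite verifies it against an independent lgamma-based enumeration
to 1e-12 for totals up to 500. We chose the exact test over the chi-squared
approximation because the QC threshold sits deep in the tail where the
approximation is unreliable at low MAF.

Global snpGene screens use a chi-squared test on the genotype-count × group
table, pooling the homozygous-alternate class into the heterozygotes when
any expected cell drops below 5. xQTL scans fit, per (variant, feature),
ordinary least squares of the analysis-scale feature on the additive dosage
plus covariates (default age, sex and top-8 genotype PCs computed on
mean-imputed standardized dosages), with Wald p-values and the fixed
$P < 10^{-5}$ hit threshold and no further multiplicity correction. Missing
dosages are dropped pairwise; monomorphic variants are skipped. Variant →
gene annotation is interval-based on BED-style half-open 0-based
coordinates with a symmetric flank (default 10 kb): a variant at 1-based
position $p$ maps to a gene iff $p - 1 \in [\text{start}-\text{flank},
\text{end}+\text{flank})$, with class precedence exonic > intronic >
intergenic.

## Risk models

Three nested logistic tiers: Baseline I (age, BMI, drinking, smoking),
Baseline II (+ β-CTX, osteocalcin, PINP) and the M3S model (+ molecular
signatures). Gender can be added to every tier with a flag. The molecular
subset is chosen by greedy mRMR under the MID criterion — first pick
maximizes mutual information with the outcome, each next pick maximizes
relevance minus mean redundancy — with MI estimated on equal-frequency
4-bin discretization and lexicographic tie-breaks, run on the training
split only. The fit is IRLS maximum likelihood with a tiny L2 penalty
(1e-6 on standardized slopes) so perfect separation yields a finite,
warned-about fit; coefficients and Wald slope standard errors are reported
on the original scale. Evaluation uses a seed-fixed stratified 70/30
split: AUC is the Mann–Whitney statistic with midrank ties, intervals are
DeLong (via pROC), decision curves report net benefit
$TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and treat-none.

## Fracture-risk ranking and composite indices

Each feature is scored directly as a risk index; orientation is chosen so
the AUC is ≥ 0.5 and recorded (−1 for protective indices such as BMD).
Candidates clear AUC > 0.6. Covariate-adjusted AUC residualizes the feature
on one of three schemes — (1) age + gender, (2) + prior fracture, (3) + FN
BMD — by least squares within the population and recomputes the oriented
AUC on the residuals; we chose residualization because it is deterministic,
transparent, and reduces exactly the covariate-explained part of the
ranking signal. Composite indices enumerate every panel of up to four
candidates and score each panel by the sum of member values, each member
first oriented and z-scored within the population so "sum of abundances"
is scale-comparable across members; a raw-sum mode reproduces the literal
unstandardized definition. Both populations are supported: ALL (everyone)
and OP (osteoporosis samples only).

## The synthetic cohort generator

The generator is first-class, tested code: it encodes the statistical
structure the analyses assume so that every stage can be exercised and
calibrated without patient data. Defaults: 91 normal / 158 osteopenic / 117
osteoporosis samples; two osteoporosis subtypes of equal expected size;
300/200/150 features for methylation/metabolites/microbiota; 10 subtype
signature features per modality shifted by 1.5 z-units (alternating sign);
20/15/15 group-signature features at 1.0 z; 10 microbiota–metabolite pairs
rewired from Spearman +0.6 (subtype 1) to −0.6 (subtype 2); 400 variants at
Hardy–Weinberg proportions with MAF in (0.05, 0.45) and 1% missingness;
5 planted variant→feature effects of 1 latent-SD per alternate allele; and
a logistic fracture model with intercept logit(0.07), +1.2 log-odds for
subtype 2, −0.6 per FN-BMD SD and +1.0 for prior fracture. Where no
external value pins these down, the magnitudes were fixed once so that
planted structure is recoverable but not trivial at the default cohort
size — effect sizes are testability choices, not estimates of real
signature strengths.

Modality synthesis works on a Gaussian latent scale (where all mean shifts
and QTL effects are planted) and then maps through each modality's natural
observation transform: inverse-logit around per-feature baselines for
methylation, exponential for metabolites, exponential followed by closure
to the simplex (logistic-normal) for microbiota. Correlation rewiring is
planted afterwards by a Gaussian-copula quantile remap that targets the
requested Spearman correlation (using the exact Pearson↔Spearman relation
for bivariate normals) while preserving each feature's within-stratum
marginal exactly, up to the final simplex re-closure for compositions.
Phenotypes encode the subtype contrast — subtype 1 lower at hip sites,
higher at the lumbar spine, better follow-up BMD response — and group-wise
BMD/turnover differences. All randomness fans out from one master seed
through named sub-streams, so enlarging one modality never perturbs
another's draws, and identical configurations are bit-identical.

What the generator does *not* emulate: array chemistry and probe noise,
sequencing depth and zero inflation in microbiome profiles, batch effects,
imputation uncertainty, linkage disequilibrium between variants,
population stratification (beyond what the PCs covariate path can absorb),
and longitudinal trajectories beyond one follow-up BMD delta. Green tests
on this generator therefore demonstrate the pipeline's statistical
correctness and calibration, not robustness to those real-data pathologies.

## Numerical and operational choices

* Exact Wilcoxon p-values when both groups are ≤ 25 and untied; otherwise
  the normal approximation with tie correction and continuity correction.
* Screens use raw P < 0.05 (the field's screening convention for these
  analyses); BH q-values are always reported alongside, and DAM discovery
  lists use BH at 0.05.
* Self-expression solves pick the cheaper Gram side automatically; the
  k-means step uses a fixed seed sequence, making entire runs reproducible
  to the byte.
* Floats serialize at 10 significant digits, which makes every
  reader/writer pair a byte-stable round trip.
* Degenerate inputs fail loudly: empty sample intersections, beta values
  outside [0, 1], compositions that do not close, collinear covariates,
  disconnected affinity graphs with more components than clusters.

Problem sizes used by the test suite (reduced feature counts ~300 per
modality, 20 cohort replicates for clustering properties, 50 replicates for
xQTL type-I calibration, 10 resamples for stability) were chosen as the
smallest sizes at which the measured properties are stable; they are the
package's own simulation-study design.

## Known limitations

The autoencoders are deliberately small and full-batch; they are not meant
for thousands of samples or GPU-scale feature counts. The xQTL scan is a
dense per-pair OLS without LD-aware pruning or mixed-model relatedness
control. The composite screen is exhaustive and should be kept under ~20
candidates. Baseline multi-omics clustering methods (SNF, PINS, PFA) are
not re-implemented; `compare_labelings()` ingests their label files for
side-by-side evaluation instead.
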