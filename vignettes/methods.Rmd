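---
title: "Methods: variance decomposition and genomic prediction in open-pollinated progeny trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance decomposition and genomic prediction in open-pollinated progeny trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`larchgp` partitions the phenotypic variance of traits measured on an
open-pollinated (OP) forest progeny trial into additive, dominance,
imprinting (parent-of-origin) and first-order (additive-by-additive)
epistatic components, and benchmarks genomic prediction models built on
those components. The observational unit is a tree on a randomized complete
block (RCB) grid; the full linear mixed model is

$$y = X\beta + Z_p p + a + d + i + e + \varepsilon,$$

where $\beta$ holds a grand mean and fixed block effects, $p$ are i.i.d.
row-plot effects, and the genetic components have covariances
$G_A\sigma^2_a$, $G_D\sigma^2_d$, $G_I\sigma^2_i$ and
$G_{AA}\sigma^2_e$. Pedigree-based counterparts ($A_A$ from the tabular
method; $A_D$ from parental additive relationships) give the ABLUP model
family; every reduced model is the same engine with a subset of terms.

Key conventions:

* the counted allele at every locus is re-oriented to the *minor* allele,
  and $p_j$ is its observed frequency among non-imputed calls, so the
  denominators $2\sum p_j(1-p_j)$ (additive) and $\sum(2p_j(1-p_j))^2$
  (dominance, imprinting) are well defined and reproducible;
* imputation (binomial draws at the observed allele frequency) precedes
  matrix construction, but frequencies are always computed from observed
  calls, avoiding circularity between imputation draws and frequencies;
* the imprinting design codes ordered heterozygotes $\pm 1$ (maternal
  allele listed first). Parental origin is resolved by Mendelian deduction
  only — a homozygous genotyped dam (or, in the full-sib pedigree view,
  sire) fixes the phase. Unresolvable heterozygotes contribute 0 to $M_I$
  and are counted in a phasing report rather than dropping the tree, which
  keeps all matrices conformable;
* $G_{AA}$ is the Hadamard square $G_A \# G_A$, positive semidefinite by
  the Schur product theorem. Any covariance used in a fit is "bent" by an
  escalating ridge ($10^{-8}\times$ mean diagonal) until its smallest
  eigenvalue reaches $10^{-10}$, because finite-sample $G_D$/$G_I$ can be
  numerically indefinite.

## REML engine

All ABLUP/GBLUP variants are fitted by one multi-kernel REML engine
(`fit_reml()`), maximizing the restricted likelihood over positively
constrained variance components. The default algorithm takes one EM warm-up
step and then average-information (AI) updates with step-halving; a pure EM
mode is retained because its monotone likelihood ascent makes a useful
cross-check (the suite verifies AI and EM agree to $10^{-6}$ in log
likelihood on instances with interior optima, and that REML equals the
closed-form ANOVA estimators on balanced one-way designs and a dense
grid-search oracle at small $n$).

Numerical choices worth recording:

* the constraint floor is $10^{-8}\,\mathrm{var}(y)$. A larger floor (e.g.
  $10^{-6}\,\mathrm{var}(y)$) measurably violates nesting monotonicity —
  holding a useless component at the floor costs $|{\rm score}|\times$ floor
  in log likelihood, which at $10^{-6}$ scale exceeds the $10^{-6}$
  agreement we require between nested fits;
* components at the floor are held (and re-enter when their score turns
  positive), and they still count in $\rho$, the number of estimated
  variance parameters: the package compares *pre-specified model forms*,
  not post-hoc reduced ones. $\rho$ excludes fixed effects, following the
  usual REML-AIC convention;
* `AIC = -2 logL + 2 rho`; the default BIC uses the standard $\log(n)\rho$
  penalty, with `bic_variant = "doubled"` available for reports that double
  it. Models within 2 of the best criterion value are reported as tied;
* convergence is declared on the largest relative parameter change
  ($10^{-8}$ by default); non-convergence returns a usable fit flagged
  `converged = FALSE`, mirroring how trait/model combinations that fail to
  converge are reported rather than dropped.

Heritabilities are $h^2 = \sigma^2_a/\sigma^2_P$ and
$H^2 = \sigma^2_g/\sigma^2_P$, where $\sigma^2_g$ sums exactly the genetic
terms present in the model and $\sigma^2_P$ all random components including
plot and residual. Standard errors use the delta method with the inverse
average-information matrix over free components.

## RKHS regression

The RKHS models replace each genomic matrix with a reproducing kernel and
are fitted by a blocked Gibbs sampler: conditional normal updates for fixed
effects and for each component's genetic values in the eigenbasis of its
kernel (where the conditional posterior is diagonal), scaled inverse
chi-square updates for all variances, and conditional-normal imputation of
masked responses. Validation trees therefore enter the sampler with their
phenotypes set to `NA`: the imputed values are draws from the model and
carry no information, so masking correctness holds by construction (and is
tested).

The trial data never dictate bandwidths or priors, so these are package
design choices:

* kernels are Gaussian, $K_{xy} = \exp(-h\,d^2_{xy})$, on the squared
  Euclidean distance between marker rows normalized by its own mean, making
  $h$ scale-free. The default is kernel averaging over
  $h \in \{0.25, 1, 5\}$, each (component, bandwidth) pair a separate
  variance term;
* the averaging set also includes, by default, each component's *linear*
  kernel — the genomic relationship matrix itself, and its Hadamard square
  for the epistatic term. A linear kernel is a perfectly valid reproducing
  kernel, and including it nests GBLUP inside the RKHS model space. This
  matters for benchmarking: with purely Gaussian kernels the slightly worse
  capture of the additive signal can cancel the epistatic gain, and the
  comparison against GBLUP-A degenerates into a coin flip on data where the
  two models are nearly equivalent;
* the epistatic kernel defaults to the Hadamard square of the additive
  kernel (configurable to its own Gaussian kernel);
* variance priors are scaled inverse chi-square with 5 degrees of freedom,
  scales set so each prior mode equals an equal split of $\mathrm{var}(y)$
  across terms — weakly informative and identical across components;
* default chain settings are 20,000 iterations, 2,000 burn-in, thinning 100
  (180 retained draws); the cross-validation experiments below use shorter
  chains (2,500 / 500 / thin 2) because posterior *means* of genetic values
  are what is scored and averaging over all post-burn-in draws suppresses
  Monte Carlo noise far faster than thinned tails. Basic effective-sample
  size diagnostics are reported per variance component.

## Synthetic trials

The generator's defaults emulate the motivating trial: 66 OP families of
9-12 trees (about 661 progeny) from an orchard with 152 maternal and 97
pollen-parent clones, 11,333 SNPs with founder minor allele frequencies
uniform on [0.05, 0.5], Hardy-Weinberg founders, Mendelian unlinked
gametes with recorded parental origin, an RCB layout with 5 blocks and
5-tree row plots on a 2 m grid, 17.7% missing-at-random genotype calls, and
phenotypes summing block, plot, genetic and residual effects. Pollen
parents are drawn uniformly (panmixia, no selfing); the pollen-contribution
distribution of a real orchard is unknown, and this is a modeling choice.
Family sizes are uniform on the configured range. Block effects are fixed
draws (SD 0.5 by default) recorded in the truth object; the default
variance shares (additive 0.25, dominance 0.05, imprinting 0.05, epistasis
0.15, plot 0.05, residual 0.45) sit between the additive-dominated and
epistasis-dominated trait classes the package is designed to distinguish.

Genetic values are drawn, by default, from multivariate normals whose
covariances are the *realized* relationship matrices of the simulated
genotypes. The fitted model is then correctly specified, which makes
parameter recovery a clean test of the estimator rather than of a
generating-model approximation. A marker-effect mode
(`marker_effects = TRUE`) instead builds additive, dominance and imprinting
values from per-marker effect draws and the epistatic value from random
pairwise products of centered additive codes (functional
additive-by-additive epistasis, whose implied covariance is again the
Hadamard square); it exists for robustness studies where model
misspecification is the point.

What passing tests on these data do *not* show: the generator has unlinked
loci (no LD), exact Hardy-Weinberg founders, missingness that is
missing-at-random, no genotyping error, and — in the default mode —
genetic values that match the fitted covariance model exactly. Real GBS
data violate all of these, so recovery results here bound what the
estimator can do under ideal conditions, not what any particular field
dataset will yield.

## Experiment sizes and two honest limitations

The packaged experiments run at desk scale: recovery and cross-validation
use trials of 400 progeny (40 families of 10; 50 maternal and 68
pollen parents, the pollen pool scaled from the motivating trial's 97
sires for 572 assigned progeny) and 2,000 SNPs, with 50 replicates for
recovery and 10 replicates of 5-fold cross-validation for prediction.
Recovery fits use relationship matrices built from exactly the loci the
generator used, and omit the plot term when the generating plot share is
zero — re-filtered matrices or a family-nested plot indicator otherwise
absorb several percent of the genetic share and corrupt the bias
measurement.

Two findings from these experiments deserve emphasis:

1. **Epistatic and residual variance are barely separable at this scale.**
   $G_{AA}$ is close to an identity matrix plus weak family structure, so
   the likelihood distinguishes $\sigma^2_e$ from $\sigma^2_\varepsilon$
   only through modest half-sib/full-sib covariances. Mean variance shares
   are recovered nearly unbiasedly (maximum absolute bias 0.001-0.033
   across the three packaged architectures), but individual-replicate
   estimates of the epistatic share have a standard deviation around 0.3
   and collapse to the boundary in a nontrivial fraction of replicates —
   multi-start AI-REML and EM confirm these are genuine likelihood optima,
   and on epistasis-dominated data the median AIC difference between models
   with and without the epistatic term is approximately zero. No
   classification rule built on such a likelihood can reliably label single
   replicates as additive- versus epistasis-dominated at this sample size;
   the packaged classification check documents this limit rather than
   hiding it.

2. **Epistatic predictive gain is real but small on synthetic data.** With
   covariance-correct simulation, the best possible epistasis-aware
   predictor is the linear GBLUP-AE model, and its advantage over GBLUP-A
   is bounded by the epistatic covariance between validation and training
   relatives (about +0.01-0.03 in predictive ability at $n=400$). GS-RKHS
   with the linear-plus-Gaussian kernel set tracks this gain and beats
   GBLUP-A in most replicates of the epistasis-dominated architecture,
   while showing no significant advantage under a pure-additive
   architecture — the qualitative pattern expected for the two trait
   classes — but the synthetic margins are much smaller than the gaps
   reported on real data, where epistasis is mechanistic rather than
   covariance-specified.

## Degenerate inputs and tie-breaks

Configuration validation rejects empty parent pools, zero SNPs, variance
shares that do not sum to one, and missingness rates of one or more. Loci
monomorphic in a progeny sample are dropped before matrix construction;
fully missing loci are a filtering error, not an imputation case. Edge
trees on the field grid use only the neighbours that exist in the
competition index; mean-zero traits flag the coefficient of variation as
undefined instead of dividing by zero; cross-validation folds with fewer
than three scored pairs or zero variance return `NA` and are excluded from
summaries with a warning. Paired model comparisons with zero-variance
differences are decided by the sign of the common difference.
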