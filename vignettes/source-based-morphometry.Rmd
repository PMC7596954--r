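---
title: "Source-based morphometry: models, parameters and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-based morphometry: models, parameters and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmtools)
```

## The model

Source-based morphometry treats a stack of voxel-based-morphometry (VBM)
gray-matter density maps as a linear mixture. With $N$ participants and $V$
voxels inside a common brain mask, the data matrix $X \in \mathbb{R}^{N
\times V}$ is modeled as

$$X \approx A\,S,$$

where the rows of $S \in \mathbb{R}^{d \times V}$ are *spatially
independent* component maps (structural covariation networks) and $A \in
\mathbb{R}^{N \times d}$ holds the *participant loadings*: the scalar
expression of each network in each participant. `sbm_decompose()` estimates
this factorization by voxel-wise demeaning, PCA whitening to order $d$, and
fixed-point ICA over the spatial dimension (symmetric decorrelation,
log-cosh contrast) — the spatial-ICA convention used when group ICA tools
are applied to stacked structural maps. Downstream inference then works on
the loadings:

* `fit_loading_glm()` regresses each loading column on diagnostic group
  with age, sex, full-scale IQ and scan site as covariates, reporting the
  group coefficient $\beta$, its $t$ and two-sided $p$, and Cohen's
  $d = t\sqrt{1/n_1 + 1/n_2}$, with Benjamini–Hochberg FDR over components.
* `permutation_glm()` runs the analogous mass-univariate voxelwise model
  with Freedman–Lane permutation and two-tailed threshold-free cluster
  enhancement (TFCE) for family-wise error control.
* `fit_cca()` and friends relate the loading matrix to symptom batteries by
  canonical correlation analysis (CCA), testing the main mode by
  permutation against a Bonferroni level of $0.05/\text{number of modes}$,
  and probing reliability by leave-one-out refits and subsampling curves.

## ICA conventions and numerical choices

**Identifiability.** ICA is blind to component order, sign and scale. Sources
are z-scored for reporting; each component's sign is canonicalized so its
spatial skewness is positive (GM covariation networks are localized
positive blobs on a near-zero background, so positive skewness puts the
network in the positive tail and makes group-effect directions
reportable). Cross-decomposition comparisons go through
`match_components()`, a greedy one-to-one assignment on absolute spatial
correlation.

**Restarts and convergence.** The fixed-point iteration uses tolerance
`1e-6` and at most 1000 iterations; 5 random restarts are run and the best
by the log-cosh negentropy proxy is kept. Restarts guard against the local
optima that appear at high model orders. Non-convergence of every restart
is an error carrying the convergence record, not a silent fallback.

**Model order.** `estimate_order()` offers two rules. `variance_threshold`
picks the smallest order capturing a configured fraction of variance.
`laplace` maximizes the Laplace approximation to the probabilistic-PCA
model evidence over the eigenspectrum of the subject-space covariance
(voxels as observations), the approach behind automatic dimensionality
estimation in group-ICA software. Two numerical points matter: the
eigenspectrum must be truncated to its numerical rank before evaluating the
evidence (a zero tail eigenvalue corrupts the residual-variance term and
drives the argmax to $N-2$), and the feature count entering the evidence is
the truncated spectrum length. With these in place the estimator recovers
planted dimensionality (a $K=10$ phantom yields estimates near 10) and
collapses to 1 on white noise.

**Variance normalization.** Whether voxel-wise variance normalization should
precede ICA is genuinely open in this tradition; the default is demeaning
only, with `variance_normalize = TRUE` available, because variance
normalization re-weights high-variance cortical rim voxels in a way the
mixing model does not require.

## The phantom generator

`generate_phantom()` produces the study conditions every test runs under: a
$20 \times 24 \times 20$ voxel grid (2 mm voxels), $N = 200$ participants,
$K = 5$ spatial sources, each a Gaussian blob of $\sigma = 2.5$ voxels
placed by rejection sampling so that all pairwise source correlations stay
below 0.2 (emulating anatomically clustered, weakly overlapping networks),
additive voxel noise of sd 0.1 against unit blob amplitude, a diagnostic
group of 58% of the sample, and group effects planted as mean shifts of
−0.36 and −0.32 sd on the first two loadings — the magnitude of the
published case–control effect sizes in this literature.

**Loadings.** Loadings are unit-variance Laplace around a positive offset
(default 10 sd). The Laplace choice is load-bearing: ICA is unidentifiable
under Gaussian loadings, so a super-Gaussian loading law is required for
parameter-recovery tests to make sense. The positive offset plays the role
of the non-negative mean GM density: it keeps the mixed maps non-negative,
so the clip at zero is essentially never active, the noiseless phantom is
an *exact* rank-$K$ product, and the truth record reproduces the emitted
matrix to the last bit. The offset contributes only a mean map, which the
ICA removes by demeaning.

**Behavior scores.** One canonical mode is planted: a latent variate $u$ (a
fixed unit-norm combination of the last three loadings) generates $Q$
behavior scores as $y_q = w_q u + \varepsilon_q$. Scaling
$\lVert w \rVert = \sigma_\varepsilon\, r_0 / \sqrt{1 - r_0^2}$ makes the
population canonical correlation exactly $r_0$ (default 0.7, the order of
published brain–symptom canonical correlations). Symptom scales receive
independent noise on top of the planted mode — their true covariance
structure is not publicly documented, so independence is the neutral
choice.

**Covariates and demographics.** Age (uniform 6–30 y), sex (Bernoulli with
the ~73%/65% male imbalance typical of autism case–control cohorts), IQ
(group means 99.4/104.9), uniform site assignment over 5 sites, and an
ADHD comorbidity indicator (46.5%/10.4%) receive small slopes on the
loadings with alternating sign across components, so covariate adjustment
is exercised without creating a dominant rank-one confound.
`generate_missingness()` masks behavior rows completely at random, with the
complete-case count equal to $N - \lfloor fN \rfloor$ (rounding toward
completeness), reproducing published attrition arithmetic such as 194
complete parent-battery cases out of 347 (55.9%).

**What the phantom does not emulate.** No cortical anatomy, no scanner or
site artifacts in the maps themselves, no registration error, no spatial
autocorrelation of the noise, and no heavy-tailed or skewed symptom
distributions. Passing tests therefore demonstrate correctness of the
estimation machinery under the generative assumptions of the method — they
do not certify performance on real multi-site MRI.

One consequence of the heavy-tailed loadings deserves note: the
homogeneity QC rule (flag a subject whose mean spatial correlation with the
others falls 3 sd below the sample mean) flags roughly 2% of phantom
subjects, because Laplace loadings legitimately produce 3-sd outliers at
that rate. On real data the same rule flags subjects for visual review
rather than automatic exclusion; the tests assert the flagged fraction
stays small rather than exactly zero. Whether QC correlations should be
computed on smoothed or raw maps is not standardized; both are exposed
(`on_smoothed` in the pipeline config), defaulting to smoothed, mirroring
QC modules that operate on processed maps.

## GLM and FDR choices

The design matrix codes group TD = 0 / autism = 1, dummy-codes site against
a reference level, and drops rows listwise per analysis — which is what
produces the shifting per-analysis sample sizes (e.g. 599 &rarr; 500 when an
ADHD covariate is requested and 99 participants lack the rating). Variant
analyses (ADHD covariate, age², interaction terms, IQ-restricted samples)
are expressed through the term list, not separate code paths. FDR is
Benjamini–Hochberg: the cited FDR procedure in this literature without a
named variant is conventionally read as BH; the step-up implementation is
cross-checked in the tests against a brute-force execution of the
definition. Cohen's $d$ is derived from the group $t$ via
$d = t\sqrt{1/n_1+1/n_2}$, the covariate-adjusted form whose sign follows
$\beta$.

## Voxelwise inference

TFCE integrates cluster extent and height across thresholds:
$\mathrm{TFCE}(v) = \sum_h e(h,v)^{E}\, h^{H}\, \mathrm{d}h$ with the
canonical $E = 0.5$, $H = 2$, $\mathrm{d}h = \max/100$ and 26-connectivity.
Two-tailed maps enhance the positive and negated maps separately and
recombine with sign. Permutation inference is Freedman–Lane: data are
residualized against the reduced (covariates-only) model, residual rows are
permuted and re-residualized, and the group statistic is recomputed against
the covariate-orthogonalized group regressor — plain label shuffling is not
exchangeable when covariates are present. The null distribution is the
maximum of the two-tailed TFCE map, giving voxelwise FWE p-values with
floor $1/(P+1)$. The connected-component labeling and threshold sweep are
compiled (Rcpp); tests require agreement with a naive R threshold-sweep
oracle to $10^{-9}$.

## CCA choices

Columns of both sets are z-scored (symptom scales have heterogeneous
units), and the canonical system is solved by SVD of the whitened
cross-covariance with rank truncation, so collinear columns fall back to a
pseudo-inverse rather than an error. No regularization is applied by
default — plain CCA at $N$ around twice the variable count is the regime
the method is used in, and a deliberately ill-posed refit (subsample sizes
at or below $\max(p_x, p_y)$) is flagged but still attempted, because the
collapse of those refits is itself a finding the stability analysis is
meant to expose. The permutation test permutes rows of $y$ (equivalent
under exchangeability and cheaper), recomputes the first canonical
correlation, and uses the conservative $(1 + \#\{r_\pi \ge r\})/(P+1)$
estimate; only the first (main) mode is tested, against $0.05/\min(p_x,
p_y)$ — the Bonferroni-over-modes reading of a single-main-mode test.
"Corrected" canonical coefficients are structure coefficients: the
correlation of each variable with its own set's canonical variate. This is
the standard interpretation-oriented correction of raw weights, it is
invariant to the arbitrary weight splits that collinearity induces, and it
is what per-variable contribution rankings should be read from.

Leave-one-out stability refits the CCA $N$ times, sign-aligns the main-mode
weights to the full-sample solution and reports the mean weight
correlation, separately for the brain and behavior sets; the subsampling
curve repeats this over random subsets of increasing size. Under the
default planted mode both LOO means exceed 0.9 and the curve rises
monotonically to 1, collapsing below roughly $\max(p_x, p_y)$ samples —
the qualitative signature that a canonical mode is real rather than
overfit.

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on phantoms:
100-seed ICA recovery at $N = 200$, $V = 9600$, $K = 5$; 1000-simulation
FDR calibration over 20 components at $N = 200$; 200-run CCA type-I
calibration at 500 permutations plus 100-seed power runs at $N = 300$,
$p_x = 20$, $p_y = 5$; leave-one-out and subsampling at the same geometry;
TFCE oracle comparisons on $8^3$ maps. These sizes were chosen to put
Monte-Carlo error well below the margins being asserted while keeping the
whole suite around a minute of compute.

## Known limitations

* The decomposition does not implement mixture-model voxel-level inference
  on component maps; display thresholding of z-scored maps is provided
  instead.
* The voxelwise module offers no variance smoothing or tail-approximation
  accelerations; permutation counts are meant to be honest and small
  problems are the target.
* The published FDR threshold of a 100-component real-data analysis cannot
  be reconstructed without all 100 p-values; nothing in the package claims
  to reproduce restricted-access results, and the real-data coefficients
  quoted in the literature serve only as the scale at which phantom effects
  are planted.
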