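# sbmtools

Source-based morphometry in R: spatial ICA decomposition of gray-matter
density maps into structural covariation networks, covariate-adjusted group
inference on the resulting participant loadings, voxelwise
permutation/TFCE inference, and permutation-tested canonical correlation
between brain components and symptom batteries — validated end to end on a
synthetic phantom with known ground truth.

## Who this is for

Voxel-based morphometry (VBM) assigns every brain voxel a gray-matter (GM)
density, and mass-univariate case–control contrasts on those maps are
famously unstable across cohorts. Source-based morphometry replaces the
voxel-by-voxel view with a mixture model: the stacked subject-by-voxel
matrix is decomposed as

    X  ≈  A S,        A: N x d participant loadings,  S: d x V spatial sources,

where the rows of `S` are spatially independent covariation networks
(estimated by FastICA after PCA whitening) and `A[i, k]` quantifies how
strongly network `k` is expressed in participant `i`. Group differences and
brain–behavior associations are then tested on the loadings:

* per-component GLM of loadings on diagnosis with age, sex, IQ and site
  covariates, Benjamini–Hochberg FDR across components, effect sizes as
  Cohen's `d = t * sqrt(1/n1 + 1/n2)`;
* mass-univariate voxelwise GLM with Freedman–Lane permutation and
  two-tailed threshold-free cluster enhancement (TFCE, `E = 0.5`, `H = 2`,
  dh = max/100, 26-connectivity) for family-wise error control;
* canonical correlation analysis (CCA) between all loadings and a symptom
  battery, with the main mode tested by permutation against a Bonferroni
  level `0.05 / n_modes`, structure-coefficient ("corrected") weights for
  interpretation, and leave-one-out plus subsampling stability curves.

Because real deeply-phenotyped cohorts of this kind are restricted-access,
the package ships a first-class phantom generator (`generate_phantom()`)
that emits NIfTI maps with planted spatial sources, group effects,
covariate slopes and one planted canonical mode — every stage of the
pipeline is testable against ground truth without any download.

## Worked example

```r
library(sbmtools)

spec <- phantom_spec(n_subjects = 200, n_sources = 5, seed = 1)
ph   <- generate_phantom(spec)         # dataset + phenotypes + truth record

dec <- sbm_decompose(ph$dataset, order = 5, seed = 1)
dec
#> sbm_ica: order 5 on 200 subjects, 9600 voxels
#>   explained variance (whitening): 0.875

match_components(dec, ph$truth$true_sources)$pairs
#>   a b     abs_r
#> 1 2 2 0.9977373
#> 2 5 3 0.9964512
#> 3 1 5 0.9964259
#> 4 4 4 0.9930722
#> 5 3 1 0.9930375

fit <- fit_loading_glm(dec$loadings, build_design(ph$phenotypes))
fit$table
#>   component    beta      t        p       d fdr_significant
#> 1      IC01 -0.0991 -0.687 4.93e-01 -0.0984           FALSE
#> 2      IC02 -0.5897 -4.131 5.41e-05 -0.5918            TRUE
#> 3      IC03 -0.3783 -2.771 6.13e-03 -0.3971            TRUE
#> 4      IC04 -0.0710 -0.479 6.32e-01 -0.0687           FALSE
#> 5      IC05  0.0777  0.532 5.95e-01  0.0762           FALSE
```

Every planted source is recovered at spatial |r| > 0.99, and the two
components carrying the planted group shifts (mean loading shifts of
−0.36 and −0.32 sd, mapped through the ICA's arbitrary component order to
IC02/IC03 here) are exactly the ones surviving FDR. The brain–behavior arm,
within the "autism" group:

```r
aut <- ph$phenotypes$group == "autism"
y   <- as.matrix(ph$phenotypes[aut, grep("^beh_", names(ph$phenotypes))])
cca <- fit_cca(dec$loadings[aut, ], y)
pt  <- cca_permutation_test(dec$loadings[aut, ], y, n_perm = 1000, seed = 1)
cca$perm_p <- pt$perm_p; cca$n_perm <- pt$n_perm
cca
#> cca_result: 116 complete cases, 5 modes (bonferroni alpha 0.01 )
#>   canonical correlations: 0.772, 0.233, 0.186, 0.091, 0.046
#>   main-mode permutation p: 0.000999 ( 1000 permutations )
```

The first canonical correlation sits near the planted population value of
0.7 and beats every one of 1000 permutations; the remaining modes are
noise. `loo_stability()` and `subsample_reproducibility()` quantify how
reliably those main-mode weights are estimated.

The full analysis — simulate, QC, decompose, GLM, voxelwise inference,
CCA — also runs as one configuration-driven call, `run_pipeline()`, or from
a shell via the thin wrapper `inst/cli/sbm_pipeline.R` (YAML config, TSV
tables, NIfTI maps, JSON summaries, config-hash provenance).

## Scope

Tissue segmentation, nonlinear registration and Jacobian modulation are
upstream of this package (phantom maps stand in for preprocessed VBM
output); anatomical labeling of components and figure styling are out of
scope. See the vignette (`vignettes/source-based-morphometry.Rmd`) for the
model assumptions, parameter defaults and what phantom validation does and
does not establish.
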