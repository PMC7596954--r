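#' Specification of a structural-covariation phantom
#'
#' Defines a synthetic gray-matter density study: N participants' maps are
#' built as mixtures of K smooth spatial sources weighted by per-participant
#' loadings, plus voxel noise. A diagnostic group effect is planted as a mean
#' shift on designated loadings, covariates (age, sex, FSIQ, site) receive
#' small slopes on the loadings, and behavior scores are generated from a
#' designated linear combination of loadings so that exactly one canonical
#' brain-behavior mode of known strength is planted.
#'
#' Loadings are unit-variance Laplace (super-Gaussian, which makes the
#' spatial ICA identifiable) around a positive offset; the offset keeps the
#' mixed densities non-negative so the clipping at zero is essentially never
#' active and the noiseless phantom is an exact rank-K product.
#'
#' @param grid_shape integer length-3 voxel grid, default `c(20, 24, 20)`.
#' @param n_subjects number of participants.
#' @param n_sources number K of planted spatial sources.
#' @param source_radius Gaussian blob sigma, in voxels.
#' @param source_amplitude peak amplitude of each blob.
#' @param noise_sd additive Gaussian noise sd per voxel.
#' @param group_effect list of `c(source, shift)` pairs: standardized mean
#'   shift on that source's loading in the autism group relative to TD.
#' @param autism_fraction fraction of subjects in the autism group.
#' @param behavior_sources indices of sources whose loadings drive behavior;
#'   default the last `min(3, n_sources)` sources.
#' @param n_behavior number Q of behavior scores.
#' @param planted_r target canonical correlation of the planted mode, in (0, 1].
#' @param behavior_noise_sd noise sd added to each behavior score.
#' @param covariate_effects named list of slopes of age (per year), sex
#'   (male = 1), fsiq (per IQ point) and site (per site index, centered) on
#'   the loadings; applied with alternating sign across components.
#' @param site_count number of scan sites.
#' @param loading_offset positive location of the Laplace loadings.
#' @param voxel_size_mm voxel dimensions in millimetres.
#' @param seed RNG seed; the phantom is a deterministic function of the spec.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20L, 24L, 20L),
                         n_subjects = 200L,
                         n_sources = 5L,
                         source_radius = 2.5,
                         source_amplitude = 1,
                         noise_sd = 0.1,
                         group_effect = list(c(1, -0.36), c(2, -0.32)),
                         autism_fraction = 0.58,
                         behavior_sources = NULL,
                         n_behavior = 5L,
                         planted_r = 0.7,
                         behavior_noise_sd = 1,
                         covariate_effects = list(age = 0.02, sex = 0.1,
                                                  fsiq = 0.005, site = 0.05),
                         site_count = 5L,
                         loading_offset = 10,
                         voxel_size_mm = c(2, 2, 2),
                         seed = 1L) {
  if (is.null(behavior_sources)) {
    nb <- min(3L, n_sources)
    behavior_sources <- seq.int(n_sources - nb + 1L, n_sources)
  }
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), n_subjects = as.integer(n_subjects),
         n_sources = as.integer(n_sources), source_radius = source_radius,
         source_amplitude = source_amplitude, noise_sd = noise_sd,
         group_effect = group_effect, autism_fraction = autism_fraction,
         behavior_sources = as.integer(behavior_sources),
         n_behavior = as.integer(n_behavior), planted_r = planted_r,
         behavior_noise_sd = behavior_noise_sd,
         covariate_effects = covariate_effects,
         site_count = as.integer(site_count), loading_offset = loading_offset,
         voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 1L))
  if (spec$n_sources >= spec$n_subjects)
    stop("n_sources must be smaller than n_subjects")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  if (spec$behavior_noise_sd <= 0) stop("behavior_noise_sd must be positive")
  src_idx <- vapply(spec$group_effect, function(ge) ge[1], numeric(1))
  if (length(src_idx) && (any(src_idx < 1) || any(src_idx > spec$n_sources)))
    stop("group_effect source indices must lie in 1..n_sources")
  if (any(spec$behavior_sources < 1) || any(spec$behavior_sources > spec$n_sources))
    stop("behavior_sources indices must lie in 1..n_sources")
  if (spec$planted_r <= 0 || spec$planted_r > 1)
    stop("planted_r must lie in (0, 1]")
  diam <- 2 * spec$source_radius
  if (any(spec$grid_shape < diam))
    stop("degenerate grid: every dimension must be at least the blob diameter (",
         diam, " voxels)")
  invisible(spec)
}

## one Gaussian blob over the grid, peak source_amplitude at `center`
blob_volume <- function(grid, center, sigma, amplitude) {
  ax <- lapply(1:3, function(d) (seq_len(grid[d]) - center[d])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  amplitude * exp(-d2 / (2 * sigma^2))
}

## rejection-sample blob centers until all pairwise spatial correlations < 0.2
sample_sources <- function(spec, mask) {
  grid <- spec$grid_shape
  margin <- ceiling(spec$source_radius)
  k <- spec$n_sources
  v <- sum(mask)
  sources <- matrix(0, k, v)
  vols <- vector("list", k)
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    tries <- tries + 1L
    if (tries > 2000L) stop("could not place ", k, " sources with pairwise ",
                            "spatial correlation < 0.2; enlarge the grid")
    center <- vapply(1:3, function(d)
      runif(1, 1 + margin, grid[d] - margin), numeric(1))
    vol <- blob_volume(grid, center, spec$source_radius, spec$source_amplitude)
    cand <- as.numeric(vol[mask])
    ok <- TRUE
    if (placed > 0L) {
      r <- suppressWarnings(cor(cand, t(sources[seq_len(placed), , drop = FALSE])))
      if (any(abs(r) >= 0.2, na.rm = TRUE)) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      sources[placed, ] <- cand
      vols[[placed]] <- vol
    }
  }
  sources
}

#' Generate a phantom gray-matter dataset with known ground truth
#'
#' Draws spatial sources, loadings, phenotypes and behavior scores according
#' to `spec`, assembles participant maps as `loadings %*% sources + noise`
#' clipped at zero, and returns both the dataset and the truth record needed
#' to score recovery. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @param dir optional output directory; when given, per-subject NIfTI maps,
#'   the mask, the phenotype TSV (`phenotypes.tsv`) and the truth JSON
#'   (`truth.json`) are written there.
#' @return A list with elements `dataset` (a [gm_dataset]), `phenotypes`
#'   (data.frame) and `truth` (class `phantom_truth`: `true_sources` K x V,
#'   `true_loadings` N x K, `noise` the realized additive term such that
#'   `true_loadings %*% true_sources + noise` equals the emitted matrix
#'   exactly, and `planted_mode` with x/y weight vectors and the planted
#'   canonical correlation).
#' @export
generate_phantom <- function(spec, dir = NULL) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    grid <- spec$grid_shape
    mask <- array(TRUE, dim = grid)
    n <- spec$n_subjects
    k <- spec$n_sources

    sources <- sample_sources(spec, mask)

    ## phenotypes
    n_aut <- round(n * spec$autism_fraction)
    group <- c(rep("autism", n_aut), rep("TD", n - n_aut))
    age <- runif(n, 6, 30)
    # male proportions mirror the case-control imbalance typical of autism
    # cohorts (~73% male in cases, ~65% in controls)
    sex <- ifelse(runif(n) < ifelse(group == "autism", 0.729, 0.647),
                  "male", "female")
    fsiq <- rnorm(n, mean = ifelse(group == "autism", 99.4, 104.9),
                  sd = ifelse(group == "autism", 18.9, 18.3))
    site <- sample.int(spec$site_count, n, replace = TRUE)
    adhd <- rbinom(n, 1, ifelse(group == "autism", 0.465, 0.104))

    ## loadings: offset Laplace, unit variance, plus planted effects
    loadings <- matrix(rlaplace_unit(n * k), n, k) + spec$loading_offset
    for (ge in spec$group_effect)
      loadings[group == "autism", ge[1]] <- loadings[group == "autism", ge[1]] + ge[2]
    ce <- spec$covariate_effects
    comp_sign <- rep_len(c(1, -1), k)
    cov_term <- (ce$age %||% 0) * (age - mean(age)) +
      (ce$sex %||% 0) * (as.numeric(sex == "male") - mean(sex == "male")) +
      (ce$fsiq %||% 0) * (fsiq - mean(fsiq)) +
      (ce$site %||% 0) * (site - mean(site))
    loadings <- loadings + outer(cov_term, comp_sign)

    ## behavior: one planted canonical mode through the designated sources
    wx <- numeric(k)
    wx[spec$behavior_sources] <- 1 / sqrt(length(spec$behavior_sources))
    lc <- sweep(loadings, 2, colMeans(loadings))
    u <- as.numeric(lc %*% wx)
    u <- u / sd(u)
    q <- spec$n_behavior
    wy_dir <- seq(q, 1) / sqrt(sum(seq(q, 1)^2))
    # |wy| chosen so the population canonical correlation equals planted_r
    wy <- wy_dir * spec$behavior_noise_sd * spec$planted_r / sqrt(1 - spec$planted_r^2)
    behavior <- outer(u, wy) +
      matrix(rnorm(n * q, sd = spec$behavior_noise_sd), n, q)
    colnames(behavior) <- sprintf("beh_%d", seq_len(q))

    ## maps
    clean <- loadings %*% sources
    emitted <- clean + matrix(rnorm(n * ncol(sources), sd = spec$noise_sd),
                              n, ncol(sources))
    emitted <- pmax(emitted, 0)
    noise <- emitted - clean   # realized additive term, including any clipping

    ids <- sprintf("sub-%03d", seq_len(n))
    phen <- data.frame(subject_id = ids, group = group, age = age, sex = sex,
                       fsiq = fsiq, site = site, adhd = adhd,
                       behavior, stringsAsFactors = FALSE)
    dataset <- gm_dataset(emitted, mask, voxel_size_mm = spec$voxel_size_mm,
                          subject_ids = ids)
    truth <- structure(
      list(true_sources = sources, true_loadings = loadings, noise = noise,
           group_effect = spec$group_effect,
           planted_mode = list(x_weights = wx, y_weights = wy,
                               r = spec$planted_r),
           behavior_names = colnames(behavior), seed = spec$seed),
      class = "phantom_truth")

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_dataset(dataset, dir)
      write.table(phen, file.path(dir, "phenotypes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(planted_mode = truth$planted_mode,
             group_effect = lapply(spec$group_effect, as.numeric),
             seed = spec$seed, n_sources = k),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    list(dataset = dataset, phenotypes = phen, truth = truth)
  })
}

#' Mask behavior scores missing completely at random
#'
#' Marks `floor(fraction * nrow)` subjects' behavior columns as missing;
#' diagnosis and covariate columns are never masked. Rounding is toward
#' completeness, i.e. the number of complete rows is
#' `nrow - floor(fraction * nrow)`.
#'
#' @param table phenotype data.frame.
#' @param fraction proportion of rows to mask, in `[0, 1)`.
#' @param seed RNG seed.
#' @param behavior_cols columns to mask; defaults to every `beh_*` column.
#' @return The table with the selected behavior entries set to `NA`.
#' @export
generate_missingness <- function(table, fraction, seed = 1L,
                                 behavior_cols = grep("^beh_", names(table),
                                                      value = TRUE)) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  if (fraction == 0 || length(behavior_cols) == 0) return(table)
  n_miss <- floor(fraction * nrow(table))
  with_seed(seed, {
    rows <- sample.int(nrow(table), n_miss)
    table[rows, behavior_cols] <- NA
  })
  table
}
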