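#' TFCE parameters
#'
#' Canonical defaults for threshold-free cluster enhancement: extent
#' exponent `E = 0.5`, height exponent `H = 2`, integration step `dh` equal
#' to 1/100 of the map maximum, 26-voxel connectivity.
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param dh integration step as a fraction of the map maximum, in `(0, 1]`.
#' @param connectivity 6, 18 or 26.
#' @return List of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = 0.01, connectivity = 26L) {
  stopifnot(E > 0, H > 0, dh > 0, dh <= 1, connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a 3D statistic map
#'
#' For each voxel, integrates `e(h, v)^E * h^H * dh` over thresholds `h`
#' from `dh_abs` up to the map maximum in steps of `dh_abs`, where
#' `e(h, v)` is the extent of the voxel's connected suprathreshold cluster
#' at height `h` and `dh_abs = params$dh * max(map)` (computed per tail).
#' Two-tailed enhancement processes the positive and negated maps separately
#' and recombines them with sign, so negative statistics receive negative
#' enhanced values.
#'
#' @param stat_volume 3D numeric array of voxelwise statistics (finite).
#' @param params a [tfce_params].
#' @param two_tailed enhance both tails (default TRUE). With
#'   `two_tailed = FALSE` an all-negative map enhances to zero.
#' @return 3D numeric array of enhanced values.
#' @export
tfce <- function(stat_volume, params = tfce_params(), two_tailed = TRUE) {
  if (!all(is.finite(stat_volume))) stop("stat map must be finite")
  d <- dim(stat_volume)
  if (length(d) != 3L) stop("stat map must be a 3D array")
  enhance_tail <- function(v) {
    v <- pmax(v, 0)
    mx <- max(v)
    if (mx <= 0) return(array(0, dim = d))
    array(.tfce_pos_cpp(as.numeric(v), as.integer(d), params$E, params$H,
                        params$dh * mx, params$connectivity), dim = d)
  }
  pos <- enhance_tail(stat_volume)
  if (!two_tailed) return(pos)
  pos - enhance_tail(-stat_volume)
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return 3D integer array of cluster labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array")
  array(.label_components_cpp(as.logical(mask), as.integer(d),
                              as.integer(connectivity)), dim = d)
}

#' Voxelwise group GLM with Freedman-Lane permutation and TFCE FWE control
#'
#' Computes the voxelwise t statistic for the group coefficient in the full
#' design, then builds the null distribution of the maximum two-tailed TFCE
#' statistic by Freedman-Lane permutation: data are residualized against the
#' reduced (covariates-only) model, residual rows are permuted, re-
#' residualized, and the group statistic recomputed against the covariate-
#' orthogonalized group regressor. Family-wise-error p values per voxel are
#' `(1 + #(null max >= observed)) / (n_perm + 1)`.
#'
#' @param dataset a [gm_dataset]; rows must align with the phenotype table
#'   the design was built from (the design's retained rows are selected).
#' @param design output of [build_design]; must contain the group column.
#' @param n_perm number of permutations (>= 100).
#' @param params a [tfce_params].
#' @param seed RNG seed for the permutations.
#' @return Object of class `voxel_inference`: `stat_map`, `tfce_map`,
#'   `fwe_p_map` (3D arrays), `null_max` (length `n_perm`), `n_perm`, `df`.
#' @export
permutation_glm <- function(dataset, design, n_perm = 1000L,
                            params = tfce_params(), seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!design$group_col %in% colnames(design$X))
    stop("group column absent from design")
  x <- design$X
  y <- dataset$data[design$rows, , drop = FALSE]
  n <- nrow(x)
  gi <- match(design$group_col, colnames(x))
  z <- x[, -gi, drop = FALSE]
  g <- x[, gi]
  qz <- qr.Q(qr(z))
  gp <- g - qz %*% crossprod(qz, g)         # covariate-orthogonal group code
  gg <- sum(gp^2)
  if (gg < 1e-12) stop("group regressor is collinear with the covariates")
  e <- y - qz %*% crossprod(qz, y)          # reduced-model residuals
  df <- n - qr(x)$rank

  t_stat <- function(ep) {
    # ep: permuted residual matrix; re-residualize against covariates
    proj <- crossprod(qz, ep)
    a <- as.numeric(crossprod(gp, ep))
    ss <- colSums(ep^2) - colSums(proj^2)
    s2 <- pmax(ss - a^2 / gg, 0) / df
    a / gg / sqrt(pmax(s2 / gg, 1e-300))
  }

  mask <- dataset$mask
  t_obs <- t_stat(e)
  tfce_obs <- tfce(unmask_volume(t_obs, mask), params, two_tailed = TRUE)
  obs_enh <- abs(tfce_obs[mask])

  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(n)
    tp <- t_stat(e[perm, , drop = FALSE])
    max(abs(tfce(unmask_volume(tp, mask), params, two_tailed = TRUE)))
  }, numeric(1)))

  fwe_p <- vapply(obs_enh, function(v) (1 + sum(null_max >= v)) / (n_perm + 1),
                  numeric(1))
  structure(
    list(stat_map = unmask_volume(t_obs, mask),
         tfce_map = tfce_obs,
         fwe_p_map = unmask_volume(fwe_p, mask, fill = 1),
         null_max = null_max, n_perm = as.integer(n_perm), df = df,
         mask = mask),
    class = "voxel_inference")
}

#' @export
print.voxel_inference <- function(x, ...) {
  cat("voxel_inference:", sum(x$mask), "voxels,", x$n_perm, "permutations\n")
  cat("  min FWE p:", signif(min(x$fwe_p_map[x$mask]), 4),
      " significant voxels (p < 0.05):", sum(x$fwe_p_map[x$mask] < 0.05), "\n")
  invisible(x)
}

#' Write voxel inference maps as NIfTI plus the null distribution as TSV
#'
#' @param inference a `voxel_inference`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_voxel_inference <- function(inference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stat = file.path(dir, "stat.nii.gz"),
             tfce = file.path(dir, "tfce.nii.gz"),
             p = file.path(dir, "one_minus_fwe_p.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(inference$stat_map), paths["stat"])
  RNifti::writeNifti(RNifti::asNifti(inference$tfce_map), paths["tfce"])
  RNifti::writeNifti(RNifti::asNifti(1 - inference$fwe_p_map), paths["p"])
  np <- file.path(dir, "null_max.tsv")
  write.table(data.frame(null_max_tfce = inference$null_max), np,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, null = np))
}
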