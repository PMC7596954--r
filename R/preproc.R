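## separable 1D Gaussian convolution matrices with reflective boundary
gauss_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma))
  offs <- (-radius):radius
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + offs
    # edge-inclusive reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    for (j in seq_along(idx)) m[i, idx[j]] <- m[i, idx[j]] + w[j]
  }
  m
}

#' Smooth a 3D volume with an isotropic Gaussian kernel
#'
#' Separable convolution along each axis with reflective boundary handling,
#' so constant images are preserved exactly near edges.
#'
#' @param vol 3D numeric array.
#' @param sigma_vox Gaussian sigma per axis, in voxels (length 1 or 3).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (length(d) != 3L) stop("vol must be a 3D array")
  sigma_vox <- rep_len(sigma_vox, 3L)
  if (all(sigma_vox <= 0)) return(vol)
  # axis 1
  m1 <- gauss_band_matrix(d[1], sigma_vox[1])
  vol <- array(m1 %*% matrix(vol, d[1], d[2] * d[3]), dim = d)
  # axis 2
  m2 <- gauss_band_matrix(d[2], sigma_vox[2])
  vol <- aperm(array(m2 %*% matrix(aperm(vol, c(2, 1, 3)), d[2], d[1] * d[3]),
                     dim = d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  m3 <- gauss_band_matrix(d[3], sigma_vox[3])
  vol <- aperm(array(m3 %*% matrix(aperm(vol, c(3, 1, 2)), d[3], d[1] * d[2]),
                     dim = d[c(3, 1, 2)]), c(2, 3, 1))
  vol
}

#' Smooth every subject map with a Gaussian kernel given as FWHM
#'
#' Each subject's masked vector is placed back into the volume (zeros outside
#' the mask), smoothed with sigma in voxels equal to
#' `fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_size_mm)` per axis, and
#' re-vectorized under the mask. `fwhm_mm = 0` is the identity.
#'
#' @param dataset a [gm_dataset].
#' @param fwhm_mm full width at half maximum of the kernel, in millimetres.
#' @return A smoothed [gm_dataset].
#' @export
smooth_fwhm <- function(dataset, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(dataset)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2)) * dataset$voxel_size_mm)
  out <- dataset$data
  for (i in seq_len(nrow(out))) {
    vol <- unmask_volume(dataset$data[i, ], dataset$mask)
    out[i, ] <- smooth_volume(vol, sigma_vox)[dataset$mask]
  }
  dataset$data <- out
  dataset
}

#' Sample-homogeneity quality control
#'
#' Computes each subject's mean Pearson correlation with all other subjects'
#' masked maps and flags subjects whose mean correlation falls more than
#' `sd_mult` standard deviations below the sample mean. Subjects with a
#' constant (zero-variance) map have undefined correlations and are flagged
#' distinctly.
#'
#' @param dataset a [gm_dataset] with at least 3 subjects.
#' @param sd_mult flagging threshold in sample standard deviations (default 3).
#' @return data.frame with `subject_id`, `mean_correlation`, `flagged` and
#'   `note` ("ok", "low_correlation" or "undefined_correlation").
#' @export
homogeneity_qc <- function(dataset, sd_mult = 3) {
  n <- nrow(dataset$data)
  if (n < 3L) stop("homogeneity QC needs at least 3 subjects")
  sds <- apply(dataset$data, 1, sd)
  constant <- sds == 0
  cm <- suppressWarnings(cor(t(dataset$data)))
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  mean_cor[constant] <- NA_real_
  mu <- mean(mean_cor, na.rm = TRUE)
  s <- sd(mean_cor, na.rm = TRUE)
  low <- !is.na(mean_cor) & (mean_cor < mu - sd_mult * s)
  data.frame(
    subject_id = dataset$subject_ids,
    mean_correlation = mean_cor,
    flagged = low | constant,
    note = ifelse(constant, "undefined_correlation",
                  ifelse(low, "low_correlation", "ok")),
    stringsAsFactors = FALSE)
}
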