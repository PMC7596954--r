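#' Masked gray-matter density dataset
#'
#' Container for a participants-by-voxels matrix of masked gray-matter
#' densities together with the geometry needed to map rows back into volume
#' space. Voxels are ordered by the mask in column-major (R array) order.
#'
#' @param data numeric matrix, N subjects by V masked voxels.
#' @param mask 3D logical array; `sum(mask)` must equal `ncol(data)`.
#' @param voxel_size_mm numeric length-3 voxel dimensions in millimetres.
#' @param subject_ids character vector of length N.
#' @param affine 4x4 voxel-to-world transform (NIfTI convention).
#'
#' @return An object of class `gm_dataset`.
#' @export
gm_dataset <- function(data, mask, voxel_size_mm = c(2, 2, 2),
                       subject_ids = NULL, affine = NULL) {
  data <- as.matrix(data)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  v <- sum(mask)
  if (v == 0L) stop("mask contains no voxels")
  if (ncol(data) != v)
    stop("data has ", ncol(data), " columns but mask has ", v, " voxels")
  if (anyNA(data)) stop("NaN/NA values inside the mask")
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%03d", seq_len(nrow(data)))
  if (length(subject_ids) != nrow(data))
    stop("subject_ids length does not match number of rows")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(
    list(data = data, mask = mask, voxel_size_mm = as.numeric(voxel_size_mm),
         subject_ids = as.character(subject_ids), affine = affine),
    class = "gm_dataset")
}

#' @export
print.gm_dataset <- function(x, ...) {
  cat("gm_dataset:", nrow(x$data), "subjects x", ncol(x$data), "voxels\n")
  cat("  grid:", paste(dim(x$mask), collapse = " x "),
      " voxel size:", paste(x$voxel_size_mm, collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
dim.gm_dataset <- function(x) dim(x$data)

#' Re-insert a masked voxel vector into a 3D volume
#'
#' Voxels outside the mask are set to `fill` (default 0).
#'
#' @param values numeric vector of length `sum(mask)`.
#' @param mask 3D logical array.
#' @param fill value outside the mask.
#' @return 3D numeric array with the dimensions of `mask`.
#' @export
unmask_volume <- function(values, mask, fill = 0) {
  if (length(values) != sum(mask))
    stop("values length does not match mask voxel count")
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Extract masked voxels from a 3D volume
#' @param vol 3D numeric array.
#' @param mask 3D logical array of the same dimensions.
#' @return numeric vector of the voxels where `mask` is TRUE.
#' @export
mask_volume <- function(vol, mask) {
  if (!all(dim(vol) == dim(mask))) stop("volume/mask dimension mismatch")
  as.numeric(vol[mask])
}

#' Load a gray-matter dataset from NIfTI files
#'
#' Reads one NIfTI volume per subject, checks that every volume shares the
#' mask's grid and affine, and returns the masked, vectorized matrix in file
#' order.
#'
#' @param paths character vector of NIfTI file paths, one per subject.
#' @param mask_path path to the mask NIfTI (nonzero = inside).
#' @param subject_ids optional ids; defaults to file basenames.
#' @return A [gm_dataset].
#' @export
load_dataset <- function(paths, mask_path, subject_ids = NULL) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.array(mask_img) != 0, dim = dim(mask_img))
  if (length(dim(mask)) != 3L) stop("mask must be a 3D volume")
  if (sum(mask) == 0L) stop("mask contains no voxels: ", mask_path)
  aff_mask <- RNifti::xform(mask_img)
  vox <- RNifti::pixdim(mask_img)[1:3]
  n <- length(paths)
  out <- matrix(NA_real_, n, sum(mask))
  for (i in seq_len(n)) {
    img <- RNifti::readNifti(paths[[i]])
    if (!all(dim(img) == dim(mask)))
      stop("volume shape mismatch with mask: ", paths[[i]])
    if (max(abs(RNifti::xform(img) - aff_mask)) > 1e-4)
      stop("affine mismatch with mask: ", paths[[i]])
    vals <- as.array(img)[mask]
    if (anyNA(vals) || any(!is.finite(vals)))
      stop("non-finite voxels inside mask: ", paths[[i]])
    out[i, ] <- vals
  }
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  gm_dataset(out, mask, voxel_size_mm = vox, subject_ids = subject_ids,
             affine = aff_mask)
}

#' Write a gray-matter dataset as NIfTI volumes
#'
#' Writes one `.nii.gz` per subject plus `mask.nii.gz` into `dir`.
#'
#' @param dataset a [gm_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of subject file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- RNifti::asNifti(array(0, dim = dim(dataset$mask)))
  ref <- RNifti::`sform<-`(ref, structure(dataset$affine, code = 2L))
  paths <- file.path(dir, paste0(dataset$subject_ids, ".nii.gz"))
  for (i in seq_len(nrow(dataset$data))) {
    vol <- unmask_volume(dataset$data[i, ], dataset$mask)
    RNifti::writeNifti(RNifti::asNifti(vol, reference = ref), paths[i])
  }
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(
    RNifti::asNifti(array(as.numeric(dataset$mask), dim = dim(dataset$mask)),
                    reference = ref),
    mask_path)
  invisible(paths)
}
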