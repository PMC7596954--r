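## Laplace approximation to the PCA model evidence (Minka), evaluated on the
## eigenspectrum of the subject-space covariance; observations are voxels.
## The spectrum must already be truncated to its numerical rank: a
## (near-)zero tail eigenvalue corrupts the residual-variance term.
laplace_evidence <- function(spectrum, rank, n_samples) {
  n_features <- length(spectrum)
  if (rank >= n_features) return(-Inf)
  pu <- -rank * log(2)
  i <- seq_len(rank)
  pu <- pu + sum(lgamma((n_features - i + 1) / 2) -
                   ((n_features - i + 1) / 2) * log(pi))
  pl <- -sum(log(spectrum[seq_len(rank)])) * n_samples / 2
  v <- sum(spectrum[(rank + 1):length(spectrum)]) / (n_features - rank)
  if (v <= 0) return(-Inf)
  pv <- -log(v) * n_samples * (n_features - rank) / 2
  m <- n_features * rank - rank * (rank + 1) / 2
  pp <- log(2 * pi) * (m + rank) / 2
  spectrum_ <- spectrum
  spectrum_[(rank + 1):length(spectrum_)] <- v
  pa <- 0
  for (i in seq_len(rank)) {
    j <- (i + 1):length(spectrum)
    pa <- pa + sum(log((spectrum[i] - spectrum[j]) *
                         (1 / spectrum_[j] - 1 / spectrum_[i])) +
                     log(n_samples))
  }
  pu + pl + pv + pp - pa / 2 - rank * log(n_samples) / 2
}

#' Estimate the ICA model order from the data eigenspectrum
#'
#' `laplace` maximizes the Laplace approximation to the probabilistic-PCA
#' model evidence over the eigenspectrum of the subject-space covariance
#' (voxels as observations), the approach used by automatic dimensionality
#' estimation in group ICA tools. `variance_threshold` returns the smallest
#' order whose leading eigenvalues capture at least `variance_fraction` of
#' the total variance. Data are voxel-wise demeaned first; the spectrum is
#' truncated to its numerical rank before either rule is applied.
#'
#' @param dataset a [gm_dataset] with at least 10 subjects.
#' @param method `"laplace"` or `"variance_threshold"`.
#' @param variance_fraction retained-variance target for the threshold rule.
#' @return Integer model order in `[1, N - 1]`.
#' @export
estimate_order <- function(dataset, method = c("laplace", "variance_threshold"),
                           variance_fraction = 0.99) {
  method <- match.arg(method)
  x <- dataset$data
  n <- nrow(x)
  if (n < 10L) stop("order estimation needs at least 10 subjects")
  v <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(tcrossprod(xc) / v, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  rank_num <- sum(ev > ev[1] * 1e-10)
  ev_use <- ev[seq_len(rank_num)]
  if (method == "variance_threshold") {
    frac <- cumsum(ev_use) / sum(ev)
    d <- which(frac >= variance_fraction)[1]
    if (is.na(d)) d <- rank_num
  } else {
    kmax <- min(rank_num - 1L, n - 1L)
    if (kmax < 1L) return(1L)
    ll <- vapply(seq_len(kmax), function(k)
      laplace_evidence(ev_use, k, n_samples = v), numeric(1))
    d <- which.max(ll)
  }
  as.integer(min(max(d, 1L), n - 1L))
}

## one FastICA run: symmetric fixed-point with log-cosh contrast on whitened
## spatial data z (d x V); returns unmixing matrix plus convergence record
fastica_run <- function(z, tol, max_iter) {
  d <- nrow(z)
  v <- ncol(z)
  w <- matrix(rnorm(d * d), d, d)
  sv <- svd(w)
  w <- sv$u %*% t(sv$v)
  lim <- Inf
  it <- 0L
  while (it < max_iter && lim > tol) {
    it <- it + 1L
    u <- w %*% z
    g <- tanh(u)
    gp <- rowMeans(1 - g^2)
    w1 <- tcrossprod(g, z) / v - diag(gp, d) %*% w
    sv <- svd(w1)
    w1 <- sv$u %*% t(sv$v)
    lim <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
  }
  s <- w %*% z
  contrast <- sum((rowMeans(log(cosh(s))) - .logcosh_gauss)^2)
  list(w = w, iterations = it, final_tol = lim,
       converged = lim <= tol, contrast = contrast)
}

#' Source-based morphometry decomposition by spatial ICA
#'
#' Voxel-wise demeans the subject-by-voxel matrix, PCA-whitens it to `order`
#' dimensions, and runs fixed-point ICA (symmetric decorrelation, log-cosh
#' contrast) over the spatial dimension, so that component maps are
#' independent across voxels and each component carries one loading per
#' participant. The best of `n_restarts` randomly initialized runs by final
#' contrast value is kept. Each component's sign is canonicalized so its
#' spatial skewness is positive, and sources are z-scored for reporting;
#' `loadings %*% sources` plus the stored offsets reconstructs the whitened
#' subspace projection exactly (see [reconstruct_sbm]).
#'
#' @param dataset a [gm_dataset].
#' @param order number of components, in `[1, min(N, V)]` (`order = 1` is
#'   the degenerate one-component limit, a pure PCA projection).
#' @param n_restarts random restarts (best kept).
#' @param seed RNG seed; the decomposition is deterministic given it.
#' @param tol convergence tolerance on the unmixing update.
#' @param max_iter maximum fixed-point iterations per restart.
#' @param variance_normalize z-score voxel columns (instead of demeaning
#'   only) before whitening.
#' @return Object of class `sbm_ica` with `sources` (d x V, z-scored),
#'   `loadings` (N x d), `order`, `explained_variance`, `convergence` (one
#'   record per restart), `seed`, and reconstruction offsets.
#' @export
sbm_decompose <- function(dataset, order, n_restarts = 5L, seed = 1L,
                          tol = 1e-6, max_iter = 1000L,
                          variance_normalize = FALSE) {
  x <- dataset$data
  n <- nrow(x)
  v <- ncol(x)
  if (order < 1L || order > min(n, v))
    stop("order must lie in [1, min(N, V)]")
  col_mu <- colMeans(x)
  xc <- sweep(x, 2, col_mu)
  if (variance_normalize) {
    s <- apply(xc, 2, sd)
    s[s == 0] <- 1
    xc <- sweep(xc, 2, s, "/")
  }
  eg <- eigen(tcrossprod(xc) / v, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (ev[order] <= ev[1] * 1e-12)
    stop("data rank below requested order; reduce `order`")
  e_d <- eg$vectors[, seq_len(order), drop = FALSE]
  d_d <- ev[seq_len(order)]
  k_white <- sweep(t(e_d), 1, sqrt(d_d), "/")     # d x N
  z <- k_white %*% xc                              # whitened spatial data
  explained <- sum(d_d) / sum(ev)

  runs <- with_seed(seed, lapply(seq_len(n_restarts), function(r)
    fastica_run(z, tol, max_iter)))
  conv <- lapply(seq_along(runs), function(r)
    c(restart = r, runs[[r]][c("iterations", "final_tol", "converged",
                               "contrast")]))
  ok <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(ok)) {
    cond <- simpleError("ICA did not converge in any restart")
    cond$convergence <- conv
    stop(cond)
  }
  best <- which.max(vapply(runs, function(r)
    if (r$converged) r$contrast else -Inf, numeric(1)))
  w <- runs[[best]]$w
  s_raw <- w %*% z                                  # d x V, unit-variance rows
  a <- e_d %*% diag(sqrt(d_d), order) %*% t(w)      # N x d mixing (loadings)

  # sign convention: positive spatial skewness per component
  sk <- apply(s_raw, 1, function(r) mean((r - mean(r))^3) / (sd(r)^3 + 1e-30))
  flip <- ifelse(sk < 0, -1, 1)
  s_raw <- s_raw * flip
  a <- sweep(a, 2, flip, "*")

  src_mu <- rowMeans(s_raw)
  src_sd <- apply(s_raw, 1, sd)
  sources <- sweep(sweep(s_raw, 1, src_mu), 1, src_sd, "/")
  loadings <- sweep(a, 2, src_sd, "*")
  mean_offset <- as.numeric(a %*% src_mu)
  colnames(loadings) <- sprintf("IC%02d", seq_len(order))

  structure(
    list(sources = sources, loadings = loadings, order = as.integer(order),
         explained_variance = explained, convergence = conv,
         seed = as.integer(seed), mean_offset = mean_offset,
         voxel_means = col_mu, mask = dataset$mask,
         subject_ids = dataset$subject_ids, best_restart = best),
    class = "sbm_ica")
}

#' @export
print.sbm_ica <- function(x, ...) {
  cat("sbm_ica: order", x$order, "on", nrow(x$loadings), "subjects,",
      ncol(x$sources), "voxels\n")
  cat("  explained variance (whitening):",
      sprintf("%.3f", x$explained_variance), "\n")
  invisible(x)
}

#' Reconstruct the whitened-subspace projection of the data
#'
#' Returns `loadings %*% sources` plus the stored per-subject and per-voxel
#' offsets; equals the rank-`order` PCA projection of the input matrix.
#'
#' @param decomposition an `sbm_ica` object.
#' @return N x V numeric matrix.
#' @export
reconstruct_sbm <- function(decomposition) {
  d <- decomposition
  d$loadings %*% d$sources + d$mean_offset +
    matrix(d$voxel_means, nrow(d$loadings), length(d$voxel_means), byrow = TRUE)
}

#' Match components across two decompositions by spatial correlation
#'
#' Greedy one-to-one assignment maximizing total absolute spatial
#' correlation: the largest remaining |r| entry is matched first, then its
#' row and column are removed. Pairs with |r| below `min_abs_r` are reported
#' unmatched.
#'
#' @param a,b `sbm_ica` objects (or source matrices) over the same voxels.
#' @param min_abs_r minimum absolute spatial correlation for a match.
#' @return List with `pairs` (data.frame: `a`, `b`, `abs_r`) and `unmatched`
#'   (list of leftover indices per side).
#' @export
match_components <- function(a, b, min_abs_r = 0.5) {
  sa <- if (inherits(a, "sbm_ica")) a$sources else as.matrix(a)
  sb <- if (inherits(b, "sbm_ica")) b$sources else as.matrix(b)
  if (ncol(sa) != ncol(sb))
    stop("decompositions have different voxel counts: ",
         ncol(sa), " vs ", ncol(sb))
  r <- abs(cor(t(sa), t(sb)))
  pairs <- data.frame(a = integer(0), b = integer(0), abs_r = numeric(0))
  avail_a <- rep(TRUE, nrow(r))
  avail_b <- rep(TRUE, ncol(r))
  repeat {
    sub <- r
    sub[!avail_a, ] <- -Inf
    sub[, !avail_b] <- -Inf
    best <- which.max(sub)
    if (length(best) == 0 || !is.finite(sub[best]) || sub[best] < min_abs_r)
      break
    ij <- arrayInd(best, dim(r))
    pairs <- rbind(pairs, data.frame(a = ij[1], b = ij[2], abs_r = r[best]))
    avail_a[ij[1]] <- FALSE
    avail_b[ij[2]] <- FALSE
    if (!any(avail_a) || !any(avail_b)) break
  }
  list(pairs = pairs,
       unmatched = list(a = which(avail_a), b = which(avail_b)))
}

#' Write an ICA decomposition to disk
#'
#' Sources as a 4D NIfTI (one volume per component), loadings as TSV
#' (`subject_id` + one column per component), convergence log as JSON.
#' Optionally writes display-thresholded maps with `|Z|` banded into
#' `[lo, hi]` (values below `lo` zeroed, above `hi` clamped).
#'
#' @param decomposition an `sbm_ica`.
#' @param dir output directory.
#' @param threshold optional length-2 `c(lo, hi)` display band, e.g. `c(3, 5)`.
#' @return Invisibly, the paths written.
#' @export
write_sbm <- function(decomposition, dir, threshold = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- decomposition
  grid <- dim(d$mask)
  arr <- array(0, dim = c(grid, d$order))
  for (k in seq_len(d$order))
    arr[, , , k] <- unmask_volume(d$sources[k, ], d$mask)
  src_path <- file.path(dir, "sources.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), src_path)
  paths <- src_path
  if (!is.null(threshold)) {
    thr <- arr
    thr[abs(thr) < threshold[1]] <- 0
    thr[thr > threshold[2]] <- threshold[2]
    thr[thr < -threshold[2]] <- -threshold[2]
    tp <- file.path(dir, "sources_thresholded.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(thr), tp)
    paths <- c(paths, tp)
  }
  lt <- data.frame(subject_id = d$subject_ids, d$loadings,
                   stringsAsFactors = FALSE)
  lp <- file.path(dir, "loadings.tsv")
  write.table(lt, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- file.path(dir, "convergence.json")
  jsonlite::write_json(d$convergence, cp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, lp, cp))
}
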