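## rank-truncated SVD basis of a z-scored matrix; returns orthonormal basis
## U (N x r), plus the map from basis coordinates to variable weights
svd_basis <- function(m, tol = 1e-10) {
  s <- svd(m)
  r <- sum(s$d > s$d[1] * tol)
  list(u = s$u[, seq_len(r), drop = FALSE],
       v = s$v[, seq_len(r), drop = FALSE],
       d = s$d[seq_len(r)], rank = r)
}

#' Canonical correlation analysis between loadings and behavior scores
#'
#' Columns of both sets are z-scored, rows with any missing value in either
#' set are dropped first, and the canonical system is solved through the SVD
#' of the whitened cross-covariance (rank-truncated, so collinear columns
#' are handled by pseudo-inverse). Canonical variates are scaled to unit
#' variance. When `N <= ncol(x)` the fit is exactly collinear and a warning
#' about overfit is issued.
#'
#' @param x N x px numeric matrix (e.g. component loadings).
#' @param y N x py numeric matrix (e.g. symptom scores; NA rows dropped).
#' @return Object of class `cca_result`: `correlations` (non-increasing, in
#'   `[0, 1]`), `x_weights`, `y_weights` (columns give each mode's raw
#'   canonical coefficients on the z-scored variables), `x_variates`,
#'   `y_variates` (unit variance), `n_modes = min(px, py)`,
#'   `bonferroni_alpha = 0.05 / n_modes`, `n` (complete cases used),
#'   `complete` (logical row filter).
#' @export
fit_cca <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  cc <- complete.cases(x) & complete.cases(y)
  xs <- x[cc, , drop = FALSE]
  ys <- y[cc, , drop = FALSE]
  n <- nrow(xs)
  if (n < 3L) stop("need at least 3 complete cases")
  if (is.null(colnames(xs))) colnames(xs) <- sprintf("x%d", seq_len(ncol(xs)))
  if (is.null(colnames(ys))) colnames(ys) <- sprintf("y%d", seq_len(ncol(ys)))
  xz <- zscore_cols(xs, strict = TRUE, what = "x")
  yz <- zscore_cols(ys, strict = TRUE, what = "y")
  if (n <= ncol(xz))
    warning("N <= number of x variables: canonical correlations are ",
            "degenerate (overfit); interpret with caution")
  bx <- svd_basis(xz)
  by <- svd_basis(yz)
  m <- crossprod(bx$u, by$u)
  sv <- svd(m)
  k <- min(bx$rank, by$rank)
  r <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  # weights on z-scored variables; variates have unit variance
  wx <- bx$v %*% (sv$u[, seq_len(k), drop = FALSE] / bx$d) * sqrt(n - 1)
  wy <- by$v %*% (sv$v[, seq_len(k), drop = FALSE] / by$d) * sqrt(n - 1)
  xv <- bx$u %*% sv$u[, seq_len(k), drop = FALSE] * sqrt(n - 1)
  yv <- by$u %*% sv$v[, seq_len(k), drop = FALSE] * sqrt(n - 1)
  rownames(wx) <- colnames(xs)
  rownames(wy) <- colnames(ys)
  n_modes <- min(ncol(xz), ncol(yz))
  structure(
    list(correlations = r, x_weights = wx, y_weights = wy,
         x_variates = xv, y_variates = yv,
         n_modes = n_modes, bonferroni_alpha = 0.05 / n_modes,
         n = n, complete = cc,
         x_names = colnames(xs), y_names = colnames(ys)),
    class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result:", x$n, "complete cases,", x$n_modes, "modes",
      "(bonferroni alpha", signif(x$bonferroni_alpha, 3), ")\n")
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n")
  if (!is.null(x$perm_p))
    cat("  main-mode permutation p:", signif(x$perm_p, 4),
        "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Corrected (structure) canonical coefficients
#'
#' Raw canonical coefficients are unstable under collinearity; for
#' interpretation each variable's contribution to a mode is expressed as the
#' correlation between that variable and the mode's canonical variate from
#' its own set (structure-coefficient form). Ranking variables by the
#' absolute corrected coefficient of the main mode drives reporting.
#'
#' @param result a fitted `cca_result`.
#' @param x,y the matrices passed to [fit_cca].
#' @return The result with `x_corrected` and `y_corrected` (variables x
#'   modes) added.
#' @export
correct_coefficients <- function(result, x, y) {
  cc <- result$complete
  xs <- as.matrix(x)[cc, , drop = FALSE]
  ys <- as.matrix(y)[cc, , drop = FALSE]
  result$x_corrected <- cor(xs, result$x_variates)
  result$y_corrected <- cor(ys, result$y_variates)
  rownames(result$x_corrected) <- result$x_names
  rownames(result$y_corrected) <- result$y_names
  result
}

#' Permutation test of the main CCA mode
#'
#' Rows of `y` are permuted `n_perm` times; for each permutation the first
#' canonical correlation is recomputed, and the main-mode p value is
#' `(1 + #(r_perm >= r_obs)) / (n_perm + 1)`. Significance is declared
#' against the Bonferroni level `0.05 / n_modes`.
#'
#' @param x,y matrices as in [fit_cca] (complete cases used).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `perm_p`, `r_obs`, `null` (permutation distribution of
#'   the first canonical correlation), `n_perm`, `n_modes`,
#'   `bonferroni_alpha`, `significant`.
#' @export
cca_permutation_test <- function(x, y, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  x <- as.matrix(x)
  y <- as.matrix(y)
  cc <- complete.cases(x) & complete.cases(y)
  xz <- zscore_cols(x[cc, , drop = FALSE], strict = TRUE, what = "x")
  yz <- zscore_cols(y[cc, , drop = FALSE], strict = TRUE, what = "y")
  n <- nrow(xz)
  bx <- svd_basis(xz)
  by <- svd_basis(yz)
  first_r <- function(uy) min(1, svd(crossprod(bx$u, uy))$d[1])
  r_obs <- first_r(by$u)
  # permuting rows of y permutes the rows of its orthonormal basis, so the
  # SVD of y need not be recomputed per permutation
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    first_r(by$u[sample.int(n), , drop = FALSE]), numeric(1)))
  n_modes <- min(ncol(xz), ncol(yz))
  p <- (1 + sum(null >= r_obs)) / (n_perm + 1)
  list(perm_p = p, r_obs = r_obs, null = null, n_perm = as.integer(n_perm),
       n_modes = n_modes, bonferroni_alpha = 0.05 / n_modes,
       significant = p < 0.05 / n_modes)
}

## sign-aligned correlation of a refit main-mode weight vector with the
## full-sample one
aligned_weight_cor <- function(w_ref, w_new) {
  if (length(w_new) != length(w_ref)) return(NA_real_)
  r <- suppressWarnings(cor(w_ref, w_new))
  if (is.na(r)) return(NA_real_)
  abs(r)
}

#' Leave-one-out stability of the main CCA mode
#'
#' Refits the CCA with each subject left out, sign-aligns the main-mode
#' weight vectors to the full-sample ones, and records the correlation of
#' weight vectors for the x and y sets separately. Folds whose refit fails
#' are flagged and excluded from the summary with a warning.
#'
#' @param x,y matrices as in [fit_cca] (complete cases used; N >= 10).
#' @return Object of class `stability_report`: `loo_weight_corr_x`,
#'   `loo_weight_corr_y` (per-fold), `mean_x`, `mean_y`, `failed_folds`.
#' @export
loo_stability <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  cc <- complete.cases(x) & complete.cases(y)
  xs <- x[cc, , drop = FALSE]
  ys <- y[cc, , drop = FALSE]
  n <- nrow(xs)
  if (n < 10L) stop("leave-one-out stability needs at least 10 complete cases")
  full <- fit_cca(xs, ys)
  wx <- full$x_weights[, 1]
  wy <- full$y_weights[, 1]
  rx <- ry <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(fit_cca(xs[-i, , drop = FALSE], ys[-i, , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(fit_i)) {
      failed <- c(failed, i)
      next
    }
    rx[i] <- aligned_weight_cor(wx, fit_i$x_weights[, 1])
    ry[i] <- aligned_weight_cor(wy, fit_i$y_weights[, 1])
  }
  if (length(failed))
    warning(length(failed), " leave-one-out folds failed to refit and were ",
            "excluded from the summary")
  structure(
    list(loo_weight_corr_x = rx, loo_weight_corr_y = ry,
         mean_x = mean(rx, na.rm = TRUE), mean_y = mean(ry, na.rm = TRUE),
         failed_folds = failed, n = n),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report: N =", x$n, "\n")
  cat("  mean LOO weight correlation: x", sprintf("%.3f", x$mean_x),
      " y", sprintf("%.3f", x$mean_y), "\n")
  invisible(x)
}

#' Subsampling reproducibility curve of the main CCA mode
#'
#' For each requested sample size, draws `n_draws` random subsets, refits
#' the CCA, and records the sign-aligned correlation of the main-mode x
#' weights with the full-sample weights. Sizes at or below
#' `max(px, py)` are ill-posed (the fit is rank-degenerate); they are
#' flagged but still attempted through the rank-truncated pseudo-inverse
#' solver.
#'
#' @param x,y matrices as in [fit_cca].
#' @param sizes integer vector of subsample sizes (each <= N).
#' @param n_draws random draws per size.
#' @param seed RNG seed.
#' @return data.frame with `size`, `mean_r`, `sd_r`, `se_r`, `n_draws`,
#'   `ill_posed`.
#' @export
subsample_reproducibility <- function(x, y, sizes, n_draws = 20L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  cc <- complete.cases(x) & complete.cases(y)
  xs <- x[cc, , drop = FALSE]
  ys <- y[cc, , drop = FALSE]
  n <- nrow(xs)
  if (any(sizes > n)) stop("subsample sizes must not exceed N = ", n)
  full <- fit_cca(xs, ys)
  wx <- full$x_weights[, 1]
  res <- with_seed(seed, lapply(sizes, function(sz) {
    rs <- vapply(seq_len(n_draws), function(d) {
      idx <- if (sz == n) seq_len(n) else sample.int(n, sz)
      fit_d <- tryCatch(
        suppressWarnings(fit_cca(xs[idx, , drop = FALSE],
                                 ys[idx, , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(fit_d)) return(NA_real_)
      aligned_weight_cor(wx, fit_d$x_weights[, 1])
    }, numeric(1))
    c(mean_r = mean(rs, na.rm = TRUE), sd_r = sd(rs, na.rm = TRUE),
      se_r = sd(rs, na.rm = TRUE) / sqrt(sum(!is.na(rs))))
  }))
  out <- data.frame(size = sizes, do.call(rbind, res),
                    n_draws = n_draws,
                    ill_posed = sizes <= max(ncol(xs), ncol(ys)))
  out
}

#' Write CCA results: per-mode JSON, weight tables, main-mode scatter data
#'
#' @param result a `cca_result`, ideally after [correct_coefficients] and
#'   with `perm_p`/`n_perm` fields attached.
#' @param dir output directory.
#' @param color optional per-subject vector (complete cases) written with
#'   the scatter data to color-code the main mode, e.g. a symptom score.
#' @return Invisibly, the written paths.
#' @export
write_cca <- function(result, dir, color = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, "modes.json")
  jsonlite::write_json(
    list(correlations = result$correlations, n = result$n,
         n_modes = result$n_modes,
         bonferroni_alpha = result$bonferroni_alpha,
         perm_p = result$perm_p, n_perm = result$n_perm),
    jp, auto_unbox = TRUE, digits = NA, na = "null")
  wt <- data.frame(variable = c(result$x_names, result$y_names),
                   set = rep(c("x", "y"),
                             c(length(result$x_names), length(result$y_names))),
                   raw_weight = c(result$x_weights[, 1], result$y_weights[, 1]))
  if (!is.null(result$x_corrected))
    wt$corrected <- c(result$x_corrected[, 1], result$y_corrected[, 1])
  wp <- file.path(dir, "weights.tsv")
  write.table(wt, wp, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- data.frame(x_variate = result$x_variates[, 1],
                   y_variate = result$y_variates[, 1])
  if (!is.null(color)) sc$color <- color
  sp <- file.path(dir, "main_mode_scatter.tsv")
  write.table(sc, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jp, wp, sp))
}
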