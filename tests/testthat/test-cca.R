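test_that("canonical correlations match the closed form and an established solver", {
  set.seed(1)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- matrix(rnorm(50 * 4), 50, 4)
  fit <- fit_cca(x, y)

  # closed form: sqrt of eigenvalues of Sxx^-1 Sxy Syy^-1 Syx
  xz <- scale(x); yz <- scale(y)
  m <- solve(cov(xz)) %*% cov(xz, yz) %*% solve(cov(yz)) %*% cov(yz, xz)
  lam <- sort(Re(eigen(m)$values), decreasing = TRUE)
  expect_equal(fit$correlations, sqrt(lam[1:4]), tolerance = 1e-8)

  # established implementation agrees on correlations, weights up to sign/scale
  cc <- cancor(scale(x, scale = FALSE), scale(y, scale = FALSE))
  expect_equal(fit$correlations, cc$cor, tolerance = 1e-6)
  for (k in 1:4)
    expect_gt(abs(cor(fit$y_weights[, k] / apply(y, 2, sd),
                      cc$ycoef[, k])), 1 - 1e-6)

  # structural properties: sorted correlations, unit-variance orthogonal variates
  expect_true(all(diff(fit$correlations) <= 1e-12))
  expect_true(all(fit$correlations >= 0 & fit$correlations <= 1))
  expect_equal(unname(apply(fit$x_variates, 2, var)), rep(1, 4),
               tolerance = 1e-8)
  cx <- crossprod(scale(fit$x_variates, scale = FALSE)) / 49
  expect_lt(max(abs(cx - diag(4))), 1e-8)
  expect_equal(unname(diag(cor(fit$x_variates, fit$y_variates))),
               fit$correlations, tolerance = 1e-8)

  # affine rescaling of any column leaves correlations unchanged
  x2 <- x
  x2[, 3] <- -7 * x2[, 3] + 100
  y2 <- y
  y2[, 1] <- 0.01 * y2[, 1] - 2
  expect_equal(fit_cca(x2, y2)$correlations, fit$correlations,
               tolerance = 1e-8)
})

test_that("identity, mode counts and error paths behave as specified", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(fit_cca(x, x)$correlations, rep(1, 3), tolerance = 1e-10)

  y5 <- matrix(rnorm(40 * 5), 40, 5)
  fit <- fit_cca(y5, x)
  expect_equal(fit$n_modes, 3L)
  expect_equal(fit$bonferroni_alpha, 0.05 / 3)

  xz <- x
  xz[, 2] <- 4
  expect_error(fit_cca(xz, y5), "zero-variance column in x: x2")
  colnames(xz) <- c("a", "const", "c")
  expect_error(fit_cca(xz, y5), "const")
  expect_warning(fit_cca(matrix(rnorm(5 * 6), 5, 6), matrix(rnorm(5 * 2), 5, 2)),
                 "overfit")
})

test_that("corrected coefficients are structure correlations", {
  set.seed(3)
  n <- 200
  u <- rnorm(n)
  # single informative column in near-orthonormal x
  x <- cbind(u + rnorm(n, sd = 0.1), matrix(rnorm(n * 3), n, 3))
  y <- cbind(u + rnorm(n, sd = 0.1), rnorm(n))
  fit <- correct_coefficients(fit_cca(x, y), x, y)
  expect_equal(dim(fit$x_corrected), c(4L, 2L))
  # corrected = correlation between variable and its own-set variate
  expect_equal(unname(fit$x_corrected[, 1]),
               unname(cor(x, fit$x_variates[, 1])[, 1]), tolerance = 1e-10)
  expect_equal(unname(which.max(abs(fit$x_corrected[, 1]))), 1L)

  # raw weights split arbitrarily over collinear twins; corrected ones agree
  xc <- cbind(u, u, matrix(rnorm(n * 2), n, 2))
  fitc <- correct_coefficients(suppressWarnings(fit_cca(xc, y)), xc, y)
  expect_equal(fitc$x_corrected[1, 1], fitc$x_corrected[2, 1],
               tolerance = 1e-10)

  # flipping a variate flips its corrected coefficients consistently
  flipped <- fit
  flipped$x_variates[, 1] <- -flipped$x_variates[, 1]
  flipped$y_variates[, 1] <- -flipped$y_variates[, 1]
  refl <- correct_coefficients(flipped, x, y)
  expect_equal(refl$x_corrected[, 1], -fit$x_corrected[, 1], tolerance = 1e-12)
  expect_equal(refl$y_corrected[, 1], -fit$y_corrected[, 1], tolerance = 1e-12)
})

test_that("permutation test honors its floor and detects a planted mode", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3)
  pt <- cca_permutation_test(x, x, n_perm = 200, seed = 1)
  expect_equal(pt$perm_p, 1 / 201)

  sim <- simulate_planted_cca(n = 300, px = 20, py = 5, r0 = 0.7, seed = 5)
  pt2 <- cca_permutation_test(sim$x, sim$y, n_perm = 500, seed = 2)
  expect_lt(pt2$perm_p, 0.05 / 5)
  expect_true(pt2$significant)
  expect_equal(pt2$n_modes, 5L)

  # permutation distribution is a valid null: same-seed reproducibility
  pt3 <- cca_permutation_test(sim$x, sim$y, n_perm = 500, seed = 2)
  expect_identical(pt2$null, pt3$null)
  expect_error(cca_permutation_test(x, x, n_perm = 10), "at least 100")
})

test_that("leave-one-out weights are stable under signal, unstable under noise", {
  sim <- simulate_planted_cca(n = 300, px = 20, py = 5, r0 = 0.7, seed = 6)
  st <- loo_stability(sim$x, sim$y)
  expect_gte(st$mean_x, 0.9)
  expect_gte(st$mean_y, 0.9)
  expect_true(all(st$loo_weight_corr_x >= -1 & st$loo_weight_corr_x <= 1,
                  na.rm = TRUE))

  # overfit regime: pure noise with px close to N
  set.seed(7)
  xn <- matrix(rnorm(60 * 50), 60, 50)
  yn <- matrix(rnorm(60 * 50), 60, 50)
  st_noise <- suppressWarnings(loo_stability(xn, yn))
  expect_gte(st$mean_x - st_noise$mean_x, 0.3)

  # exact linear relation at minimal N: every fold correlates perfectly
  set.seed(8)
  x2 <- matrix(rnorm(10 * 2), 10, 2)
  st_exact <- loo_stability(x2, x2 %*% matrix(c(1, 0.5, -0.5, 2), 2))
  expect_equal(st_exact$loo_weight_corr_x, rep(1, 10), tolerance = 1e-6)
  expect_error(loo_stability(x2[1:5, ], x2[1:5, ]), "at least 10")
})

test_that("subsampling reproducibility grows with sample size", {
  sim <- simulate_planted_cca(n = 250, px = 10, py = 4, r0 = 0.7, seed = 9)
  curve <- subsample_reproducibility(sim$x, sim$y, sizes = c(8, 60, 250),
                                     n_draws = 10, seed = 1)
  expect_equal(curve$mean_r[curve$size == 250], 1)  # full sample by construction
  expect_true(curve$ill_posed[curve$size == 8])
  expect_false(curve$ill_posed[curve$size == 60])
  expect_true(all(diff(curve$mean_r) >= -0.05))
  expect_error(subsample_reproducibility(sim$x, sim$y, sizes = 500), "exceed")
})
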