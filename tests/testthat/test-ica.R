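test_that("order estimation recovers exact rank and planted dimensionality", {
  ph <- small_phantom(seed = 5, n = 50, k = 2, noise_sd = 0,
                      group_effect = list())
  expect_equal(estimate_order(ph$dataset, "variance_threshold",
                              variance_fraction = 0.999), 2L)

  # planted K = 10 at moderate noise: Laplace evidence lands near 10
  hits <- vapply(1:5, function(s) {
    ph10 <- generate_phantom(phantom_spec(n_subjects = 200, n_sources = 10,
                                          seed = 500 + s))
    estimate_order(ph10$dataset, "laplace")
  }, integer(1))
  expect_true(all(hits >= 8 & hits <= 12))

  # pure white noise: no structure, estimate stays small
  noise_hits <- vapply(1:5, function(s) {
    set.seed(600 + s)
    ds <- gm_dataset(matrix(rnorm(100 * 2000), 100, 2000),
                     array(TRUE, c(10, 20, 10)))
    estimate_order(ds, "laplace")
  }, integer(1))
  expect_true(all(noise_hits <= 3))

  expect_error(estimate_order(small_phantom(n = 5, k = 2)$dataset),
               "at least 10")
})

test_that("decomposition recovers planted sources and is deterministic", {
  ph <- generate_phantom(phantom_spec(n_subjects = 120, n_sources = 5,
                                      noise_sd = 0.1, seed = 31))
  dec <- sbm_decompose(ph$dataset, order = 5, n_restarts = 3, seed = 2)
  m <- match_components(dec, ph$truth$true_sources)
  expect_equal(nrow(m$pairs), 5L)
  expect_true(all(m$pairs$abs_r >= 0.95))

  # z-scored sources; finite loadings
  expect_equal(unname(rowMeans(dec$sources)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(dec$sources, 1, sd)), rep(1, 5), tolerance = 1e-10)
  expect_true(all(is.finite(dec$loadings)))
  # positive spatial skewness sign convention
  skew <- apply(dec$sources, 1, function(r) mean(r^3))
  expect_true(all(skew > 0))

  dec2 <- sbm_decompose(ph$dataset, order = 5, n_restarts = 3, seed = 2)
  expect_identical(dec$sources, dec2$sources)
  expect_identical(dec$loadings, dec2$loadings)

  # different seeds agree after matching (well-conditioned phantom)
  dec3 <- sbm_decompose(ph$dataset, order = 5, n_restarts = 3, seed = 99)
  m2 <- match_components(dec, dec3)
  expect_true(all(m2$pairs$abs_r >= 0.99))
})

test_that("one-component limit recovers a single planted source", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(12, 12, 12),
                                      n_subjects = 60, n_sources = 1,
                                      noise_sd = 0.02, group_effect = list(),
                                      seed = 8))
  dec <- sbm_decompose(ph$dataset, order = 1, n_restarts = 2, seed = 1)
  r <- cor(dec$sources[1, ], ph$truth$true_sources[1, ])
  expect_gte(abs(r), 0.999)
})

test_that("whitened reconstruction error equals the PCA truncation error", {
  ph <- small_phantom(seed = 13, n = 40, k = 3, noise_sd = 0.2)
  x <- ph$dataset$data
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(tcrossprod(xc) / ncol(xc), symmetric = TRUE,
              only.values = TRUE)$values
  dec <- sbm_decompose(ph$dataset, order = 3, n_restarts = 2, seed = 4)
  resid <- x - reconstruct_sbm(dec)
  expect_equal(sum(resid^2), ncol(xc) * sum(ev[4:length(ev)]),
               tolerance = 1e-8)
})

test_that("decomposition agrees with an established ICA implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  ph <- generate_phantom(phantom_spec(grid_shape = c(12, 12, 12),
                                      n_subjects = 60, n_sources = 3,
                                      noise_sd = 0.1, seed = 17))
  dec <- sbm_decompose(ph$dataset, order = 3, n_restarts = 3, seed = 5)
  td <- withr::local_tempdir()
  xp <- file.path(td, "x.csv")
  sp <- file.path(td, "s.csv")
  write.table(ph$dataset$data, xp, sep = ",", row.names = FALSE,
              col.names = FALSE)
  script <- file.path(td, "run_ica.py")
  writeLines(c(
    "import numpy as np, sys",
    "from sklearn.decomposition import FastICA",
    sprintf("x = np.loadtxt('%s', delimiter=',')", xp),
    "x = x - x.mean(axis=0)",
    "ica = FastICA(n_components=3, whiten='unit-variance', random_state=0,",
    "              max_iter=1000, tol=1e-6)",
    "s = ica.fit_transform(x.T).T   # spatial sources",
    sprintf("np.savetxt('%s', s, delimiter=',')", sp)), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  skip_if(status != 0, "scikit-learn unavailable")
  s_ref <- as.matrix(read.table(sp, sep = ","))
  m <- match_components(dec, s_ref)
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$abs_r >= 0.95))
})

test_that("component matching resolves permutation and sign ambiguity", {
  ph <- small_phantom(seed = 23, n = 50, k = 4, noise_sd = 0.1)
  dec <- sbm_decompose(ph$dataset, order = 4, n_restarts = 2, seed = 3)

  m_self <- match_components(dec, dec)
  expect_equal(m_self$pairs$abs_r, rep(1, 4), tolerance = 1e-12)
  expect_equal(m_self$pairs$a, m_self$pairs$b)

  perm <- c(3, 1, 4, 2)
  flip <- c(1, -1, -1, 1)
  shuffled <- dec
  shuffled$sources <- dec$sources[perm, ] * flip
  m_perm <- match_components(dec, shuffled)
  expect_equal(m_perm$pairs$abs_r, rep(1, 4), tolerance = 1e-12)
  recovered <- m_perm$pairs$b[order(m_perm$pairs$a)]
  expect_equal(perm[recovered], 1:4)

  expect_error(match_components(dec$sources, dec$sources[, 1:10]),
               "voxel counts")
})

test_that("order bounds and rank deficiencies are rejected", {
  ph <- small_phantom(seed = 2, n = 20, k = 2, noise_sd = 0)
  expect_error(sbm_decompose(ph$dataset, order = 0), "order")
  expect_error(sbm_decompose(ph$dataset, order = 21), "order")
  # noiseless rank-2 data cannot support order 5
  expect_error(sbm_decompose(ph$dataset, order = 5), "rank")
})
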