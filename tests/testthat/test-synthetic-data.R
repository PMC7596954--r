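test_that("noiseless phantom mixtures have exact source rank and reconstruct", {
  ph <- small_phantom(seed = 5, n = 50, k = 2, noise_sd = 0,
                      group_effect = list())
  x <- ph$dataset$data
  sv <- svd(x)$d
  expect_equal(qr(x)$rank, 2L)
  expect_lt(sv[3] / sv[1], 1e-12)
  # emitted = loadings x sources exactly (clipping inactive by construction)
  recon <- ph$truth$true_loadings %*% ph$truth$true_sources
  expect_equal(max(abs(x - recon)), 0)
  expect_equal(max(abs(ph$truth$noise)), 0)
})

test_that("phantom generation is deterministic given the seed", {
  a <- small_phantom(seed = 11)
  b <- small_phantom(seed = 11)
  expect_identical(a$dataset$data, b$dataset$data)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$true_sources, b$truth$true_sources)
  c <- small_phantom(seed = 12)
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("truth record reconstructs emitted maps up to the stored noise", {
  ph <- small_phantom(seed = 3, noise_sd = 0.2)
  recon <- ph$truth$true_loadings %*% ph$truth$true_sources + ph$truth$noise
  expect_equal(max(abs(recon - ph$dataset$data)), 0)
  expect_true(all(ph$dataset$data >= 0))
})

test_that("planted group shift has the expected two-sample t power", {
  # d = 0.8 with 100 per group: significant at p < 0.01 in >= 95/100 seeds
  hits <- vapply(1:100, function(s) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = c(10, 10, 10), n_subjects = 200, n_sources = 2,
      source_radius = 2, group_effect = list(c(1, 0.8)),
      autism_fraction = 0.5, seed = 1000 + s))
    g <- ph$phenotypes$group
    t.test(ph$truth$true_loadings[g == "autism", 1],
           ph$truth$true_loadings[g == "TD", 1])$p.value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("emitted voxel variance matches the generative closed form", {
  # at voxels where the mixture mean is far from the clip at zero:
  # var = noise_sd^2 + sum_k s_k(v)^2 (unit-variance loadings)
  ph <- generate_phantom(phantom_spec(grid_shape = c(12, 12, 12),
                                      n_subjects = 1000, n_sources = 2,
                                      noise_sd = 0.3, group_effect = list(),
                                      covariate_effects = list(), seed = 21))
  s <- ph$truth$true_sources
  mean_map <- 10 * colSums(s)      # loading offset x blob sum
  expected <- 0.3^2 + colSums(s^2)
  idx <- which(mean_map > 4 * sqrt(expected) & colSums(s^2) > 0.01)
  emp <- apply(ph$dataset$data[, idx, drop = FALSE], 2, var)
  # aggregate level agrees within 5%; per-voxel deviations are sampling noise
  expect_lt(abs(mean(emp) - mean(expected[idx])) / mean(expected[idx]), 0.05)
  rel <- abs(emp - expected[idx]) / expected[idx]
  expect_lt(median(rel), 0.10)
})

test_that("planted canonical mode is recovered by a direct CCA oracle", {
  ph <- generate_phantom(phantom_spec(n_subjects = 400, seed = 9))
  y <- as.matrix(ph$phenotypes[, grep("^beh_", names(ph$phenotypes))])
  fit <- fit_cca(ph$truth$true_loadings, y)
  expect_lt(abs(fit$correlations[1] - ph$truth$planted_mode$r), 0.05)
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(4, 20, 20), source_radius = 2.5),
               "degenerate grid")
  expect_error(phantom_spec(n_subjects = 4, n_sources = 5), "n_sources")
  expect_error(phantom_spec(group_effect = list(c(9, 0.5))), "group_effect")
  expect_error(phantom_spec(planted_r = 1.2), "planted_r")
})

test_that("phantom writes NIfTI maps, phenotype TSV and truth JSON", {
  td <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(grid_shape = c(8, 8, 8), n_subjects = 5,
                                      n_sources = 2, source_radius = 1.5,
                                      seed = 2), dir = td)
  expect_true(file.exists(file.path(td, "sub-001.nii.gz")))
  expect_true(file.exists(file.path(td, "mask.nii.gz")))
  phen <- read.delim(file.path(td, "phenotypes.tsv"))
  expect_setequal(
    c("subject_id", "group", "age", "sex", "fsiq", "site", "adhd"),
    setdiff(names(phen), grep("^beh_", names(phen), value = TRUE)))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(truth$planted_mode$r, 0.7)
})

test_that("missingness masks the requested fraction of behavior rows", {
  ph <- small_phantom(seed = 4, n = 60)
  tab <- ph$phenotypes

  expect_identical(generate_missingness(tab, 0), tab)
  expect_error(generate_missingness(tab, 1), "fraction")

  # the published parent-battery attrition: 44.1% missing of 347 leaves 194
  big <- tab[rep(1:60, length.out = 347), ]
  m <- generate_missingness(big, 0.441, seed = 2)
  complete <- sum(stats::complete.cases(m[grep("^beh_", names(m))]))
  expect_equal(complete, 194)
  expect_equal(round(100 * complete / 347, 1), 55.9)
  # diagnosis and covariates never masked
  expect_false(anyNA(m$group))
  expect_false(anyNA(m$age))

  m1 <- generate_missingness(tab, 0.5, seed = 1)
  m2 <- generate_missingness(tab, 0.5, seed = 2)
  n1 <- which(is.na(m1$beh_1))
  n2 <- which(is.na(m2$beh_1))
  expect_equal(length(n1), length(n2))
  expect_false(identical(n1, n2))
})
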