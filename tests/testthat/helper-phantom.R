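# Shared fixtures: all synthetic, built in code at test time.

# small, fast phantom for structural tests
small_phantom <- function(seed = 7, n = 80, k = 3, noise_sd = 0.1,
                          grid = c(14, 16, 14), ...) {
  generate_phantom(phantom_spec(grid_shape = grid, n_subjects = n,
                                n_sources = k, noise_sd = noise_sd,
                                seed = seed, ...))
}

# loading-model simulator mirroring the phantom generator's assumptions but
# without maps: unit-variance Laplace loadings, optional group shift and
# covariates; used for GLM/CCA calibration at scale
simulate_loadings <- function(n, d, seed, group_shift = NULL,
                              shift_component = 1) {
  set.seed(seed)
  group <- rep(c("autism", "TD"), length.out = n)
  l <- matrix((rexp(n * d) - rexp(n * d)) / sqrt(2), n, d)
  if (!is.null(group_shift))
    l[group == "autism", shift_component] <-
      l[group == "autism", shift_component] + group_shift
  phen <- data.frame(subject_id = sprintf("s%03d", seq_len(n)), group = group,
                     age = runif(n, 6, 30),
                     sex = sample(c("male", "female"), n, replace = TRUE),
                     fsiq = rnorm(n, 100, 15),
                     site = sample.int(3, n, replace = TRUE),
                     adhd = rbinom(n, 1, 0.3))
  list(loadings = l, phenotypes = phen)
}

# x/y pair with one planted canonical mode of population correlation r0,
# following the generator's construction (latent variate + independent noise)
simulate_planted_cca <- function(n, px, py, r0, seed, noise_sd = 1) {
  set.seed(seed)
  x <- matrix((rexp(n * px) - rexp(n * px)) / sqrt(2), n, px)
  wx <- numeric(px)
  wx[seq_len(min(3, px))] <- 1 / sqrt(min(3, px))
  u <- as.numeric(scale(x %*% wx))
  wy_dir <- seq(py, 1) / sqrt(sum(seq(py, 1)^2))
  wy <- wy_dir * noise_sd * r0 / sqrt(1 - r0^2)
  y <- outer(u, wy) + matrix(rnorm(n * py, sd = noise_sd), n, py)
  list(x = x, y = y, wx = wx, wy = wy)
}

# independent pure-R TFCE oracle: naive threshold sweep with R-level
# flood-fill labeling, no shared code with the compiled implementation
tfce_brute_r <- function(vol, E, H, dh_frac, connectivity = 26) {
  d <- dim(vol)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(offsets != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  if (connectivity == 18) offsets <- offsets[rowSums(abs(offsets)) <= 2, , drop = FALSE]
  grid_idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                    z = seq_len(d[3])))
  one_tail <- function(v) {
    out <- array(0, d)
    mx <- max(v)
    if (mx <= 0) return(out)
    dh <- dh_frac * mx
    for (s in seq_len(floor(mx / dh + 1e-12))) {
      h <- s * dh
      above <- v >= h
      seen <- array(FALSE, d)
      for (start in which(above)) {
        if (seen[start]) next
        # flood fill one cluster from `start`
        members <- integer(0)
        queue <- start
        seen[start] <- TRUE
        while (length(queue)) {
          cur <- queue[1]
          queue <- queue[-1]
          members <- c(members, cur)
          nb <- sweep(offsets, 2, grid_idx[cur, ], "+")
          ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
            nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
          lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) +
            d[1] * d[2] * (nb[ok, 3] - 1)
          lin <- lin[above[lin] & !seen[lin]]
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
        out[members] <- out[members] + length(members)^E * h^H * dh
      }
    }
    out
  }
  one_tail(pmax(vol, 0)) - one_tail(pmax(-vol, 0))
}
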