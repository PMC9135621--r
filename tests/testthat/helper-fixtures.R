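# small desk-scale configurations used across the unit tests

tiny_config <- function(...) {
  args <- list(grid_dims = c(12L, 12L, 12L),
               n_per_group = c(HC = 8L, ESZ = 6L),
               n_sites = 2L, n_timepoints = 40L, rng_seed = 42L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# deterministic smooth noise maps (participants x voxels)
smooth_noise_maps <- function(n, dims = c(12L, 12L, 12L), sigma = 1.5,
                              sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(NA_real_, n, prod(dims))
    for (i in seq_len(n)) {
      f <- smooth_volume(array(rnorm(prod(dims)), dim = dims), sigma)
      m[i, ] <- sd * as.vector(f) / stats::sd(as.vector(f))
    }
    attr(m, "dims") <- dims
    m
  })
}

# brute-force OLS via explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# brute-force BH step-up: largest i with p_(i) <= i*q/m rejected
bh_oracle_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
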