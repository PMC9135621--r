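test_that("seed thresholding follows the probability cut-off", {
  expect_equal(threshold_seed(array(0.9, c(8, 8, 8)), 0.8)$n_voxels, 512)
  expect_error(threshold_seed(array(0.5, c(8, 8, 8)), 0.8), "empty")
  p <- array(0, c(8, 8, 8))
  p[sample(length(p), 12)] <- 0.85
  expect_equal(threshold_seed(p, 0.8)$n_voxels, 12)
  expect_error(threshold_seed(array(1.5, c(8, 8, 8))), "\\[0, 1\\]")
})

test_that("seed time-series is the unweighted spatial mean", {
  d <- c(4L, 4L, 4L); nt <- 10L
  x <- sin(seq_len(nt))
  data <- array(0, c(d, nt))
  mask <- array(FALSE, d); mask[1:2, 1, 1] <- TRUE
  data[1, 1, 1, ] <- x
  data[2, 1, 1, ] <- 2 * x
  expect_equal(extract_seed_timeseries(data, mask), 1.5 * x)
  # all mask voxels identical: returns that series
  data[2, 1, 1, ] <- x
  expect_equal(extract_seed_timeseries(data, mask), x)
  # brute-force loop oracle on a random run
  set.seed(1)
  data[] <- rnorm(length(data))
  mask[] <- runif(length(mask)) < 0.3
  byloop <- sapply(seq_len(nt), function(t) mean(data[, , , t][mask]))
  expect_equal(extract_seed_timeseries(data, mask), byloop,
               tolerance = 1e-12)
  expect_error(extract_seed_timeseries(data, array(TRUE, c(3, 3, 3))),
               "does not match")
})

test_that("first-level GLM recovers exact coefficients", {
  nt <- 30L
  s <- sin(seq_len(nt) / 2)
  des <- first_level_design(s, drift = FALSE)
  mk_run <- function(f) {
    a <- array(0, c(2, 1, 1, nt)); a[1, 1, 1, ] <- f; a[2, 1, 1, ] <- s
    a
  }
  expect_equal(fit_first_level(mk_run(s), des)[1, 1, 1], 1,
               tolerance = 1e-12)
  expect_equal(fit_first_level(mk_run(2 * s + 7), des)[1, 1, 1], 2,
               tolerance = 1e-12)
})

test_that("first-level GLM matches the normal-equations oracle", {
  set.seed(2)
  nt <- 50L; d <- c(5L, 4L, 3L)
  run <- array(rnorm(prod(d) * nt), c(d, nt))
  s <- rnorm(nt)
  nuis <- matrix(rnorm(nt * 2), nt)
  des <- first_level_design(s, nuisance = nuis)
  beta <- fit_first_level(run, des)
  oracle <- apply(matrix(run, prod(d), nt), 1,
                  function(y) ols_oracle(des$X, y)[1])
  expect_lt(max(abs(as.vector(beta) - oracle)), 1e-10)
})

test_that("seed betas honour the linear-model invariances", {
  set.seed(3)
  nt <- 40L; d <- c(4L, 4L, 2L)
  run <- array(rnorm(prod(d) * nt), c(d, nt))
  s <- rnorm(nt)
  base <- fit_first_level(run, first_level_design(s))
  # orthogonal nuisance leaves the seed beta unchanged
  ortho <- rnorm(nt)
  ortho <- resid(lm(ortho ~ cbind(s, seq_len(nt))))
  with_n <- fit_first_level(run, first_level_design(s, nuisance = ortho))
  expect_lt(max(abs(base - with_n)), 1e-10)
  # scaling the regressor by c scales betas by 1/c
  scaled <- fit_first_level(run, first_level_design(3 * s))
  expect_equal(as.vector(scaled), as.vector(base) / 3, tolerance = 1e-10)
  # adding a constant to voxel series changes nothing (intercept present)
  shifted <- fit_first_level(run + 11, first_level_design(s))
  expect_lt(max(abs(base - shifted)), 1e-10)
})

test_that("degenerate designs and voxels are handled explicitly", {
  s <- rnorm(20)
  expect_error(first_level_design(s, nuisance = cbind(bad = 2 * s)),
               "bad")
  expect_error(first_level_design(c(s[-1], NA)), "non-finite")
  # zero-variance voxel flagged out with beta 0
  a <- array(rnorm(2 * 20), c(2, 1, 1, 20))
  a[2, 1, 1, ] <- 5
  b <- fit_first_level(a, first_level_design(s))
  expect_equal(b[2, 1, 1], 0)
  expect_false(attr(b, "mask")[2, 1, 1])
  expect_equal(attr(b, "n_masked_out"), 1L)
})
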