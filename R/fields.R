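#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian smoothing along each axis with reflecting-style
#' row-normalised kernels (constants are preserved exactly). Used by the
#' synthetic-data generator to give baseline, site-offset and age-slope
#' fields realistic spatial autocorrelation, and optionally to smooth
#' voxel time-series before first-level fitting.
#'
#' @param arr 3D numeric array.
#' @param sigma Smoothing standard deviation in voxels; `sigma <= 0` is a
#'   no-op.
#' @return Smoothed array with the same dimensions.
#' @export
smooth_volume <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  if (sigma <= 0) return(arr)
  kmat <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    K / rowSums(K)
  }
  a <- array(kmat(d[1]) %*% matrix(arr, d[1]), d)
  a <- aperm(a, c(2, 3, 1))
  a <- array(kmat(d[2]) %*% matrix(a, d[2]), c(d[2], d[3], d[1]))
  a <- aperm(a, c(2, 3, 1))
  a <- array(kmat(d[3]) %*% matrix(a, d[3]), c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

# Smooth Gaussian random field scaled to a target marginal SD.
random_field <- function(dims, sigma, sd = 1, mean = 0) {
  f <- array(rnorm(prod(dims)), dim = dims)
  f <- smooth_volume(f, sigma)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  mean + sd * f
}
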