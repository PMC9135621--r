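#' Define a seed region from a probabilistic atlas map
#'
#' Thresholds a probability map at a stringent cut-off (default 0.80) to
#' obtain the binary seed mask.
#'
#' @param probability_map 3D array with values in `[0, 1]`.
#' @param threshold Probability threshold in `(0, 1]`.
#' @return A `seed_definition`: list with `mask` (logical 3D array),
#'   `threshold`, `n_voxels`.
#' @export
#' @examples
#' p <- array(0.9, c(8, 8, 8))
#' threshold_seed(p, 0.8)$n_voxels
threshold_seed <- function(probability_map, threshold = 0.8) {
  stopifnot(is.array(probability_map), length(dim(probability_map)) == 3L)
  if (any(probability_map < 0 | probability_map > 1, na.rm = TRUE))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  mask <- !is.na(probability_map) & probability_map >= threshold
  if (!any(mask))
    stop("seed mask is empty at threshold ", threshold, call. = FALSE)
  structure(list(mask = mask, threshold = threshold,
                 n_voxels = sum(mask)),
            class = "seed_definition")
}

#' @export
print.seed_definition <- function(x, ...) {
  cat(sprintf("<seed_definition> %d voxels at probability >= %g\n",
              x$n_voxels, x$threshold))
  invisible(x)
}

#' Extract the mean seed time-series from a run
#'
#' Unweighted spatial mean over the seed mask voxels at each timepoint.
#'
#' @param run A `bold_run` (or a bare 4D array).
#' @param seed A [threshold_seed()] definition (or a logical 3D array).
#' @return Numeric vector of length `t`.
#' @export
extract_seed_timeseries <- function(run, seed) {
  data <- if (inherits(run, "bold_run")) run$data else run
  mask <- if (inherits(seed, "seed_definition")) seed$mask else seed
  d <- dim(data)
  stopifnot(length(d) == 4L)
  if (!identical(dim(mask), d[1:3]))
    stop("seed grid ", paste(dim(mask), collapse = "x"),
         " does not match run grid ", paste(d[1:3], collapse = "x"),
         call. = FALSE)
  m <- matrix(data, prod(d[1:3]), d[4])
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' First-level design matrix
#'
#' The seed regressor of interest plus nuisance columns: an intercept and a
#' linear drift term by default, with optional user-supplied columns (e.g.
#' task-activity or physiological regressors as additional nuisance).
#'
#' @param seed_regressor Numeric vector, the seed time-series.
#' @param nuisance Optional numeric matrix (`t` x `k`) of extra nuisance
#'   regressors.
#' @param drift Include a linear drift column.
#' @return A `first_level_design`: list with `X` (named columns, seed
#'   first) and `seed_col`.
#' @export
first_level_design <- function(seed_regressor, nuisance = NULL,
                               drift = TRUE) {
  t_len <- length(seed_regressor)
  if (any(!is.finite(seed_regressor)))
    stop("seed regressor contains non-finite values", call. = FALSE)
  X <- cbind(seed = seed_regressor, intercept = rep(1, t_len))
  if (drift)
    X <- cbind(X, drift = seq_len(t_len) / t_len - 0.5)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == t_len)
    if (any(!is.finite(nuisance)))
      stop("nuisance regressors contain non-finite values", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, seed_col = 1L), class = "first_level_design")
}

#' Fit the first-level voxelwise seed GLM
#'
#' Ordinary least squares of every voxel's time-series on the seed
#' regressor plus nuisance columns; the returned map holds the seed
#' coefficient. Voxels with zero temporal variance get beta 0 and are
#' flagged out of the analysis mask.
#'
#' @param run A `bold_run` (or 4D array).
#' @param design A [first_level_design()].
#' @return 3D beta array with attributes `mask` (logical 3D array of
#'   analysed voxels) and `n_masked_out`.
#' @export
fit_first_level <- function(run, design) {
  data <- if (inherits(run, "bold_run")) run$data else run
  d <- dim(data)
  stopifnot(length(d) == 4L, inherits(design, "first_level_design"))
  X <- design$X
  if (nrow(X) != d[4])
    stop("design has ", nrow(X), " timepoints but run has ", d[4],
         call. = FALSE)
  Y <- t(matrix(data, prod(d[1:3]), d[4])) # t x V
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)[design$seed_col, ]
  v <- col_vars(Y)
  flat <- v <= .Machine$double.eps * 100
  beta[flat] <- 0
  out <- array(beta, dim = d[1:3])
  attr(out, "mask") <- array(!flat, dim = d[1:3])
  attr(out, "n_masked_out") <- sum(flat)
  out
}

# column variances without loading an extra package
col_vars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}
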