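#' Fit a normative reference model on healthy-control maps
#'
#' Per-voxel ordinary least squares of HC connectivity maps on either site
#' dummies (`kind = "site"`) or an intercept plus linear age
#' (`kind = "age"`). The residual standard error
#' `sqrt(RSS / (n_hc - k))` — the "standard error of the regression" —
#' is stored per voxel and later divides observed-minus-predicted
#' deviations, so held-out HC deviations have approximately unit variance.
#' Only HC rows are accepted: if the covariate table carries a `group`
#' column, any non-HC row is an error.
#'
#' @param maps HC maps: list of 3D arrays or an `n x V` matrix.
#' @param covariates Data frame aligned with `maps` rows; needs `site`
#'   (kind "site") or `age` (kind "age"); an optional `group` column must
#'   be all `"HC"`.
#' @param kind `"site"` or `"age"`.
#' @param dims Grid dims when `maps` is a matrix.
#' @return A `normative_model` with per-voxel `coef` (k x V), `resid_se`,
#'   `mask` (voxels with positive residual variance), `kind`, `levels`
#'   (site labels), `n_hc`, `k`, `dims`.
#' @export
fit_normative <- function(maps, covariates, kind = c("site", "age"),
                          dims = NULL) {
  kind <- match.arg(kind)
  m <- as_map_matrix(maps)
  if (is.null(dims)) dims <- attr(m, "dims")
  n <- nrow(m)
  stopifnot(nrow(covariates) == n)
  if (!is.null(covariates$group) && any(covariates$group != "HC"))
    stop("normative model must be fitted on HC only; found group(s): ",
         paste(setdiff(unique(covariates$group), "HC"), collapse = ", "),
         call. = FALSE)
  if (kind == "site") {
    if (is.null(covariates$site)) stop("covariates need a 'site' column",
                                       call. = FALSE)
    site <- factor(covariates$site)
    counts <- table(site)
    thin <- names(counts)[counts < 2]
    if (length(thin))
      stop("site(s) with fewer than 2 HC: ", paste(thin, collapse = ", "),
           call. = FALSE)
    X <- model.matrix(~site)
    levels <- levels(site)
  } else {
    if (is.null(covariates$age)) stop("covariates need an 'age' column",
                                      call. = FALSE)
    X <- cbind(intercept = 1, age = covariates$age)
    levels <- NULL
  }
  k <- ncol(X)
  if (n <= k + 1)
    stop("need more than k + 1 = ", k + 1, " HC to fit the reference model",
         call. = FALSE)
  XtX <- crossprod(X)
  coefs <- solve(XtX, crossprod(X, m))           # k x V
  resid <- m - X %*% coefs
  rss <- colSums(resid^2)
  resid_se <- sqrt(rss / (n - k))
  mask <- resid_se > sqrt(.Machine$double.eps)
  structure(list(kind = kind, coef = coefs, resid_se = resid_se,
                 mask = mask, levels = levels, n_hc = n, k = k,
                 dims = dims, X_names = colnames(X)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model> kind=%s, n_hc=%d, k=%d, grid %s (%d/%d voxels in mask)\n",
    x$kind, x$n_hc, x$k, paste(x$dims, collapse = "x"),
    sum(x$mask), length(x$mask)))
  invisible(x)
}

# design row for one participant under a fitted model
normative_design_row <- function(model, covariates_row) {
  if (model$kind == "site") {
    s <- as.character(covariates_row$site)
    if (!s %in% model$levels)
      stop("site '", s, "' was not present in the HC reference fit",
           call. = FALSE)
    x <- as.numeric(model$levels == s)
    x[1] <- 1 # treatment coding: intercept + dummies for levels 2..k
    x
  } else {
    c(1, covariates_row$age)
  }
}

#' Predicted (expected HC) map for a participant
#'
#' @param object A `normative_model`.
#' @param covariates_row One-row data frame with the model's covariate.
#' @param ... Unused.
#' @return 3D array of predicted values.
#' @export
predict.normative_model <- function(object, covariates_row, ...) {
  x <- normative_design_row(object, covariates_row)
  array(as.vector(x %*% object$coef), dim = object$dims)
}

#' Normative deviation z-score map
#'
#' `z_v = (observed_v - predicted_v) / residual SE_v`: the participant's
#' map expressed voxelwise in standard-deviation units relative to the HC
#' reference. Voxels outside the model mask are `NA`.
#'
#' @param map 3D connectivity map (or vector of length V).
#' @param covariates_row One-row data frame (`site` or `age`).
#' @param model A [fit_normative()] model.
#' @return 3D z-score array.
#' @export
zscore_map <- function(map, covariates_row, model) {
  v <- if (is.array(map) && length(dim(map)) == 3L) {
    if (!identical(dim(map), as.integer(model$dims)))
      stop("map grid does not match the model grid", call. = FALSE)
    as.vector(map)
  } else as.vector(map)
  stopifnot(length(v) == length(model$resid_se))
  x <- normative_design_row(model, covariates_row)
  pred <- as.vector(x %*% model$coef)
  z <- (v - pred) / model$resid_se
  z[!model$mask] <- NA_real_
  array(z, dim = model$dims)
}

#' Z-score a whole cohort of maps
#'
#' @param maps `n x V` matrix or list of 3D arrays.
#' @param covariates Data frame aligned with `maps` rows.
#' @param model A `normative_model`.
#' @return `n x V` matrix of deviation z-scores (NA outside the mask).
#' @export
zscore_maps <- function(maps, covariates, model) {
  m <- as_map_matrix(maps)
  stopifnot(nrow(covariates) == nrow(m))
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m)))
    out[i, ] <- as.vector(zscore_map(m[i, ], covariates[i, , drop = FALSE],
                                     model))
  out
}
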