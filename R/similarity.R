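#' Vectorize a 3D map in the canonical voxel order
#'
#' Values at mask voxels in lexicographic order with the first axis
#' fastest (R's native column-major order), so any two maps vectorized
#' with the same mask align voxel-for-voxel.
#'
#' @param map 3D array.
#' @param mask Logical 3D array on the same grid; `NULL` takes all finite
#'   voxels of `map`.
#' @return Numeric vector of length `sum(mask)`.
#' @export
vectorize_map <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(map)
  if (!identical(dim(map), dim(mask)))
    stop("map grid ", paste(dim(map), collapse = "x"),
         " does not match mask grid ", paste(dim(mask), collapse = "x"),
         call. = FALSE)
  map[mask]
}

#' Scatter a vector back into a 3D map
#'
#' Inverse of [vectorize_map()]: fills mask voxels in canonical order,
#' `NA` elsewhere.
#'
#' @param values Numeric vector of length `sum(mask)`.
#' @param mask Logical 3D array.
#' @return 3D array.
#' @export
scatter_map <- function(values, mask) {
  stopifnot(length(values) == sum(mask))
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- values
  out
}

#' Fisher r-to-z transform
#'
#' `atanh(r) = 0.5 * log((1 + r) / (1 - r))`; odd in `r`, defined for
#' `|r| < 1`.
#'
#' @param r Correlation(s) in `(-1, 1)`.
#' @return Fisher z value(s).
#' @export
#' @examples
#' fisher_z(0.5) # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("Fisher z is undefined for |r| >= 1", call. = FALSE)
  atanh(r)
}

#' Template similarity coefficient for one participant
#'
#' Pearson correlation between a participant's deviation z-map and the
#' unthresholded group template over a shared mask, with the Fisher r-to-z
#' transform attached — one similarity coefficient per participant.
#'
#' @param zmap Participant 3D deviation map.
#' @param template 3D template map.
#' @param mask Logical mask; `NULL` uses the intersection of finite voxels
#'   of both maps.
#' @return List with `r`, `fisher_z`, `n_voxels`.
#' @export
similarity_coefficient <- function(zmap, template, mask = NULL) {
  if (!identical(dim(zmap), dim(template)))
    stop("map and template grids differ", call. = FALSE)
  if (is.null(mask)) mask <- is.finite(zmap) & is.finite(template)
  a <- vectorize_map(zmap, mask)
  b <- vectorize_map(template, mask)
  if (length(a) < 3L)
    stop("need at least 3 mask voxels to correlate", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined: constant vector over the mask",
         call. = FALSE)
  r <- cor(a, b)
  # atanh maps r = +/-1 (exact proportionality) to +/-Inf
  list(r = r, fisher_z = atanh(r), n_voxels = length(a))
}

#' Similarity coefficients for a cohort
#'
#' Correlates every participant's deviation map with the template over one
#' shared mask — the intersection of the template's finite voxels and
#' every participant's finite voxels, computed once so all vectors share
#' length and ordering.
#'
#' @param zmaps `n x V` matrix (rows named by participant id) or list of
#'   3D arrays.
#' @param template 3D template array.
#' @param mask Optional logical 3D mask overriding the intersection mask.
#' @return Data frame: `id`, `r`, `fisher_z`, `n_voxels`.
#' @export
similarity_table <- function(zmaps, template, mask = NULL) {
  m <- as_map_matrix(zmaps)
  stopifnot(length(template) == ncol(m))
  tv <- as.vector(template)
  if (is.null(mask)) {
    keep <- is.finite(tv) & apply(is.finite(m), 2, all)
  } else {
    keep <- as.vector(mask)
  }
  if (sum(keep) < 3L) stop("shared mask has fewer than 3 voxels",
                           call. = FALSE)
  tb <- tv[keep]
  if (sd(tb) == 0) stop("template is constant over the mask", call. = FALSE)
  sub <- m[, keep, drop = FALSE]
  r <- as.vector(cor(t(sub), tb))
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(m)))
  data.frame(id = ids, r = r, fisher_z = atanh(r),
             n_voxels = sum(keep), row.names = NULL,
             stringsAsFactors = FALSE)
}
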