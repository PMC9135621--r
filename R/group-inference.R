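#' Group one-sample t-map
#'
#' Per voxel `t = mean / (sd / sqrt(n))` with `df = n - 1`. Voxels with
#' zero between-participant variance are masked out (`NA`).
#'
#' @param maps List of 3D contrast arrays (one per participant), or an
#'   `n x V` matrix.
#' @param dims Grid dimensions (required when `maps` is a matrix).
#' @return A `stat_map`: list with 3D `data`, `statistic = "t"`, `df`, `n`.
#' @export
one_sample_t_map <- function(maps, dims = NULL) {
  m <- as_map_matrix(maps)
  if (is.null(dims)) dims <- attr(m, "dims")
  n <- nrow(m)
  if (n < 2L) stop("one-sample t-map needs at least 2 participants",
                   call. = FALSE)
  mu <- colMeans(m)
  s <- sqrt(pmax(0, (colSums(m^2) - n * mu^2) / (n - 1)))
  t <- mu / (s / sqrt(n))
  t[s <= 0] <- NA_real_
  structure(list(data = array(t, dim = dims), statistic = "t",
                 df = n - 1L, n = n),
            class = "stat_map")
}

as_map_matrix <- function(maps) {
  if (is.matrix(maps)) {
    m <- maps
    if (is.null(attr(m, "dims"))) attr(m, "dims") <- c(ncol(m), 1L, 1L)
    return(m)
  }
  d <- check_same_grid(maps)
  m <- do.call(rbind, lapply(maps, as.vector))
  attr(m, "dims") <- d
  m
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s statistic, %s n=%d, grid %s\n", x$statistic,
              if (x$statistic == "t") sprintf("df=%d, ", x$df) else "",
              x$n, paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Convert t statistics to standard-normal z scores
#'
#' `z = qnorm(pt(t; df))` evaluated through log-tail probabilities so that
#' extreme |t| convert without underflow; odd in `t` and strictly
#' increasing. `NA`s (masked voxels) propagate.
#'
#' @param t Numeric vector or array of t statistics.
#' @param df Degrees of freedom (>= 1).
#' @return z values with the shape of `t`.
#' @export
#' @examples
#' t_to_z(2, 17)
t_to_z <- function(t, df) {
  stopifnot(df >= 1)
  z <- t
  ok <- !is.na(t)
  # work in the upper tail of |t| for numerical stability
  logp <- pt(abs(t[ok]), df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- sign(t[ok]) * qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' Cluster-defining z threshold for a two-tailed voxelwise p
#'
#' The standard-normal quantile `qnorm(1 - p/2)` used as the voxelwise
#' cluster-defining threshold; at `p = 0.001` this is the conventional
#' 3.29.
#'
#' @param p Two-tailed voxelwise probability.
#' @return The |z| threshold.
#' @export
#' @examples
#' cluster_defining_z(0.001)
cluster_defining_z <- function(p = 0.001) {
  stopifnot(p > 0, p < 1)
  qnorm(1 - p / 2)
}

#' Convert a t stat_map to a z stat_map
#'
#' @param stat A `stat_map` with `statistic = "t"`.
#' @return A `stat_map` with `statistic = "z"`.
#' @export
stat_map_to_z <- function(stat) {
  stopifnot(inherits(stat, "stat_map"), stat$statistic == "t")
  structure(list(data = t_to_z(stat$data, stat$df), statistic = "z",
                 df = stat$df, n = stat$n),
            class = "stat_map")
}

#' Label suprathreshold clusters
#'
#' Connected components of `|z| > cdt`, with positive and negative voxels
#' labelled separately (a two-tailed cluster-defining threshold). Face
#' connectivity (6-neighbourhood) by default; 18 and 26 are available.
#'
#' @param z 3D z array (`NA` treated as subthreshold).
#' @param cdt Cluster-defining threshold on `|z|`.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (3D integer array, 0 = background, ids
#'   contiguous from 1), `sizes`, `signs` per cluster.
#' @export
label_clusters <- function(z, cdt = 3.29, connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(z)
  zz <- z; zz[is.na(zz)] <- 0
  pos <- label_components_3d(as.logical(zz > cdt), as.integer(d),
                             as.integer(connectivity))
  neg <- label_components_3d(as.logical(zz < -cdt), as.integer(d),
                             as.integer(connectivity))
  npos <- max(pos)
  labels <- pos
  labels[neg > 0L] <- neg[neg > 0L] + npos
  nclust <- npos + max(neg)
  sizes <- if (nclust > 0L) tabulate(labels[labels > 0L], nclust) else
    integer(0)
  list(labels = array(labels, dim = d), sizes = sizes,
       signs = c(rep(1L, npos), rep(-1L, max(neg))))
}

#' Cluster-extent inference with a sign-flip permutation null
#'
#' Forms the group one-sample t-map from participant contrast maps,
#' converts it to z, labels clusters exceeding the two-tailed
#' cluster-defining threshold, and assigns each cluster a family-wise
#' corrected p-value from the permutation distribution of the maximum
#' cluster size under random sign flips of the participant maps. Because
#' z is a monotone function of t, thresholding is done in t-space at the
#' t value whose z equals `cdt`, so the permutation loop never converts
#' whole maps.
#'
#' @param maps List of participant contrast maps, or `n x V` matrix.
#' @param cdt Cluster-defining threshold on `|z|` (default 3.29, the
#'   two-tailed 0.001 normal quantile).
#' @param alpha Corrected cluster significance threshold.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param perm_seed Seed for the permutation stream.
#' @param dims Grid dims when `maps` is a matrix.
#' @return A `cluster_result`: `table` (significant clusters: `id`, `size`,
#'   `sign`, `peak_z`, `peak_i/j/k`, `p_fwe`), `labels` (3D array labelling
#'   significant clusters), `zmap` (`stat_map`), `candidates` (all
#'   suprathreshold clusters), `null_max_size`, and the parameters.
#' @export
cluster_threshold <- function(maps, cdt = 3.29, alpha = 0.05,
                              n_perm = 1000L, connectivity = 6L,
                              perm_seed = 20220414L, dims = NULL) {
  if (cdt <= 0) stop("cdt must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if ((n_perm + 1) * alpha < 1)
    warning("n_perm = ", n_perm, " cannot resolve corrected p < ", alpha,
            "; proceeding")
  m <- as_map_matrix(maps)
  if (is.null(dims)) dims <- attr(m, "dims")
  n <- nrow(m)
  tmap <- one_sample_t_map(m, dims = dims)
  zmap <- stat_map_to_z(tmap)
  # t-space equivalent of the z threshold (monotone transform)
  t_cdt <- qt(pnorm(cdt, lower.tail = FALSE, log.p = TRUE), df = tmap$df,
              lower.tail = FALSE, log.p = TRUE)

  cand <- label_clusters(zmap$data, cdt = cdt, connectivity = connectivity)
  # permutation null of the maximum cluster size (both tails pooled)
  ss <- colSums(m^2)
  null_max <- local_seed(perm_seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    mu <- crossprod(m, signs) / n                   # V x n_perm
    se <- sqrt(pmax(0, sweep(-n * mu^2, 1, ss, `+`) / (n - 1)) / n)
    tm <- mu / se
    tm[!is.finite(tm)] <- 0
    max_cluster_size_cols(tm, as.integer(dims), t_cdt,
                          as.integer(connectivity))
  })
  k <- length(cand$sizes)
  p_fwe <- if (k) vapply(cand$sizes, function(s)
    (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1)) else numeric(0)

  zz <- zmap$data; zz[is.na(zz)] <- 0
  peak_of <- function(cl) {
    vox <- which(cand$labels == cl)
    vox[which.max(abs(zz[vox]))]
  }
  cand_tab <- data.frame(
    id = seq_len(k), size = cand$sizes, sign = cand$signs,
    peak_z = numeric(k), peak_i = integer(k), peak_j = integer(k),
    peak_k = integer(k), p_fwe = p_fwe)
  if (k) {
    pk <- vapply(seq_len(k), peak_of, numeric(1))
    ijk <- arrayInd(pk, dims)
    cand_tab$peak_z <- zz[pk]
    cand_tab$peak_i <- ijk[, 1]; cand_tab$peak_j <- ijk[, 2]
    cand_tab$peak_k <- ijk[, 3]
  }
  keep <- which(cand_tab$p_fwe < alpha)
  table <- cand_tab[keep, , drop = FALSE]
  labels <- array(0L, dim = dims)
  if (length(keep)) {
    for (new_id in seq_along(keep))
      labels[cand$labels == keep[new_id]] <- new_id
    table$id <- seq_along(keep)
  }
  rownames(table) <- NULL
  structure(list(table = table, labels = labels, zmap = zmap,
                 candidates = cand_tab, null_max_size = null_max,
                 cdt = cdt, alpha = alpha, n_perm = n_perm,
                 connectivity = connectivity, n = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> n=%d, |z| > %g, %d-connectivity, %d permutations\n",
    x$n, x$cdt, x$connectivity, x$n_perm))
  cat(sprintf("  %d candidate cluster(s), %d significant at corrected p < %g\n",
              nrow(x$candidates), nrow(x$table), x$alpha))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Mean map value within each cluster ROI
#'
#' @param map 3D array to summarise.
#' @param clusters A `cluster_result` or a 3D integer label array.
#' @return Named numeric vector, one unweighted mean per cluster id.
#' @export
extract_roi_means <- function(map, clusters) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else clusters
  if (!identical(dim(map), dim(labels)))
    stop("map grid does not match cluster label grid", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(setNames(numeric(0), character(0)))
  out <- vapply(ids, function(i) mean(map[labels == i]), numeric(1))
  setNames(out, paste0("cluster", ids))
}

#' One-way repeated-measures ANOVA with paired follow-ups
#'
#' Within-subject one-way ANOVA (subject as the blocking factor) across
#' drug conditions, fitted with `stats::aov` and an `Error(subject)`
#' stratum, followed by two-sided paired t-tests for each condition pair
#' with Benjamini-Hochberg adjustment across the pairs.
#'
#' @param roi_values Numeric matrix, participants x conditions (complete
#'   cases required; column names label the conditions).
#' @return An `rm_anova`: list with `F`, `df1`, `df2`, `p`, and `pairwise`
#'   data.frame (`pair`, `t`, `df`, `p`, `p_fdr`).
#' @export
repeated_measures_anova <- function(roi_values) {
  roi_values <- as.matrix(roi_values)
  if (ncol(roi_values) < 2L) stop("need at least 2 conditions",
                                  call. = FALSE)
  if (nrow(roi_values) < 3L) stop("need at least 3 participants",
                                  call. = FALSE)
  if (any(!is.finite(roi_values)))
    stop("missing cells: listwise complete data required", call. = FALSE)
  conds <- colnames(roi_values)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(roi_values)))
  conds <- make.unique(conds)
  long <- data.frame(
    y = as.vector(roi_values),
    condition = factor(rep(conds, each = nrow(roi_values)), levels = conds),
    subject = factor(rep(seq_len(nrow(roi_values)), ncol(roi_values))))
  fit <- aov(y ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  p <- tab["condition", "Pr(>F)"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  ss_within <- tab["condition", "Sum Sq"] + tab["Residuals", "Sum Sq"]
  if (ss_within <= 1e-12 * max(sum(roi_values^2), 1)) {
    # no within-subject variability at all (identical conditions up to
    # roundoff): report a null effect rather than a 0/0 ratio
    Fv <- 0; p <- 1
  }
  pairs <- utils::combn(seq_along(conds), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- t.test(roi_values[, a], roi_values[, b], paired = TRUE)
    data.frame(pair = paste(conds[a], "vs", conds[b]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  pw$p_fdr <- p.adjust(pw$p, method = "BH")
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p, pairwise = pw),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  print(x$pairwise)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH adjusted p-values (via `stats::p.adjust`) plus rejection
#' flags at level `q`.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L)
    return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}
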