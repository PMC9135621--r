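#' Synthetic probabilistic seed atlas
#'
#' A probability map peaking at 1 in the grid centre and decaying linearly
#' with Euclidean distance, so the stringent 0.80 threshold keeps a compact
#' ball of central voxels (33 on the default grid) — a stand-in for a
#' probabilistic subcortical atlas entry.
#'
#' @param config A [sim_config()].
#' @return 3D array of probabilities in `[0, 1]`.
#' @export
simulate_seed_atlas <- function(config) {
  d <- config$grid_dims
  ctr <- (d + 1) / 2
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  dist <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
                 (idx[, 3] - ctr[3])^2)
  array(pmax(0, 1 - dist / 10), dim = d)
}

#' Planted dysconnectivity pattern ("true template")
#'
#' The ground-truth spatial pattern that the generator plants: compact
#' positive blocks in designated "sensory" voxels away from the seed
#' (hyper-connectivity only, matching the phenomenon the template models),
#' lightly smoothed and scaled to unit SD over the grid. Drug sessions
#' increase seed coupling proportionally to this pattern, and clinical
#' connectivity maps load on it with participant-specific \eqn{\lambda_i}.
#'
#' @param config A [sim_config()].
#' @return 3D array with unit marginal SD.
#' @export
simulate_template_pattern <- function(config) {
  d <- config$grid_dims
  pat <- array(0, dim = d)
  blk <- function(cx, cy, cz, r = 1L) {
    xs <- pmax(1L, cx - r):pmin(d[1], cx + r)
    ys <- pmax(1L, cy - r):pmin(d[2], cy + r)
    zs <- pmax(1L, cz - r):pmin(d[3], cz + r)
    pat[xs, ys, zs] <<- 1
  }
  # three sensory-analogue blocks in separate octants, clear of the seed
  q1 <- round(d / 4); q3 <- round(3 * d / 4)
  blk(q1[1], q1[2], q3[3])
  blk(q3[1], q3[2], q3[3])
  blk(q3[1], q1[2], q1[3])
  pat <- smooth_volume(pat, 0.8)
  pat / stats::sd(as.vector(pat))
}

#' Shared spatial fields for a simulated study
#'
#' Baseline, per-site offset, and per-voxel age-slope fields are smooth
#' Gaussian random fields drawn once per configuration (from a dedicated
#' substream) and shared by every participant, giving cluster inference
#' realistic spatial autocorrelation.
#'
#' @param config A [sim_config()].
#' @return List with `baseline`, `site_offsets` (list of 3D arrays, one per
#'   site), and `age_slope` 3D arrays.
#' @export
simulate_cohort_fields <- function(config) {
  d <- config$grid_dims
  local_seed(substream_seed(config$rng_seed, "fields"), {
    list(
      baseline = random_field(d, config$field_smooth_sigma,
                              sd = config$baseline_sd),
      site_offsets = lapply(seq_len(config$n_sites), function(s)
        random_field(d, config$field_smooth_sigma,
                     sd = config$site_offset_sd)),
      age_slope = random_field(d, config$field_smooth_sigma,
                               sd = config$age_slope_sd)
    )
  })
}

#' Simulate one participant's connectivity map
#'
#' `map = baseline + site_offset + age_slope * (age - age_center) +
#' lambda_i * template / sd(template) + N(0, noise_sd)`, evaluated
#' voxelwise. The template is rescaled to unit SD so loadings are in
#' map-SD units.
#'
#' @param participant One row of a [simulate_cohort()] table.
#' @param template 3D array on the configured grid.
#' @param config A [sim_config()].
#' @param fields Optional precomputed [simulate_cohort_fields()] output.
#' @return 3D numeric array.
#' @export
simulate_connectivity_map <- function(participant, template, config,
                                      fields = NULL) {
  d <- config$grid_dims
  if (!identical(dim(template), as.integer(d)))
    stop("template grid ", paste(dim(template), collapse = "x"),
         " does not match configured grid ", paste(d, collapse = "x"),
         call. = FALSE)
  if (is.null(fields)) fields <- simulate_cohort_fields(config)
  tpl <- template / stats::sd(as.vector(template))
  noise <- local_seed(substream_seed(config$rng_seed, "map", participant$id),
                      array(rnorm(prod(d), 0, config$noise_sd), dim = d))
  fields$baseline +
    fields$site_offsets[[participant$site]] +
    fields$age_slope * (participant$age - config$age_center) +
    participant$loading * tpl +
    noise
}

#' Simulate connectivity maps for a whole cohort
#'
#' @param cohort A [simulate_cohort()] table.
#' @param template 3D template array.
#' @param config A [sim_config()].
#' @param fields Optional precomputed fields.
#' @return Numeric matrix, participants x voxels (rows named by id).
#' @export
simulate_study_maps <- function(cohort, template, config, fields = NULL) {
  if (is.null(fields)) fields <- simulate_cohort_fields(config)
  out <- matrix(NA_real_, nrow(cohort), prod(config$grid_dims),
                dimnames = list(cohort$id, NULL))
  for (i in seq_len(nrow(cohort))) {
    out[i, ] <- as.vector(
      simulate_connectivity_map(cohort[i, ], template, config, fields))
  }
  out
}

#' Simulate null between-day contrast maps
#'
#' The generator's contrast-level output when the drug effect is zero:
#' day-specific additive offsets cancel in the within-day differencing,
#' leaving independent zero-mean smooth residual noise per participant.
#' These maps are exchangeable under sign flips, which is exactly the
#' null the permutation cluster test assumes; they drive the type-I-error
#' studies without re-running full BOLD sessions.
#'
#' @param n Number of participants.
#' @param config A [sim_config()] (grid, smoothing and noise scales).
#' @return `n x V` matrix of contrast maps with `dims` attribute.
#' @export
simulate_null_contrast_maps <- function(n, config) {
  d <- config$grid_dims
  out <- local_seed(substream_seed(config$rng_seed, "null_contrast"), {
    m <- matrix(NA_real_, n, prod(d))
    for (i in seq_len(n))
      m[i, ] <- as.vector(random_field(d, config$field_smooth_sigma,
                                       sd = config$noise_sd))
    m
  })
  attr(out, "dims") <- d
  out
}

#' Expected similarity coefficient for a planted loading
#'
#' The population Pearson correlation between a participant's normative
#' deviation map and the template under the generative model. Without a
#' template the nuisance-free form
#' \eqn{r = \lambda / \sqrt{\lambda^2 + \sigma^2}} is returned. With the
#' template supplied, the formula additionally accounts for normative
#' referencing: the HC residual SE at voxel `v` is
#' \eqn{\sqrt{\sigma_\lambda^2 T_v^2 + \sigma^2}} (loading variance
#' concentrates exactly where the template lives), so deviations are
#' shrunk most in template voxels and the expected correlation is
#' computed from the voxelwise moments of the rescaled template. Used to
#' define the "true" Fisher-z similarity that symptom generation couples
#' to.
#'
#' @param loading Individual loading(s) \eqn{\lambda_i}.
#' @param config A [sim_config()].
#' @param template Optional 3D template array (any scale; normalised
#'   internally).
#' @return Expected Fisher-z similarity, same length as `loading`.
#' @export
expected_fisher_z <- function(loading, config, template = NULL) {
  s2 <- config$noise_sd^2
  if (is.null(template)) {
    r <- loading / sqrt(loading^2 + s2)
    return(atanh(r))
  }
  tv <- as.vector(template) / sd(as.vector(template))
  se2 <- config$loading_sd^2 * tv^2 + s2
  u <- tv / sqrt(se2)
  cov_ut <- mean(u * tv) - mean(u) * mean(tv)
  var_u <- mean(u^2) - mean(u)^2
  var_t <- mean(tv^2) - mean(tv)^2
  noise_var <- mean(s2 / se2)
  r <- loading * cov_ut /
    sqrt((loading^2 * var_u + noise_var) * var_t)
  atanh(r)
}
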