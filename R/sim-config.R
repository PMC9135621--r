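VALID_GROUPS <- c("HC", "SZ", "ESZ", "CHR-P")

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator: grid geometry,
#' cohort composition, acquisition timing, planted template loadings per
#' group, nuisance field scales, and the symptom-generation model. The
#' defaults describe the study conditions the generator emulates: a
#' 24x24x24 voxel grid, TR = 2 s, 210 volumes per run, three runs per drug
#' condition, and an early-illness cohort of 85 HC / 45 CHR-P / 74 ESZ with
#' template loadings 0 / 0.15 / 0.30.
#'
#' @param grid_dims Three positive integers, the voxel grid.
#' @param n_per_group Named integer vector, participants per group; names
#'   must come from `HC`, `SZ`, `ESZ`, `CHR-P`.
#' @param n_sites Number of acquisition sites (assigned round-robin).
#' @param sexes Sex labels assigned round-robin within group.
#' @param tr_seconds Repetition time in seconds.
#' @param n_timepoints Volumes per BOLD run.
#' @param runs_per_condition Runs per infusion phase within a session day.
#' @param template_loading Named numeric vector: mean template loading
#'   \eqn{\lambda_g} per group, in map-SD units per template-SD.
#' @param loading_sd Within-group SD of individual loadings \eqn{\lambda_i}.
#' @param site_offset_sd Marginal SD of each site's smooth offset field.
#' @param age_slope_sd Marginal SD of the per-voxel linear age slope field
#'   (map units per year).
#' @param age_center Age (years) at which the age effect is zero.
#' @param baseline_sd Marginal SD of the shared smooth baseline field.
#' @param noise_sd SD of independent voxel noise added to connectivity maps.
#' @param bold_noise_sd SD of independent noise added to BOLD time-series.
#' @param field_smooth_sigma Smoothing SD (voxels) for all random fields.
#' @param coupling_increase Maximum seed-coupling increase planted in
#'   "sensory" template voxels under active drug.
#' @param symptom_slope Symptom score units per unit Fisher-z similarity
#'   (planted only in the hallucination-analogue domain).
#' @param symptom_intercept Latent symptom intercept (score units).
#' @param symptom_noise_sd SD of latent Gaussian symptom noise.
#' @param subthreshold_fraction Fraction of participants whose global
#'   severity rating falls below 2 (exercising the inclusion filter).
#' @param rng_seed Root seed; every stream in the generator derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [sim_config_fbirn()], [sim_config_ketamine()]
#' @export
#' @examples
#' cfg <- sim_config(n_per_group = c(HC = 10, ESZ = 10), n_sites = 2)
#' cfg$grid_dims
sim_config <- function(grid_dims = c(24L, 24L, 24L),
                       n_per_group = c(HC = 85L, `CHR-P` = 45L, ESZ = 74L),
                       n_sites = 3L,
                       sexes = c("M", "F"),
                       tr_seconds = 2,
                       n_timepoints = 210L,
                       runs_per_condition = 3L,
                       template_loading = c(HC = 0, `CHR-P` = 0.15,
                                            ESZ = 0.3, SZ = 0.3),
                       loading_sd = 0.2,
                       site_offset_sd = 0.1,
                       age_slope_sd = 0.005,
                       age_center = 30,
                       baseline_sd = 0.3,
                       noise_sd = 1,
                       bold_noise_sd = 1,
                       field_smooth_sigma = 1.5,
                       coupling_increase = 0.5,
                       symptom_slope = 4,
                       symptom_intercept = 6,
                       symptom_noise_sd = 2,
                       subthreshold_fraction = 0.3,
                       rng_seed = 20220414L) {
  cfg <- list(
    grid_dims = as.integer(grid_dims),
    n_per_group = n_per_group,
    n_sites = as.integer(n_sites),
    sexes = sexes,
    tr_seconds = tr_seconds,
    n_timepoints = as.integer(n_timepoints),
    runs_per_condition = as.integer(runs_per_condition),
    template_loading = template_loading,
    loading_sd = loading_sd,
    site_offset_sd = site_offset_sd,
    age_slope_sd = age_slope_sd,
    age_center = age_center,
    baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    bold_noise_sd = bold_noise_sd,
    field_smooth_sigma = field_smooth_sigma,
    coupling_increase = coupling_increase,
    symptom_slope = symptom_slope,
    symptom_intercept = symptom_intercept,
    symptom_noise_sd = symptom_noise_sd,
    subthreshold_fraction = subthreshold_fraction,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  d <- cfg$grid_dims
  if (length(d) != 3L || any(!is.finite(d)) || any(d < 1L))
    stop("grid_dims must be three positive integers", call. = FALSE)
  # seed and template regions each occupy >= 8 voxels; require room for both
  if (prod(d) < 64L || any(d < 8L))
    stop("grid too small: each dimension must be >= 8 voxels to host the ",
         "seed and template regions", call. = FALSE)
  n <- cfg$n_per_group
  if (is.null(names(n)) || any(!nzchar(names(n))))
    stop("n_per_group must be a named vector", call. = FALSE)
  bad <- setdiff(names(n), VALID_GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; valid labels are ", paste(VALID_GROUPS, collapse = ", "),
         call. = FALSE)
  if (any(n < 1L)) stop("all group counts must be >= 1", call. = FALSE)
  missing_lambda <- setdiff(names(n), names(cfg$template_loading))
  if (length(missing_lambda))
    stop("template_loading missing for group(s): ",
         paste(missing_lambda, collapse = ", "), call. = FALSE)
  stopifnot(cfg$n_sites >= 1L, cfg$tr_seconds > 0, cfg$n_timepoints >= 1L,
            cfg$runs_per_condition >= 1L, cfg$noise_sd > 0,
            cfg$site_offset_sd >= 0, cfg$age_slope_sd >= 0,
            cfg$loading_sd >= 0, cfg$bold_noise_sd >= 0,
            cfg$subthreshold_fraction >= 0, cfg$subthreshold_fraction <= 1)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  grid:", paste(x$grid_dims, collapse = "x"),
      " sites:", x$n_sites, " TR:", x$tr_seconds, "s x", x$n_timepoints,
      "volumes\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$n_per_group),
                                 x$n_per_group), collapse = ", "), "\n")
  cat("  loadings:", paste(sprintf("%s=%.2f", names(x$template_loading),
                                   x$template_loading), collapse = ", "),
      " (within-group sd ", x$loading_sd, ")\n", sep = "")
  cat("  noise_sd:", x$noise_sd, " seed:", x$rng_seed, "\n")
  invisible(x)
}

#' Preset configurations for the emulated study arms
#'
#' `sim_config_fbirn()` emulates the multi-site chronic-illness arm
#' (183 SZ / 178 HC across seven sites, site-referenced normative model);
#' `sim_config_ketamine()` emulates the single-site pharmacological arm
#' (18 healthy male volunteers with multi-run two-condition drug sessions);
#' `sim_config_early()` is the early-illness arm and equals the
#' [sim_config()] defaults (85 HC / 45 CHR-P / 74 ESZ, age-referenced
#' normative model).
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_fbirn <- function(...) {
  args <- list(n_per_group = c(HC = 178L, SZ = 183L), n_sites = 7L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' @rdname sim_config_fbirn
#' @export
sim_config_ketamine <- function(...) {
  args <- list(n_per_group = c(HC = 18L), n_sites = 1L, sexes = "M")
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' @rdname sim_config_fbirn
#' @export
sim_config_early <- function(...) {
  do.call(sim_config, list(...))
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  # named vectors must become YAML maps, not bare sequences
  for (nm in c("n_per_group", "template_loading"))
    out[[nm]] <- as.list(out[[nm]])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("n_per_group", "template_loading"))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
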