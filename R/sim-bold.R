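DAY_LABELS <- c("PL-PK", "PL-AK", "AL-AK")
BOLD_CONDITIONS <- c("saline", "placebo_ketamine", "active_ketamine",
                     "lamotrigine_ketamine")

day_drug_condition <- function(day) {
  switch(day,
         "PL-PK" = "placebo_ketamine",
         "PL-AK" = "active_ketamine",
         "AL-AK" = "lamotrigine_ketamine",
         stop("unknown session day label: ", day, call. = FALSE))
}

# Condition-dependent voxelwise seed-coupling field. Baseline coupling is a
# smooth field shared by all participants; seed voxels carry the latent
# signal with unit coupling; active-drug conditions add a coupling increase
# proportional to the planted template pattern in "sensory" voxels.
# Lamotrigine pre-treatment does not attenuate the increase (the phenomenon
# the generator emulates).
coupling_field <- function(condition, config, seed_mask, pattern) {
  if (!condition %in% BOLD_CONDITIONS)
    stop("unknown condition: ", condition, call. = FALSE)
  d <- config$grid_dims
  w <- local_seed(substream_seed(config$rng_seed, "coupling"),
                  random_field(d, config$field_smooth_sigma,
                               sd = 0.15, mean = 0.3))
  w[seed_mask] <- 1
  if (condition %in% c("active_ketamine", "lamotrigine_ketamine")) {
    w <- w + config$coupling_increase * pmax(pattern, 0) / max(pattern)
  }
  w
}

#' Simulate one BOLD run
#'
#' Every voxel follows `w_v(condition) * s(t) + drift_v(t) + N(0, sd)`,
#' where `s(t)` is a run-specific latent seed time-series (AR(1), unit SD)
#' shared by all seed voxels, `w_v` is the condition-dependent coupling
#' field, and drift is linear with a small random per-voxel coefficient.
#'
#' @param participant One cohort row.
#' @param day Session day label: `"PL-PK"`, `"PL-AK"`, or `"AL-AK"`.
#' @param run_index Run number within the session (1-based).
#' @param config A [sim_config()].
#' @param seed_mask Logical 3D array marking the seed region.
#' @param pattern Planted template pattern ([simulate_template_pattern()]).
#' @return A `bold_run`: list with 4D `data` (x, y, z, t), `tr_seconds`,
#'   `run_index`, `condition`, `participant`.
#' @export
simulate_bold_run <- function(participant, day, run_index, config,
                              seed_mask, pattern) {
  d <- config$grid_dims
  if (!any(seed_mask)) stop("empty seed mask", call. = FALSE)
  nt <- config$n_timepoints
  # runs 1..runs_per_condition are always the initial saline phase
  condition <- if (run_index <= config$runs_per_condition) "saline"
               else day_drug_condition(day)
  w <- coupling_field(condition, config, seed_mask, pattern)
  run_seed <- substream_seed(config$rng_seed, "bold", participant$id,
                             day, run_index)
  data <- local_seed(run_seed, {
    s <- as.numeric(stats::filter(rnorm(nt), 0.4, method = "recursive"))
    s <- (s - mean(s)) / sd(s)
    drift_coef <- array(rnorm(prod(d), 0, 0.1), dim = d)
    noise <- array(rnorm(prod(d) * nt, 0, config$bold_noise_sd),
                   dim = c(prod(d), nt))
    tt <- seq_len(nt) / nt - 0.5
    y <- as.vector(w) %o% s + as.vector(drift_coef) %o% tt + noise
    array(y, dim = c(d, nt))
  })
  structure(list(data = data, tr_seconds = config$tr_seconds,
                 run_index = as.integer(run_index), condition = condition,
                 participant = participant$id),
            class = "bold_run")
}

#' Simulate a full two-phase session day
#'
#' Runs `1..runs_per_condition` during the initial saline infusion, then
#' `runs_per_condition` further runs under the day's drug condition.
#'
#' @inheritParams simulate_bold_run
#' @return List of `bold_run` objects (length `2 * runs_per_condition`).
#' @export
simulate_bold_session <- function(participant, day, config, seed_mask,
                                  pattern) {
  lapply(seq_len(2L * config$runs_per_condition), function(r)
    simulate_bold_run(participant, day, r, config, seed_mask, pattern))
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s run %d (%s): %dx%dx%d x %d volumes, TR %gs\n",
              x$participant, x$run_index, x$condition,
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}
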