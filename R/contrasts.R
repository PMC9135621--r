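check_same_grid <- function(maps) {
  d <- dim(maps[[1]])
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]), d))
      stop("map ", i, " grid ", paste(dim(maps[[i]]), collapse = "x"),
           " does not match ", paste(d, collapse = "x"), call. = FALSE)
  }
  invisible(d)
}

#' Fixed-effects combination of run-level maps
#'
#' Voxelwise unweighted mean across runs — the within-participant
#' fixed-effects average used before contrasting (equal-length runs, no
#' per-run variance weighting).
#'
#' @param maps Non-empty list of 3D arrays on one grid.
#' @return 3D array.
#' @export
fixed_effects_average <- function(maps) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) == 0L) stop("no maps to average", call. = FALSE)
  d <- check_same_grid(maps)
  out <- Reduce(`+`, maps) / length(maps)
  array(out, dim = d)
}

#' Within-day contrast: drug phase minus saline phase
#'
#' `mean(late runs) - mean(early runs)`. Degenerate single-run phases are
#' supported (e.g. a participant whose middle runs were dropped, leaving
#' run 6 versus run 1).
#'
#' @param late List of run maps from the drug phase.
#' @param early List of run maps from the initial saline phase.
#' @return 3D contrast array.
#' @export
within_day_contrast <- function(late, early) {
  if (!is.list(late)) late <- list(late)
  if (!is.list(early)) early <- list(early)
  if (length(late) == 0L || length(early) == 0L)
    stop("both phases need at least one run", call. = FALSE)
  check_same_grid(c(late, early))
  fixed_effects_average(late) - fixed_effects_average(early)
}

#' Between-day contrast: active versus placebo within-day contrasts
#'
#' Voxelwise `active - placebo` of two within-day contrasts from the same
#' participant; day-specific additive offsets have already cancelled in
#' the within-day differencing, so this isolates the drug effect while
#' accounting for run-order effects.
#'
#' @param day_active Within-day contrast map for the active-drug day.
#' @param day_placebo Within-day contrast map for the placebo day.
#' @param participant Optional id attached to both maps for a consistency
#'   check.
#' @return 3D contrast array.
#' @export
between_day_contrast <- function(day_active, day_placebo,
                                 participant = NULL) {
  pa <- attr(day_active, "participant")
  pp <- attr(day_placebo, "participant")
  if (!is.null(pa) && !is.null(pp) && !identical(pa, pp))
    stop("participant mismatch between days: ", pa, " vs ", pp,
         call. = FALSE)
  check_same_grid(list(day_active, day_placebo))
  out <- day_active - day_placebo
  if (!is.null(participant)) attr(out, "participant") <- participant
  out
}
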