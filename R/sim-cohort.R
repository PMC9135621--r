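#' Simulate a participant cohort
#'
#' Draws one participant table under a `sim_config`: unique ids, group
#' labels, round-robin site and sex assignment, ages, and individual
#' template loadings \eqn{\lambda_i \sim N(\lambda_g, \sigma_\lambda)}.
#' Each participant draws from an id-keyed substream of the root seed, so
#' enlarging a group extends the cohort without reshuffling existing rows.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `id`, `group`, `site`, `age`, `sex`,
#'   `loading`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_per_group = c(HC = 4, ESZ = 4)))
#' table(coh$group, coh$site)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_group
  rows <- lapply(names(n), function(g) {
    idx <- seq_len(n[[g]])
    id <- sprintf("%s%03d", gsub("-", "", g), idx)
    site <- ((idx - 1L) %% config$n_sites) + 1L
    # sex cycles at period n_sites so site and sex stay crossed, not aliased
    sex <- config$sexes[(((idx - 1L) %/% config$n_sites) %%
                           length(config$sexes)) + 1L]
    lambda_g <- config$template_loading[[g]]
    draws <- vapply(id, function(pid) {
      local_seed(substream_seed(config$rng_seed, "participant", pid), {
        c(age = runif(1, 18, 45),
          loading = rnorm(1, lambda_g, config$loading_sd))
      })
    }, numeric(2))
    data.frame(id = id, group = g, site = site,
               age = round(draws["age", ], 1), sex = sex,
               loading = unname(draws["loading", ]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$id), all(out$age > 0))
  out
}
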