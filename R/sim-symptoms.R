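#' Symptom rating domains handled by the generator and scorer
#'
#' Positive (SAPS) and negative (SANS) symptom domains with their item
#' counts, plus the four psychosis-risk (SOPS) domains. SAPS/SANS domain
#' scores are item sum + global rating with a global >= 2 inclusion rule;
#' SOPS scores are plain item sums with no global rating.
#'
#' @format Named list of named integer vectors (items per domain).
#' @export
SYMPTOM_DOMAINS <- list(
  SAPS = c(Hallucinations = 6L, Delusions = 12L,
           `Bizarre Behavior` = 4L, `Thought Disorder` = 8L),
  SANS = c(`Affective Flattening` = 7L, Alogia = 4L,
           `Avolition-Apathy` = 3L, `Anhedonia-Asociality` = 4L),
  SOPS = c(Positive = 5L, Negative = 6L, Disorganized = 4L, General = 4L)
)

# the single domain whose latent score is coupled to the similarity
# coefficient; all other domains have slope 0
COUPLED_DOMAIN <- "Hallucinations"

#' Simulate symptom item ratings for one participant
#'
#' Each domain's total score (item sum plus global rating for SAPS/SANS,
#' item sum for SOPS) is `round(max(0, intercept + slope * z + noise))`
#' with Gaussian latent noise, so the planted slope lives on the same
#' scale the downstream regressions analyse; the slope equals
#' `config$symptom_slope` for the hallucination-analogue domain and 0
#' elsewhere. For SAPS/SANS the global severity rating tracks overall
#' severity, except that `config$subthreshold_fraction` of participants
#' receive a sub-threshold global (< 2) to exercise the inclusion
#' filter; the item ratings absorb the remainder of the total, spread
#' evenly.
#'
#' @param participant One cohort row.
#' @param true_fisher_z The participant's true (generative) Fisher-z
#'   similarity, e.g. [expected_fisher_z()] of their loading.
#' @param config A [sim_config()].
#' @param scales Which rating scales to generate.
#' @return Long `data.frame`: `id`, `scale`, `domain`, `item` (`item1`,
#'   ..., `global`), `value`.
#' @export
simulate_symptoms <- function(participant, true_fisher_z, config,
                              scales = c("SAPS", "SANS")) {
  scales <- match.arg(scales, names(SYMPTOM_DOMAINS), several.ok = TRUE)
  rows <- list()
  local_seed(substream_seed(config$rng_seed, "symptoms", participant$id), {
    for (sc in scales) {
      for (dom in names(SYMPTOM_DOMAINS[[sc]])) {
        k <- SYMPTOM_DOMAINS[[sc]][[dom]]
        slope <- if (dom == COUPLED_DOMAIN) config$symptom_slope else 0
        latent <- config$symptom_intercept + slope * true_fisher_z +
          rnorm(1, 0, config$symptom_noise_sd)
        s <- round(max(0, latent))
        nm <- paste0("item", seq_len(k))
        if (sc != "SOPS") {
          glob <- if (runif(1) < config$subthreshold_fraction)
            min(sample(0:1, 1), s)
          else max(2L, min(5L, round(s / (k + 1))))
          item_total <- max(0L, s - glob)
          nm <- c(nm, "global")
        } else {
          glob <- NULL
          item_total <- s
        }
        q <- item_total %/% k; r <- item_total %% k
        items <- pmin(5L, q + as.integer(seq_len(k) <= r))
        vals <- c(items, glob)
        rows[[length(rows) + 1L]] <- data.frame(
          id = participant$id, scale = sc, domain = dom,
          item = nm, value = as.integer(vals), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

#' Simulate a symptom table for a cohort
#'
#' @param cohort A [simulate_cohort()] table.
#' @param fisher_z Numeric vector of true Fisher-z similarities, named by
#'   participant id (or in cohort order).
#' @param config A [sim_config()].
#' @param scales Rating scales to generate.
#' @return Long symptom `data.frame` (see [simulate_symptoms()]).
#' @export
simulate_symptom_table <- function(cohort, fisher_z, config,
                                   scales = c("SAPS", "SANS")) {
  if (!is.null(names(fisher_z))) fisher_z <- fisher_z[cohort$id]
  stopifnot(length(fisher_z) == nrow(cohort))
  do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    simulate_symptoms(cohort[i, ], fisher_z[i], config, scales)))
}
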