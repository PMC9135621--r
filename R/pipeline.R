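#' Antipsychotic dose equivalents for a simulated cohort
#'
#' Log-normal chlorpromazine-equivalent doses (mg/day) for patient rows,
#' weakly coupled to the participant's template loading (so the
#' medication-confound check has a small positive rank correlation to
#' find); a configurable fraction of patients is unmedicated (dose 0),
#' and non-patient rows get `NA`.
#'
#' @param cohort A [simulate_cohort()] table.
#' @param config A [sim_config()].
#' @param medicated_fraction Fraction of patients on antipsychotics.
#' @return Numeric vector of doses aligned with `cohort` rows.
#' @export
simulate_cpzeq <- function(cohort, config, medicated_fraction = 0.825) {
  patient <- cohort$group != "HC"
  out <- rep(NA_real_, nrow(cohort))
  local_seed(substream_seed(config$rng_seed, "cpzeq"), {
    n <- sum(patient)
    lat <- 5.5 + 0.4 * scale(cohort$loading[patient])[, 1] + rnorm(n, 0, 1)
    dose <- exp(lat)
    dose[runif(n) > medicated_fraction] <- 0
    out[patient] <- round(dose, 1)
  })
  out
}

#' Pipeline run configuration
#'
#' Bundles the three study-arm generator configurations with the
#' inference thresholds. The defaults are the shipped demo: an 18-male
#' pharmacological arm, a seven-site 178 HC / 183 SZ site-referenced arm,
#' and an 85 HC / 45 CHR-P / 74 ESZ age-referenced arm, all on one
#' 24x24x24 grid; CDT `|z| > 3.29`, corrected cluster p < 0.05 from
#' sign-flip permutations, FDR q = 0.05, interaction-drop and
#' skew-transform rules as documented.
#'
#' @param rng_seed Root seed fanned out to every stage.
#' @param ketamine,fbirn,early The three arm configurations
#'   ([sim_config()] objects sharing one grid).
#' @param seed_threshold Seed probability threshold.
#' @param cdt Cluster-defining |z| threshold.
#' @param alpha Corrected cluster significance level.
#' @param n_perm Sign-flip permutations.
#' @param q FDR level.
#' @param alpha_drop Interaction-dropping threshold.
#' @param skew_threshold Skewness threshold for the sqrt transform.
#' @return A `run_config` list.
#' @export
run_config <- function(rng_seed = 20220414L,
                       ketamine = sim_config_ketamine(rng_seed = rng_seed),
                       fbirn = sim_config_fbirn(
                         rng_seed = substream_seed(rng_seed, "fbirn")),
                       early = sim_config_early(
                         rng_seed = substream_seed(rng_seed, "early")),
                       seed_threshold = 0.8, cdt = 3.29, alpha = 0.05,
                       n_perm = 500L, q = 0.05, alpha_drop = 0.05,
                       skew_threshold = 1) {
  stopifnot(cdt > 0, alpha > 0, alpha < 1, q > 0, q < 1,
            seed_threshold > 0, seed_threshold <= 1,
            alpha_drop > 0, alpha_drop < 1, n_perm >= 100)
  if (!identical(ketamine$grid_dims, fbirn$grid_dims) ||
      !identical(ketamine$grid_dims, early$grid_dims))
    stop("all study arms must share one voxel grid", call. = FALSE)
  structure(list(rng_seed = as.integer(rng_seed), ketamine = ketamine,
                 fbirn = fbirn, early = early,
                 seed_threshold = seed_threshold, cdt = cdt,
                 alpha = alpha, n_perm = as.integer(n_perm), q = q,
                 alpha_drop = alpha_drop, skew_threshold = skew_threshold),
            class = "run_config")
}

#' Derive the drug dysconnectivity template from simulated sessions
#'
#' The pharmacological arm end-to-end: simulate each volunteer's
#' two-phase session days, fit the first-level seed GLM per run, form
#' within-day (drug minus saline) and between-day (active minus placebo)
#' fixed-effects contrasts, then run the group one-sample t-test with
#' permutation cluster-extent correction. The unthresholded group z-map
#' is the template.
#'
#' @param config A [run_config()].
#' @param days Which session days to simulate.
#' @return List with `template` (3D z array), `clusters`
#'   (`cluster_result`), `contrast_maps` (n x V), `condition_maps` (list
#'   of n x V matrices per drug condition), `cohort`, `seed`,
#'   `pattern`, and first-level masked-voxel counts.
#' @export
derive_template <- function(config, days = DAY_LABELS) {
  kc <- config$ketamine
  cohort <- simulate_cohort(kc)
  atlas <- simulate_seed_atlas(kc)
  seed <- threshold_seed(atlas, config$seed_threshold)
  pattern <- simulate_template_pattern(kc)
  nvox <- prod(kc$grid_dims)
  n <- nrow(cohort)
  rpc <- kc$runs_per_condition
  contrast <- matrix(NA_real_, n, nvox, dimnames = list(cohort$id, NULL))
  cond_maps <- list(placebo_ketamine = contrast, active_ketamine = contrast,
                    lamotrigine_ketamine = contrast)
  masked_out <- 0L
  for (i in seq_len(n)) {
    within <- list()
    for (day in days) {
      phase <- list(early = vector("list", rpc), late = vector("list", rpc))
      for (r in seq_len(2L * rpc)) {
        run <- simulate_bold_run(cohort[i, ], day, r, kc, seed$mask,
                                 pattern)
        des <- first_level_design(extract_seed_timeseries(run, seed))
        beta <- fit_first_level(run, des)
        masked_out <- masked_out + attr(beta, "n_masked_out")
        if (r <= rpc) phase$early[[r]] <- beta
        else phase$late[[r - rpc]] <- beta
      }
      within[[day]] <- within_day_contrast(phase$late, phase$early)
      drug <- day_drug_condition(day)
      if (drug %in% names(cond_maps))
        cond_maps[[drug]][i, ] <- as.vector(fixed_effects_average(
          phase$late))
    }
    if (all(c("PL-AK", "PL-PK") %in% days))
      contrast[i, ] <- as.vector(between_day_contrast(within[["PL-AK"]],
                                                      within[["PL-PK"]]))
  }
  attr(contrast, "dims") <- kc$grid_dims
  clusters <- cluster_threshold(contrast, cdt = config$cdt,
                                alpha = config$alpha,
                                n_perm = config$n_perm,
                                perm_seed = substream_seed(
                                  config$rng_seed, "perm"))
  list(template = clusters$zmap$data, clusters = clusters,
       contrast_maps = contrast, condition_maps = cond_maps,
       cohort = cohort, seed = seed, pattern = pattern,
       n_first_level_masked = masked_out)
}

#' ROI repeated-measures comparison across drug conditions
#'
#' Mean connectivity per significant cluster and condition, one
#' within-subject ANOVA per cluster, and BH FDR across the cluster-ANOVA
#' family.
#'
#' @param tpl A [derive_template()] result.
#' @return List with `roi_means` (list of participant x condition
#'   matrices), `anovas` (list of `rm_anova`), `omnibus_p_fdr`,
#'   `fdr_family`.
#' @export
roi_condition_anovas <- function(tpl) {
  labels <- tpl$clusters$labels
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L)
    return(list(roi_means = list(), anovas = list(),
                omnibus_p_fdr = numeric(0), fdr_family = 0L))
  dims <- dim(labels)
  conds <- names(tpl$condition_maps)
  roi_means <- lapply(ids, function(cl) {
    sapply(conds, function(cn) {
      m <- tpl$condition_maps[[cn]]
      apply(m, 1, function(row)
        mean(array(row, dims)[labels == cl]))
    })
  })
  names(roi_means) <- paste0("cluster", ids)
  anovas <- lapply(roi_means, repeated_measures_anova)
  omnibus <- vapply(anovas, `[[`, numeric(1), "p")
  adj <- fdr_bh(omnibus)
  list(roi_means = roi_means, anovas = anovas,
       omnibus_p_fdr = adj$p_adjusted, fdr_family = length(omnibus))
}

# one clinical arm: simulate maps, fit the HC normative model, z-score,
# correlate with the template, and run the group model
clinical_arm <- function(cfg, template, kind, include_site, alpha_drop) {
  cohort <- simulate_cohort(cfg)
  fields <- simulate_cohort_fields(cfg)
  maps <- simulate_study_maps(cohort, template, cfg, fields)
  hc <- cohort$group == "HC"
  model <- fit_normative(maps[hc, , drop = FALSE],
                         cohort[hc, , drop = FALSE], kind = kind,
                         dims = cfg$grid_dims)
  zmaps <- zscore_maps(maps, cohort, model)
  sim <- similarity_table(zmaps, template)
  groups <- group_anova(sim, cohort, include_site = include_site,
                        alpha_drop = alpha_drop,
                        group_levels = names(cfg$n_per_group))
  list(cohort = cohort, model = model, sim = sim, groups = groups,
       n_masked_voxels = sum(!model$mask))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in dependency order — template derivation from
#' the pharmacological arm, ROI condition ANOVAs, both clinical arms
#' (site- and age-referenced normative deviation maps, similarity
#' coefficients, group models), symptom regressions with the
#' interaction-dropping procedure, and the medication-confound check —
#' and writes all outputs (NIfTI volumes, TSV tables, JSON manifest)
#' under `out_dir`. Outputs are write-once: an existing non-empty
#' `out_dir` is refused unless `overwrite = TRUE`. Given the same
#' configuration the run is bit-reproducible.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory ", out_dir,
         " is not empty; outputs are write-once (use overwrite = TRUE)",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  tpl <- derive_template(config)
  write_map(tpl$template, p("template_z.nii"))
  write_map(tpl$clusters$labels + 0, p("cluster_labels.nii"))
  write_table_tsv(tpl$clusters$table, p("clusters.tsv"))
  roi <- roi_condition_anovas(tpl)

  fb <- clinical_arm(config$fbirn, tpl$template, kind = "site",
                     include_site = TRUE, alpha_drop = config$alpha_drop)
  ez <- clinical_arm(config$early, tpl$template, kind = "age",
                     include_site = FALSE, alpha_drop = config$alpha_drop)

  # chronic-arm symptom models (8 SAPS/SANS domains) + medication check
  sz <- fb$cohort[fb$cohort$group == "SZ", ]
  sz_true_z <- expected_fisher_z(sz$loading, config$fbirn, tpl$template)
  sz_sym <- simulate_symptom_table(sz, setNames(sz_true_z, sz$id),
                                   config$fbirn, c("SAPS", "SANS"))
  sz_scores <- compute_symptom_scores(sz_sym, config$skew_threshold)
  sz_reg <- symptom_regression(sz_scores, fb$sim, fb$cohort,
                               include_site = TRUE,
                               alpha_drop = config$alpha_drop,
                               q = config$q)
  cpz <- simulate_cpzeq(fb$cohort, config$fbirn)
  sz_cpz <- cpz[fb$cohort$group == "SZ"]
  confound <- spearman_confound(sz_cpz,
                                fb$sim$fisher_z[match(sz$id, fb$sim$id)])

  # early-arm symptom models: SAPS/SANS in ESZ (8), SOPS in CHR-P (4)
  esz <- ez$cohort[ez$cohort$group == "ESZ", ]
  esz_sym <- simulate_symptom_table(
    esz, setNames(expected_fisher_z(esz$loading, config$early, tpl$template), esz$id),
    config$early, c("SAPS", "SANS"))
  esz_reg <- symptom_regression(compute_symptom_scores(
    esz_sym, config$skew_threshold), ez$sim, ez$cohort,
    alpha_drop = config$alpha_drop, q = config$q)
  chr <- ez$cohort[ez$cohort$group == "CHR-P", ]
  chr_sym <- simulate_symptom_table(
    chr, setNames(expected_fisher_z(chr$loading, config$early, tpl$template), chr$id),
    config$early, "SOPS")
  chr_reg <- symptom_regression(compute_symptom_scores(
    chr_sym, config$skew_threshold), ez$sim, ez$cohort,
    alpha_drop = config$alpha_drop, q = config$q)

  write_table_tsv(cbind(fb$cohort, cpzeq = cpz), p("fbirn_phenotype.tsv"))
  write_table_tsv(fb$sim, p("fbirn_similarity.tsv"))
  write_table_tsv(ez$cohort, p("early_phenotype.tsv"))
  write_table_tsv(ez$sim, p("early_similarity.tsv"))
  write_table_tsv(sz_reg, p("sz_symptom_models.tsv"))
  write_table_tsv(esz_reg, p("esz_symptom_models.tsv"))
  write_table_tsv(chr_reg, p("chrp_symptom_models.tsv"))

  manifest <- list(
    package_version = as.character(packageVersion("ketsim")),
    rng_seed = config$rng_seed,
    config_hash = config_hash(config),
    thresholds = list(seed_threshold = config$seed_threshold,
                      cdt = config$cdt, alpha = config$alpha,
                      n_perm = config$n_perm, q = config$q,
                      alpha_drop = config$alpha_drop,
                      skew_threshold = config$skew_threshold),
    template = list(n_participants = nrow(tpl$cohort),
                    seed_voxels = tpl$seed$n_voxels,
                    n_clusters = nrow(tpl$clusters$table),
                    cluster_sizes = tpl$clusters$table$size,
                    first_level_masked_voxels = tpl$n_first_level_masked),
    fdr_families = list(roi_anovas = roi$fdr_family,
                        fbirn_pairwise = fb$groups$fdr_family,
                        early_pairwise = ez$groups$fdr_family,
                        sz_symptoms = attr(sz_reg, "fdr_family"),
                        esz_symptoms = attr(esz_reg, "fdr_family"),
                        chrp_symptoms = attr(chr_reg, "fdr_family")),
    masked_voxels = list(fbirn_normative = fb$n_masked_voxels,
                         early_normative = ez$n_masked_voxels),
    results = list(
      roi_anova_p_fdr = unname(roi$omnibus_p_fdr),
      fbirn = list(omnibus = fb$groups$omnibus,
                   pairwise = fb$groups$pairwise,
                   within = fb$groups$within),
      early = list(omnibus = ez$groups$omnibus,
                   pairwise = ez$groups$pairwise,
                   within = ez$groups$within),
      cpzeq_spearman = confound)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, template = tpl, roi = roi,
                 fbirn = fb, early = ez, sz_symptoms = sz_reg,
                 esz_symptoms = esz_reg, chrp_symptoms = chr_reg,
                 confound = confound))
}
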