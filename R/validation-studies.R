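#' Validation studies
#'
#' Self-contained simulation studies that probe the statistical
#' guarantees of the pipeline: oracle equivalence of the estimators,
#' calibration of normative deviation scores, family-wise type-I error of
#' the permutation cluster test, recovery of planted group loadings and
#' symptom slopes, and bit-reproducibility of a full run. They are used
#' by the test suite and by `scripts/acceptance.R`, and are exported so
#' users can re-run them at other settings.
#'
#' @name validation-studies
NULL

#' @describeIn validation-studies Maximum absolute disagreement between
#'   each estimator and an independent brute-force implementation on
#'   random small instances (first-level GLM, one-sample t,
#'   repeated-measures ANOVA, Pearson, Spearman, BH FDR).
#' @param seed Integer seed for the study.
#' @export
study_oracle_errors <- function(seed = 1L) {
  local_seed(substream_seed(seed, "oracle"), {
    errs <- c()
    # first-level GLM betas vs explicit normal equations
    nt <- 40L; d <- c(4L, 3L, 3L)
    run <- array(rnorm(prod(d) * nt), c(d, nt))
    des <- first_level_design(rnorm(nt),
                              nuisance = matrix(rnorm(nt * 2), nt))
    beta <- fit_first_level(run, des)
    XtXi <- solve(t(des$X) %*% des$X) %*% t(des$X)
    oracle <- apply(matrix(run, prod(d), nt), 1,
                    function(y) (XtXi %*% y)[1])
    errs["first_level_beta"] <- max(abs(as.vector(beta) - oracle))
    # one-sample t vs the textbook formula
    maps <- lapply(1:12, function(i) array(rnorm(60), c(5, 4, 3)))
    tm <- one_sample_t_map(maps)
    flat <- sapply(maps, as.vector)
    t_or <- apply(flat, 1, function(v) mean(v) / (sd(v) / sqrt(12)))
    errs["one_sample_t"] <- max(abs(as.vector(tm$data) - t_or))
    # repeated-measures ANOVA vs the sums-of-squares decomposition
    x <- matrix(rnorm(30), 10, 3)
    res <- repeated_measures_anova(x)
    gm <- mean(x)
    ss_cond <- nrow(x) * sum((colMeans(x) - gm)^2)
    ss_subj <- ncol(x) * sum((rowMeans(x) - gm)^2)
    ss_err <- sum((x - gm)^2) - ss_cond - ss_subj
    F_or <- (ss_cond / 2) / (ss_err / 18)
    errs["rm_anova_F"] <- abs(res$F - F_or)
    # Pearson similarity vs the covariance formula
    a <- array(rnorm(120), c(6, 5, 4)); b <- array(rnorm(120), c(6, 5, 4))
    r <- similarity_coefficient(a, b)$r
    av <- as.vector(a) - mean(a); bv <- as.vector(b) - mean(b)
    errs["pearson_r"] <- abs(r - sum(av * bv) /
                               sqrt(sum(av^2) * sum(bv^2)))
    # Spearman (with ties) vs rank-then-Pearson
    xs <- sample(1:6, 30, replace = TRUE)
    ys <- xs + sample(1:4, 30, replace = TRUE)
    errs["spearman_rho"] <- abs(spearman_confound(xs, ys)$rho -
                                  cor(rank(xs), rank(ys)))
    # BH FDR vs the explicit step-up minimum formula
    p <- runif(20)
    got <- fdr_bh(p)$p_adjusted
    o <- order(p); m <- length(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    adj <- pmin(adj, 1)[order(o)]
    errs["fdr_bh"] <- max(abs(got - adj))
    errs
  })
}

#' @describeIn validation-studies Held-out HC calibration of normative
#'   deviation z-scores: fits the site-referenced model on `n_hc` healthy
#'   controls and scores `n_holdout` more, returning the pooled mean and
#'   SD of the held-out deviations (which should approach 0 and 1).
#' @param n_hc HC used to fit the reference model.
#' @param n_holdout Held-out HC scored against it.
#' @export
study_normative_calibration <- function(seed = 1L, n_hc = 200L,
                                        n_holdout = 200L) {
  cfg <- sim_config(n_per_group = c(HC = n_hc + n_holdout),
                    rng_seed = substream_seed(seed, "calibration"))
  cohort <- simulate_cohort(cfg)
  template <- simulate_template_pattern(cfg)
  maps <- simulate_study_maps(cohort, template, cfg)
  fit_idx <- seq_len(n_hc)
  model <- fit_normative(maps[fit_idx, ], cohort[fit_idx, ],
                         kind = "site", dims = cfg$grid_dims)
  z <- zscore_maps(maps[-fit_idx, ], cohort[-fit_idx, ], model)
  vals <- z[, model$mask, drop = FALSE]
  list(mean = mean(vals), sd = sd(as.vector(vals)),
       n_hc = n_hc, n_holdout = n_holdout)
}

#' @describeIn validation-studies Family-wise type-I error of the
#'   permutation cluster test: fraction of null replicates (no planted
#'   effect) with at least one surviving cluster, with the binomial 95%
#'   band around the nominal level.
#' @param n_reps Null replicates.
#' @param n Participants per replicate.
#' @param n_perm Sign-flip permutations per replicate.
#' @param alpha Corrected cluster significance level.
#' @export
study_cluster_type1 <- function(seed = 1L, n_reps = 200L, n = 18L,
                                n_perm = 500L, alpha = 0.05) {
  hits <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(rng_seed = substream_seed(seed, "null", r))
    maps <- simulate_null_contrast_maps(n, cfg)
    res <- cluster_threshold(maps, alpha = alpha, n_perm = n_perm,
                             perm_seed = substream_seed(seed, "perm", r),
                             dims = cfg$grid_dims)
    nrow(res$table) > 0L
  }, logical(1))
  bounds <- stats::qbinom(c(0.025, 0.975), n_reps, alpha) / n_reps
  list(rate = mean(hits), lower = bounds[1], upper = bounds[2],
       n_reps = n_reps, alpha = alpha)
}

#' @describeIn validation-studies Recovery of planted group template
#'   loadings through the full normative + similarity path: fraction of
#'   replicate cohorts in which the group mean Fisher-z similarities
#'   reproduce the planted loading order (HC < CHR-P < ESZ).
#' @export
study_loading_recovery <- function(seed = 1L, n_reps = 100L) {
  template <- simulate_template_pattern(sim_config())
  ordered <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(rng_seed = substream_seed(seed, "order", r))
    cohort <- simulate_cohort(cfg)
    maps <- simulate_study_maps(cohort, template, cfg)
    hc <- cohort$group == "HC"
    model <- fit_normative(maps[hc, ], cohort[hc, ], kind = "age",
                           dims = cfg$grid_dims)
    z <- zscore_maps(maps, cohort, model)
    sim <- similarity_table(z, template)
    gm <- tapply(sim$fisher_z, cohort$group, mean)
    gm[["HC"]] < gm[["CHR-P"]] && gm[["CHR-P"]] < gm[["ESZ"]]
  }, logical(1))
  list(rate = mean(ordered), n_reps = n_reps)
}

#' @describeIn validation-studies Recovery of the planted symptom slope:
#'   replicate cohorts couple the hallucination-analogue score to the
#'   true Fisher-z similarity, and the common-slope regression on the
#'   measured similarity coefficients is compared with the planted value
#'   via its Monte-Carlo standard error.
#' @param n_patients Patients per replicate cohort.
#' @export
study_symptom_recovery <- function(seed = 1L, n_reps = 50L,
                                   n_patients = 100L) {
  template <- simulate_template_pattern(sim_config())
  slopes <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_per_group = c(HC = 100L, SZ = n_patients),
                      rng_seed = substream_seed(seed, "slope", r))
    cohort <- simulate_cohort(cfg)
    maps <- simulate_study_maps(cohort, template, cfg)
    hc <- cohort$group == "HC"
    model <- fit_normative(maps[hc, ], cohort[hc, ], kind = "site",
                           dims = cfg$grid_dims)
    sz <- cohort[!hc, ]
    z <- zscore_maps(maps[!hc, , drop = FALSE], sz, model)
    sim <- similarity_table(z, template)
    sym <- simulate_symptom_table(
      sz, setNames(expected_fisher_z(sz$loading, cfg, template), sz$id), cfg, "SAPS")
    scores <- compute_symptom_scores(sym, skew_threshold = Inf)
    res <- symptom_regression(scores, sim, sz, include_site = TRUE,
                              alpha_drop = 0)
    res$slope[res$domain == "Hallucinations"]
  }, numeric(1))
  list(mean_slope = mean(slopes),
       mc_se = sd(slopes) / sqrt(length(slopes)),
       true_slope = sim_config()$symptom_slope, n_reps = n_reps)
}

#' @describeIn validation-studies Bit-reproducibility: runs the full
#'   pipeline twice under one configuration and compares every output
#'   file byte for byte.
#' @param config A [run_config()]; the default demo configuration.
#' @export
study_determinism <- function(config = run_config()) {
  d1 <- tempfile("runA"); d2 <- tempfile("runB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  run_pipeline(config, d1)
  run_pipeline(config, d2)
  files <- sort(dir(d1))
  same <- vapply(files, function(f) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    identical(a, b)
  }, logical(1))
  list(identical = all(same) && identical(files, sort(dir(d2))),
       n_files = length(files), files = files,
       manifest = jsonlite::read_json(file.path(d1, "manifest.json")))
}
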