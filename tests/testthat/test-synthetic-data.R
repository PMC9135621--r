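test_that("cohort, BOLD and map generation are bit-reproducible", {
  cfg <- tiny_config()
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  coh <- simulate_cohort(cfg)
  tplp <- simulate_template_pattern(cfg)
  seed <- threshold_seed(simulate_seed_atlas(cfg), 0.8)
  r1 <- simulate_bold_run(coh[1, ], "PL-AK", 4, cfg, seed$mask, tplp)
  r2 <- simulate_bold_run(coh[1, ], "PL-AK", 4, cfg, seed$mask, tplp)
  expect_identical(r1$data, r2$data)
  expect_identical(simulate_study_maps(coh, tplp, cfg),
                   simulate_study_maps(coh, tplp, cfg))
  sym1 <- simulate_symptoms(coh[1, ], 0.2, cfg)
  expect_identical(sym1, simulate_symptoms(coh[1, ], 0.2, cfg))
})

test_that("adding participants extends a cohort without reshuffling", {
  small <- tiny_config(n_per_group = c(HC = 5L))
  big <- tiny_config(n_per_group = c(HC = 9L))
  c1 <- simulate_cohort(small)
  c2 <- simulate_cohort(big)
  expect_identical(c1, c2[seq_len(5), ])
})

test_that("zero template loading gives group mean loadings near zero", {
  lam0 <- c(HC = 0, ESZ = 0)
  draws <- unlist(lapply(seq_len(200), function(r) {
    cfg <- tiny_config(n_per_group = c(HC = 3L, ESZ = 3L),
                       template_loading = lam0,
                       rng_seed = substream_seed(7L, "rep", r))
    simulate_cohort(cfg)$loading
  }))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("a planted SZ-HC loading gap is recovered in nearly all cohorts", {
  wins <- vapply(seq_len(100), function(r) {
    cfg <- tiny_config(n_per_group = c(HC = 6L, SZ = 6L),
                       template_loading = c(HC = 0, SZ = 0.5),
                       rng_seed = substream_seed(11L, "rep", r))
    coh <- simulate_cohort(cfg)
    mean(coh$loading[coh$group == "SZ"]) >
      mean(coh$loading[coh$group == "HC"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("noise-free seed voxels recover unit first-level beta", {
  cfg <- tiny_config(bold_noise_sd = 0)
  coh <- simulate_cohort(cfg)
  seed <- threshold_seed(simulate_seed_atlas(cfg), 0.8)
  tplp <- simulate_template_pattern(cfg)
  run <- simulate_bold_run(coh[1, ], "PL-PK", 1, cfg, seed$mask, tplp)
  des <- first_level_design(extract_seed_timeseries(run, seed))
  beta <- fit_first_level(run, des)
  expect_equal(unname(beta[seed$mask]), rep(1, seed$n_voxels),
               tolerance = 1e-6)
})

test_that("zero coupling difference yields a null between-day contrast", {
  cfg <- tiny_config(bold_noise_sd = 0, coupling_increase = 0)
  coh <- simulate_cohort(cfg)
  seed <- threshold_seed(simulate_seed_atlas(cfg), 0.8)
  tplp <- simulate_template_pattern(cfg)
  within <- lapply(c("PL-PK", "PL-AK"), function(day) {
    betas <- lapply(seq_len(2L * cfg$runs_per_condition), function(r) {
      run <- simulate_bold_run(coh[1, ], day, r, cfg, seed$mask, tplp)
      fit_first_level(run,
                      first_level_design(extract_seed_timeseries(run, seed)))
    })
    within_day_contrast(betas[4:6], betas[1:3])
  })
  contrast <- between_day_contrast(within[[2]], within[[1]])
  expect_lt(max(abs(contrast)), 1e-7)
})

test_that("a planted coupling increase is recovered by cluster inference", {
  # near-noiseless end-to-end: sessions -> GLM -> contrasts -> clusters
  # (a little measurement noise keeps the one-sample t defined)
  # n = 8 keeps the two-sided sign-flip null resolvable below alpha
  cfg <- tiny_config(n_per_group = c(HC = 8L), bold_noise_sd = 0.05)
  coh <- simulate_cohort(cfg)
  seed <- threshold_seed(simulate_seed_atlas(cfg), 0.8)
  tplp <- simulate_template_pattern(cfg)
  contrasts <- lapply(seq_len(nrow(coh)), function(i) {
    within <- lapply(c("PL-PK", "PL-AK"), function(day) {
      betas <- lapply(seq_len(6L), function(r) {
        run <- simulate_bold_run(coh[i, ], day, r, cfg, seed$mask, tplp)
        fit_first_level(run, first_level_design(
          extract_seed_timeseries(run, seed)))
      })
      within_day_contrast(betas[4:6], betas[1:3])
    })
    between_day_contrast(within[[2]], within[[1]])
  })
  res <- cluster_threshold(contrasts, n_perm = 200, perm_seed = 5L)
  expect_gt(nrow(res$table), 0)
  # recovered clusters sit on the planted pattern's positive support and
  # overlap its core blocks
  expect_true(all(tplp[res$labels > 0] > 0))
  expect_true(any((tplp > 0.5)[res$labels > 0]))
})

test_that("symptom generation couples only through the planted slope", {
  cfg <- tiny_config(symptom_noise_sd = 0, symptom_slope = 2,
                     subthreshold_fraction = 0)
  coh <- simulate_cohort(tiny_config(n_per_group = c(HC = 50L)))
  zs <- seq(0, 5, length.out = 50)
  tab <- simulate_symptom_table(coh, setNames(zs, coh$id), cfg, "SAPS")
  sc <- compute_symptom_scores(tab, skew_threshold = Inf)
  hall <- sc[sc$domain == "Hallucinations", ]
  hall <- hall[match(coh$id, hall$id), ]
  fit <- lm(scale(hall$raw) ~ scale(zs))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  # uncoupled domain carries no slope (noise-free: constant latent score)
  del <- sc[sc$domain == "Delusions", ]
  expect_equal(sd(del$raw[match(coh$id, del$id)]), 0)
})

test_that("the configured fraction falls below the inclusion cut-off", {
  cfg <- tiny_config(subthreshold_fraction = 0.3)
  coh <- simulate_cohort(tiny_config(n_per_group = c(HC = 150L, SZ = 150L)))
  tab <- simulate_symptom_table(coh, setNames(rep(0.2, 300), coh$id), cfg,
                                "SAPS")
  sc <- compute_symptom_scores(tab)
  frac <- mean(!sc$included[sc$domain == "Hallucinations"])
  expect_gt(frac, 0.3 - 3 * sqrt(0.3 * 0.7 / 300))
  expect_lt(frac, 0.3 + 3 * sqrt(0.3 * 0.7 / 300))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_per_group = c(PATIENT = 5L)), "unknown group")
  expect_error(sim_config(grid_dims = c(4, 4, 4)), "grid too small")
  expect_error(sim_config(n_per_group = c(HC = 0L)), ">= 1")
  expect_error(sim_config(n_per_group = c(HC = 5L),
                          template_loading = c(SZ = 1)), "template_loading")
})
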