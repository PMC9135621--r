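make_long <- function(id, domain, items, global = NULL, scale = "SAPS") {
  nm <- paste0("item", seq_along(items))
  val <- items
  if (!is.null(global)) { nm <- c(nm, "global"); val <- c(val, global) }
  data.frame(id = id, scale = scale, domain = domain, item = nm,
             value = as.integer(val), stringsAsFactors = FALSE)
}

test_that("symptom scores follow the sum-plus-global rule and filter", {
  tab <- rbind(make_long("a", "Hallucinations", c(2, 3, 0, 1), 3),
               make_long("b", "Hallucinations", c(5, 5, 4, 3), 1),
               make_long("c", "Hallucinations", c(0, 0, 0, 0), 2))
  sc <- compute_symptom_scores(tab, skew_threshold = Inf)
  expect_equal(sc$raw[sc$id == "a"], 9)
  expect_false(sc$included[sc$id == "b"]) # global = 1: below mild
  expect_true(sc$included[sc$id == "c"])
  expect_false(any(sc$transformed))
  expect_equal(sc$score, sc$raw)
  expect_error(compute_symptom_scores(transform(tab, value = value - 10)),
               "negative")
})

test_that("skewed domains are square-root transformed domain-wide", {
  # heavily right-skewed included raw scores trip the transform
  ids <- sprintf("p%02d", 1:12)
  raws <- c(rep(2, 9), 16, 25, 9) # skewness > 1
  tab <- do.call(rbind, lapply(seq_along(ids), function(i)
    make_long(ids[i], "Hallucinations", c(raws[i] - 2, 0, 0, 0), 2)))
  tab$value <- pmax(tab$value, 0)
  sc <- compute_symptom_scores(tab, skew_threshold = 1)
  expect_true(all(sc$transformed))
  expect_equal(sc$score, sqrt(sc$raw))
  expect_equal(sc$score[sc$raw == 9], 3)
})

test_that("group model reproduces known degrees of freedom", {
  # three groups (85/45/74) with a sex main effect: residual df = 200
  cfg <- sim_config(rng_seed = 77L)
  coh <- simulate_cohort(cfg)
  sim <- data.frame(id = coh$id,
                    fisher_z = withr::with_seed(77L, rnorm(nrow(coh))))
  ga <- group_anova(sim, coh, include_site = FALSE, alpha_drop = 0,
                    group_levels = c("HC", "CHR-P", "ESZ"))
  expect_equal(ga$omnibus$df2, 204L - 4L)
  expect_equal(ga$omnibus$df2, 200L)
  expect_equal(ga$omnibus$df1, 2L)
  expect_equal(nrow(ga$pairwise), 3L)
  expect_equal(ga$fdr_family, 3L)
  expect_true(all(ga$pairwise$p_fdr >= ga$pairwise$p - 1e-15))
})

test_that("covariate-free two-group d reduces to classical pooled d", {
  set.seed(19)
  n <- 40
  dat <- data.frame(id = sprintf("p%02d", 1:n),
                    group = rep(c("HC", "SZ"), each = n / 2),
                    sex = "M", site = 1,
                    stringsAsFactors = FALSE)
  sim <- data.frame(id = dat$id,
                    fisher_z = rnorm(n) + 0.8 * (dat$group == "SZ"))
  ga <- group_anova(sim, dat, include_site = FALSE)
  x <- sim$fisher_z[dat$group == "HC"]; y <- sim$fisher_z[dat$group == "SZ"]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  d_classic <- (mean(y) - mean(x)) / sp
  expect_equal(ga$pairwise$d, d_classic, tolerance = 1e-10)
  expect_equal(ga$pairwise$estimate, mean(y) - mean(x), tolerance = 1e-10)
})

test_that("adjusted means and contrasts agree with emmeans", {
  set.seed(20)
  n <- 60
  dat <- data.frame(id = sprintf("p%02d", 1:n),
                    group = sample(c("HC", "SZ"), n, TRUE),
                    sex = sample(c("M", "F"), n, TRUE),
                    site = sample(1:3, n, TRUE), stringsAsFactors = FALSE)
  sim <- data.frame(id = dat$id, fisher_z = rnorm(n))
  ga <- group_anova(sim, dat, include_site = TRUE, alpha_drop = 0,
                    group_levels = c("HC", "SZ"))
  em <- emmeans::emmeans(ga$model, "group")
  es <- as.data.frame(em)
  expect_equal(ga$within$mean_fisher_z, es$emmean, tolerance = 1e-8)
  ec <- as.data.frame(emmeans::contrast(em, "revpairwise"))
  expect_equal(ga$pairwise$estimate, ec$estimate, tolerance = 1e-8)
  expect_equal(ga$pairwise$t, ec$t.ratio, tolerance = 1e-8)
})

test_that("group model names empty cells and aliased terms", {
  dat <- data.frame(id = c("a", "b", "c", "d"),
                    group = c("HC", "HC", "SZ", "SZ"),
                    sex = c("M", "M", "F", "F"), stringsAsFactors = FALSE)
  sim <- data.frame(id = dat$id, fisher_z = rnorm(4))
  expect_error(group_anova(sim, dat), "empty design cell")
})

test_that("perfect linear symptom coupling gives unit standardized slope", {
  n <- 40
  set.seed(21)
  fz <- rnorm(n)
  scores <- data.frame(id = sprintf("p%02d", 1:n), scale = "SAPS",
                       domain = "Hallucinations", raw = fz, score = fz,
                       included = TRUE, transformed = FALSE,
                       stringsAsFactors = FALSE)
  sim <- data.frame(id = scores$id, fisher_z = fz)
  cov <- data.frame(id = scores$id,
                    sex = rep(c("M", "F"), n / 2),
                    stringsAsFactors = FALSE)
  res <- suppressWarnings(symptom_regression(scores, sim, cov))
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_false(res$interaction_retained)
})

test_that("a planted interaction switches to per-sex slopes", {
  n <- 120
  set.seed(22)
  fz <- rnorm(n)
  sex <- rep(c("M", "F"), n / 2)
  sc <- ifelse(sex == "M", 2 * fz, -2 * fz) + rnorm(n, 0, 0.1)
  scores <- data.frame(id = sprintf("p%03d", 1:n), scale = "SAPS",
                       domain = "Hallucinations", raw = sc, score = sc,
                       included = TRUE, transformed = FALSE,
                       stringsAsFactors = FALSE)
  sim <- data.frame(id = scores$id, fisher_z = fz)
  cov <- data.frame(id = scores$id, sex = sex, stringsAsFactors = FALSE)
  res <- symptom_regression(scores, sim, cov)
  expect_true(res$interaction_retained)
  expect_equal(res$slope_M, 2, tolerance = 0.1)
  expect_equal(res$slope_F, -2, tolerance = 0.1)
  expect_true(is.na(res$beta))
})

test_that("single-sex subsamples fall back to the common slope", {
  n <- 20
  set.seed(23)
  fz <- rnorm(n)
  scores <- data.frame(id = sprintf("p%02d", 1:n), scale = "SOPS",
                       domain = "Positive", raw = fz, score = 2 * fz,
                       included = TRUE, transformed = FALSE,
                       stringsAsFactors = FALSE)
  sim <- data.frame(id = scores$id, fisher_z = fz)
  cov <- data.frame(id = scores$id, sex = "M", stringsAsFactors = FALSE)
  w <- capture_warnings(res <- symptom_regression(scores, sim, cov))
  expect_true(any(grepl("single-sex", w)))
  expect_equal(res$slope, 2, tolerance = 1e-10)
})

test_that("standardized slope ignores affine outcome rescaling", {
  n <- 50
  set.seed(24)
  fz <- rnorm(n)
  sc <- 1.5 * fz + rnorm(n, 0, 0.5)
  mk <- function(s) data.frame(id = sprintf("p%02d", 1:n), scale = "SAPS",
                               domain = "Hallucinations", raw = s,
                               score = s, included = TRUE,
                               transformed = FALSE,
                               stringsAsFactors = FALSE)
  sim <- data.frame(id = sprintf("p%02d", 1:n), fisher_z = fz)
  cov <- data.frame(id = sim$id, sex = rep(c("M", "F"), n / 2),
                    stringsAsFactors = FALSE)
  b1 <- symptom_regression(mk(sc), sim, cov)$beta
  b2 <- symptom_regression(mk(10 * sc + 3), sim, cov)$beta
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("Spearman confound check matches rank-then-Pearson", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6) # ties included
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  got <- spearman_confound(x, y)
  oracle <- cor(rank(x), rank(y))
  expect_equal(got$rho, oracle, tolerance = 1e-10)
  xs <- 1:8
  expect_equal(spearman_confound(xs, xs * 2)$rho, 1)
  expect_equal(spearman_confound(xs, rev(xs))$rho, -1)
  expect_error(spearman_confound(1:3, 1:3), "at least 5")
  expect_error(spearman_confound(rep(1, 6), 1:6), "constant")
})

test_that("Cohen's d is the adjusted difference over residual SD", {
  expect_equal(cohens_d(0, 1.3), 0)
  expect_equal(cohens_d(1, 1), 1)
  expect_error(cohens_d(1, 0), "positive")
})
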