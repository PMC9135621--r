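#' Sample skewness
#'
#' Moment coefficient `g1 = m3 / m2^(3/2)`.
#'
#' @param x Numeric vector.
#' @return Skewness (NA for fewer than 3 values or zero variance).
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Domain symptom scores from item ratings
#'
#' For each scale/domain: the raw score is the item sum plus the global
#' severity rating (SAPS/SANS) or the plain item sum (SOPS); SAPS/SANS
#' participants are included only with a global rating of at least 2
#' (mild). When the sample skewness of the included raw scores exceeds
#' `skew_threshold`, the whole domain is square-root transformed.
#'
#' @param symptoms Long table from [simulate_symptom_table()] (columns
#'   `id`, `scale`, `domain`, `item`, `value`) or equivalent.
#' @param skew_threshold Skewness above which the sqrt transform fires.
#' @return Data frame: `id`, `scale`, `domain`, `raw`, `score`,
#'   `included`, `transformed`.
#' @export
compute_symptom_scores <- function(symptoms, skew_threshold = 1) {
  stopifnot(all(c("id", "scale", "domain", "item", "value") %in%
                  names(symptoms)))
  if (any(symptoms$value < 0))
    stop("negative symptom ratings are invalid", call. = FALSE)
  out <- list()
  for (key in unique(paste(symptoms$scale, symptoms$domain, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- symptoms[symptoms$scale == parts[1] &
                      symptoms$domain == parts[2], ]
    ids <- unique(sub$id)
    has_global <- "global" %in% sub$item
    rows <- do.call(rbind, lapply(ids, function(pid) {
      si <- sub[sub$id == pid, ]
      items <- si$value[si$item != "global"]
      glob <- if (has_global) si$value[si$item == "global"] else NA_integer_
      data.frame(id = pid, scale = parts[1], domain = parts[2],
                 raw = sum(items) + if (has_global) glob else 0L,
                 included = if (has_global) glob >= 2L else TRUE,
                 stringsAsFactors = FALSE)
    }))
    sk <- sample_skewness(rows$raw[rows$included])
    rows$transformed <- !is.na(sk) && sk > skew_threshold
    rows$score <- if (rows$transformed[1]) sqrt(rows$raw) else rows$raw
    out[[key]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("id", "scale", "domain", "raw", "score", "included",
          "transformed")]
}

#' Covariate-adjusted Cohen's d
#'
#' `d = adjusted mean difference / residual SD`; in a two-group model with
#' no covariates this reduces to the classical pooled-SD d.
#'
#' @param adjusted_diff Adjusted mean difference between groups.
#' @param residual_sd Residual SD of the model (> 0).
#' @return Cohen's d.
#' @export
cohens_d <- function(adjusted_diff, residual_sd) {
  if (!is.finite(residual_sd) || residual_sd <= 0)
    stop("Cohen's d undefined: residual SD must be positive",
         call. = FALSE)
  adjusted_diff / residual_sd
}

# balanced-grid contrast row for one group: average model-matrix row over
# all combinations of the other factors (emmeans-style adjusted mean)
adjusted_mean_rows <- function(fit, data, group_var = "group") {
  tt <- stats::delete.response(stats::terms(fit))
  vars <- all.vars(tt)
  grid_vars <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) levels(x) else sort(unique(x))
  })
  names(grid_vars) <- vars
  grid <- expand.grid(grid_vars, stringsAsFactors = FALSE)
  for (v in vars) if (is.factor(data[[v]]))
    grid[[v]] <- factor(grid[[v]], levels = levels(data[[v]]))
  mm <- model.matrix(tt, grid)
  sapply(levels(data[[group_var]]), function(g)
    colMeans(mm[grid[[group_var]] == g, , drop = FALSE]))
}

#' Group comparison of similarity coefficients
#'
#' Linear model of Fisher-z similarity on group, sex and (optionally)
#' site. The model is first fitted with a group-by-sex interaction; a
#' non-significant interaction (p >= `alpha_drop`) is dropped and the
#' main-effects model is reported. Output includes the group omnibus
#' F-test, pairwise group contrasts from covariate-adjusted (balanced
#' over sex and site) means with Cohen's d (adjusted difference over
#' residual SD) and BH-FDR across the pairwise family, and within-group
#' tests of the adjusted mean similarity against 0, all on the model's
#' residual df.
#'
#' @param sim Similarity table ([similarity_table()] output) with `id`.
#' @param covariates Data frame with `id`, `group`, `sex`, and optionally
#'   `site`.
#' @param include_site Add a site main effect.
#' @param alpha_drop Two-sided p threshold below which the interaction is
#'   retained.
#' @param group_levels Optional ordering of group levels.
#' @return A `group_model_result`: `omnibus` (F, df1, df2, p),
#'   `pairwise` (estimate, t, df, p, p_fdr, d), `within` (group, mean,
#'   t, df, p), `interaction_retained`, `interaction_p`, `model`,
#'   `residual_sd`, `n`.
#' @export
group_anova <- function(sim, covariates, include_site = FALSE,
                        alpha_drop = 0.05, group_levels = NULL) {
  data <- merge(sim, covariates, by = "id")
  if (is.null(group_levels)) group_levels <- unique(covariates$group)
  data$group <- factor(data$group, levels = group_levels)
  data$sex <- factor(data$sex)
  if (include_site) data$site <- factor(data$site)
  if (nlevels(data$group) < 2L) stop("need at least 2 groups",
                                     call. = FALSE)
  empty <- table(data$group, data$sex) == 0
  if (any(empty)) {
    idx <- which(empty, arr.ind = TRUE)[1, ]
    stop("empty design cell: group ", rownames(empty)[idx[1]], " x sex ",
         colnames(empty)[idx[2]], call. = FALSE)
  }
  site_term <- if (include_site) " + site" else ""
  two_sex <- nlevels(data$sex) >= 2L
  if (two_sex) {
    f_full <- as.formula(paste0("fisher_z ~ group * sex", site_term))
    f_red <- as.formula(paste0("fisher_z ~ group + sex", site_term))
    fit_full <- lm(f_full, data = data)
    fit_red <- lm(f_red, data = data)
    int_p <- anova(fit_red, fit_full)[2, "Pr(>F)"]
    retained <- is.finite(int_p) && int_p < alpha_drop
    fit <- if (retained) fit_full else fit_red
    f_nog <- as.formula(paste0("fisher_z ~ ",
                               if (retained) "group * sex" else "sex",
                               site_term))
  } else {
    f_red <- as.formula(paste0("fisher_z ~ group", site_term))
    fit <- lm(f_red, data = data)
    int_p <- NA_real_
    retained <- FALSE
    f_nog <- as.formula(paste0("fisher_z ~ 1", site_term))
  }
  if (any(is.na(coef(fit))))
    stop("singular design: aliased term(s) ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  # omnibus group test against the model without any group term
  fit_nog <- lm(f_nog, data = data)
  om <- anova(fit_nog, fit)
  omnibus <- list(F = om[2, "F"], df1 = om[2, "Df"],
                  df2 = fit$df.residual, p = om[2, "Pr(>F)"])
  sigma <- summary(fit)$sigma
  V <- vcov(fit)
  b <- coef(fit)
  L <- adjusted_mean_rows(fit, data)        # p x n_groups
  gl <- levels(data$group)
  within <- do.call(rbind, lapply(seq_along(gl), function(i) {
    est <- sum(L[, i] * b)
    se <- sqrt(drop(t(L[, i]) %*% V %*% L[, i]))
    data.frame(group = gl[i], mean_fisher_z = est, t = est / se,
               df = fit$df.residual,
               p = 2 * pt(-abs(est / se), fit$df.residual))
  }))
  pairs <- utils::combn(seq_along(gl), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i2 <- pairs[2, j]; i1 <- pairs[1, j]
    Lc <- L[, i2] - L[, i1]
    est <- sum(Lc * b)
    se <- sqrt(drop(t(Lc) %*% V %*% Lc))
    data.frame(contrast = paste(gl[i2], "-", gl[i1]), estimate = est,
               t = est / se, df = fit$df.residual,
               p = 2 * pt(-abs(est / se), fit$df.residual),
               d = cohens_d(est, sigma))
  }))
  pairwise$p_fdr <- p.adjust(pairwise$p, method = "BH")
  structure(list(omnibus = omnibus, pairwise = pairwise, within = within,
                 interaction_retained = retained, interaction_p = int_p,
                 model = fit, residual_sd = sigma, n = nrow(data),
                 fdr_family = nrow(pairwise)),
            class = "group_model_result")
}

#' @export
print.group_model_result <- function(x, ...) {
  cat(sprintf(
    "<group_model_result> n=%d, group F(%d, %d) = %.2f, p = %.3g%s\n",
    x$n, x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p,
    if (x$interaction_retained) " [group x sex interaction retained]"
    else ""))
  cat("Pairwise (FDR family size ", x$fdr_family, "):\n", sep = "")
  print(x$pairwise, digits = 3)
  cat("Within-group mean vs 0:\n")
  print(x$within, digits = 3)
  invisible(x)
}

#' Symptom-score regressions on similarity coefficients
#'
#' For every symptom domain: regress the (possibly sqrt-transformed)
#' score of included participants on the Fisher-z similarity coefficient,
#' sex and (optionally) site, starting with a similarity-by-sex
#' interaction. A non-significant interaction (p >= `alpha_drop`) is
#' dropped and the common standardized slope is reported; a significant
#' interaction is followed up with separate per-sex slopes (the domain's
#' primary p is then the joint F-test of the similarity terms). BH FDR is
#' applied across the domain family supplied.
#'
#' @param scores [compute_symptom_scores()] output (one family of
#'   domains, e.g. the eight SAPS/SANS domains or the four SOPS domains).
#' @param sim Similarity table with `id` and `fisher_z`.
#' @param covariates Data frame with `id`, `sex`, optional `site`.
#' @param include_site Add a site main effect.
#' @param alpha_drop Interaction-dropping threshold.
#' @param q FDR level.
#' @return A `symptom_regression_result`: data frame with one row per
#'   domain (`scale`, `domain`, `n`, `beta` standardized common slope,
#'   `slope` raw common slope, `t`, `df`, `p`, `p_fdr`,
#'   `interaction_retained`, per-sex slopes when retained), with the FDR
#'   family size as an attribute.
#' @export
symptom_regression <- function(scores, sim, covariates,
                               include_site = FALSE, alpha_drop = 0.05,
                               q = 0.05) {
  doms <- unique(scores[, c("scale", "domain")])
  site_term <- if (include_site) " + site" else ""
  rows <- lapply(seq_len(nrow(doms)), function(i) {
    sc <- doms$scale[i]; dm <- doms$domain[i]
    sub <- scores[scores$scale == sc & scores$domain == dm &
                    scores$included, ]
    data <- merge(merge(sub, sim, by = "id"), covariates, by = "id")
    out <- data.frame(scale = sc, domain = dm, n = nrow(data),
                      beta = NA_real_, slope = NA_real_, t = NA_real_,
                      df = NA_real_, p = NA_real_,
                      interaction_retained = FALSE,
                      slope_M = NA_real_, slope_F = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(data) < 10L) {
      warning("domain ", dm, ": fewer than 10 included participants; ",
              "model skipped")
      return(out)
    }
    data$sex <- factor(data$sex)
    if (include_site) data$site <- factor(data$site)
    two_sex <- nlevels(data$sex) >= 2L
    if (!two_sex)
      warning("domain ", dm, ": single-sex subsample; ",
              "falling back to the common slope")
    int_p <- NA_real_
    if (two_sex) {
      fit_full <- lm(as.formula(paste0("score ~ fisher_z * sex",
                                       site_term)), data = data)
      fit_red <- lm(as.formula(paste0("score ~ fisher_z + sex",
                                      site_term)), data = data)
      int_p <- anova(fit_red, fit_full)[2, "Pr(>F)"]
    } else {
      fit_red <- lm(as.formula(paste0("score ~ fisher_z", site_term)),
                    data = data)
    }
    if (two_sex && is.finite(int_p) && int_p < alpha_drop) {
      out$interaction_retained <- TRUE
      for (s in levels(data$sex)) {
        dsub <- data[data$sex == s, ]
        if (nrow(dsub) >= 3L) {
          fs <- lm(as.formula(paste0("score ~ fisher_z", site_term)),
                   data = dsub)
          out[[paste0("slope_", s)]] <- coef(fs)[["fisher_z"]]
        }
      }
      # joint test of the similarity terms as the domain's primary p
      fit_nofz <- lm(as.formula(paste0("score ~ sex", site_term)),
                     data = data)
      cmp <- anova(fit_nofz, fit_full)
      out$t <- sqrt(max(0, cmp[2, "F"]))
      out$df <- fit_full$df.residual
      out$p <- cmp[2, "Pr(>F)"]
    } else {
      sm <- summary(fit_red)$coefficients
      out$slope <- sm["fisher_z", "Estimate"]
      out$beta <- out$slope * sd(data$fisher_z) / sd(data$score)
      out$t <- sm["fisher_z", "t value"]
      out$df <- fit_red$df.residual
      out$p <- sm["fisher_z", "Pr(>|t|)"]
    }
    out
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- p.adjust(res$p, method = "BH")
  res$reject_fdr <- !is.na(res$p_fdr) & res$p_fdr <= q
  attr(res, "fdr_family") <- nrow(res)
  class(res) <- c("symptom_regression_result", "data.frame")
  res
}

#' @export
print.symptom_regression_result <- function(x, ...) {
  cat("<symptom_regression_result> FDR family size",
      attr(x, "fdr_family"), "\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Spearman confound correlation
#'
#' Rank correlation (midrank ties) between antipsychotic dose equivalents
#' and similarity coefficients, with the asymptotic two-sided p-value —
#' a non-parametric check for a medication confound.
#'
#' @param cpzeq Dose equivalents (mg/day).
#' @param fisher_z Similarity coefficients (Fisher z).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_confound <- function(cpzeq, fisher_z) {
  ok <- is.finite(cpzeq) & is.finite(fisher_z)
  x <- cpzeq[ok]; y <- fisher_z[ok]
  if (length(x) < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
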