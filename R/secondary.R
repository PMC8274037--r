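#' Group difference of a selected feature
#'
#' Mixed-model test of the pmTBI-vs-control contrast for one feature, with
#' family as a random intercept. Clinical/cognitive features adjust for age,
#' sex, BMI and race; methylation features (component loadings, prior CpGs,
#' global methylation) additionally adjust for buccal proportion and the
#' chosen methylation PCs.
#'
#' @param feature Per-sample values aligned with `table` rows.
#' @param kind `"clinical"` or `"methylation"`.
#' @param table Sample table (needs `buccal` and PC columns for methylation
#'   features).
#' @param target Label carried into the result.
#' @param pcs Methylation PC covariate names (default `PC2`-`PC4`).
#' @return One-row data frame: `analysis_id`, `target`, `estimate`, `t_stat`,
#'   `df`, `p`.
#' @export
group_difference <- function(feature, kind = c("clinical", "methylation"),
                             table, target = "feature",
                             pcs = c("PC2", "PC3", "PC4")) {
  kind <- match.arg(kind)
  covs <- c("age", "sex", "bmi", "race")
  if (kind == "methylation") covs <- c(covs, "buccal", pcs)
  spec <- mwas_spec(predictor = "diagnosis", covariates = covs)
  fit <- fit_probe_lmm(feature, spec, table)
  data.frame(analysis_id = if (kind == "clinical") "a" else "b",
             target = target, estimate = fit$estimate, t_stat = fit$t_stat,
             df = fit$df, p = fit$p, stringsAsFactors = FALSE)
}

#' Association between a methylation feature and an outcome within patients
#'
#' Fixed-effects regression (patients only) of the methylation feature on
#' the outcome plus age, sex, BMI, race, buccal proportion and methylation
#' PCs. Reports the partial R-squared of the outcome term, in percent, from
#' the nested-model SSE ratio.
#'
#' @param feature Per-sample methylation feature aligned with `table`.
#' @param outcome Outcome column name (e.g. `"PCSI_EC"`, `"PedsQL_EC"`,
#'   `"depression_EC"`).
#' @param table Patient sample table.
#' @param target Label carried into the result.
#' @param pcs Methylation PC covariate names.
#' @return One-row data frame: `analysis_id = "c"`, `target`, `outcome`,
#'   `estimate`, `t_stat`, `df`, `p`, `R2_percent`.
#' @export
methylation_outcome_association <- function(feature, outcome, table,
                                            target = "feature",
                                            pcs = c("PC2", "PC3", "PC4")) {
  keep <- !is.na(table[[outcome]]) & !is.na(feature)
  tab <- table[keep, , drop = FALSE]
  y <- feature[keep]
  covs <- drop_constant_cols(
    covariate_matrix(tab, c("age", "sex", "bmi", "race", "buccal", pcs)))
  x <- as.numeric(tab[[outcome]])
  Xf <- cbind(1, x, covs)
  if (qr(Xf)$rank < ncol(Xf)) stop("rank-deficient design")
  full <- stats::lm.fit(Xf, y)
  reduced <- stats::lm.fit(cbind(1, covs), y)
  sse_f <- sum(full$residuals^2)
  sse_r <- sum(reduced$residuals^2)
  df <- length(y) - ncol(Xf)
  s2 <- sse_f / df
  se <- sqrt(s2 * chol2inv(chol(crossprod(Xf)))[2, 2])
  t_stat <- full$coefficients[2] / se
  data.frame(analysis_id = "c", target = target, outcome = outcome,
             estimate = unname(full$coefficients[2]), t_stat = unname(t_stat),
             df = df, p = 2 * stats::pt(-abs(t_stat), df),
             R2_percent = 100 * (1 - sse_f / sse_r), stringsAsFactors = FALSE)
}

#' Methylation-fitted depression score
#'
#' Regresses the depression score on the component loadings plus age, sex,
#' BMI and race (patients only), forms the fitted score from the loading
#' coefficients alone, and correlates it with the observed score. The
#' correlation is in-sample by construction, so a permutation null
#' (response shuffled, model refit) is reported alongside.
#'
#' @param loadings Samples x components matrix with sample-id rownames.
#' @param table Patient sample table.
#' @param visit `"SA"` or `"EC"` (selects `depression_SA` / `depression_EC`).
#' @param n_perm Permutation count for the null (default 999; 0 disables).
#' @param seed Seed for the permutations.
#' @return List: `fitted` (named score vector), `r`, `p`, `R2_percent`
#'   (`= 100 r^2`), `p_perm` (or `NA`), `coefficients`.
#' @export
fitted_depression_score <- function(loadings, table, visit = c("SA", "EC"),
                                    n_perm = 999, seed = 1) {
  visit <- match.arg(visit)
  ycol <- paste0("depression_", visit)
  ids <- intersect(rownames(loadings), table$sample_id[!is.na(table[[ycol]])])
  tab <- table[match(ids, table$sample_id), , drop = FALSE]
  L <- loadings[ids, , drop = FALSE]
  y <- as.numeric(tab[[ycol]])
  covs <- drop_constant_cols(covariate_matrix(tab, c("age", "sex", "bmi",
                                                     "race")))
  Xf <- cbind(1, L, covs)
  if (length(y) <= ncol(Xf)) stop("need more samples than predictors")
  fit <- stats::lm.fit(Xf, y)
  k <- ncol(L)
  beta_load <- fit$coefficients[1 + seq_len(k)]
  fitted <- drop(L %*% beta_load)
  ev <- stats::cor.test(fitted, y)
  r_obs <- unname(ev$estimate)

  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    r_null <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fp <- stats::lm.fit(Xf, yp)
      fit_p <- drop(L %*% fp$coefficients[1 + seq_len(k)])
      if (stats::sd(fit_p) == 0) return(0)
      stats::cor(fit_p, yp)
    }, numeric(1))
    p_perm <- (1 + sum(r_null >= r_obs)) / (n_perm + 1)
  }
  list(fitted = stats::setNames(fitted, ids), r = r_obs, p = ev$p.value,
       R2_percent = 100 * r_obs^2, p_perm = p_perm,
       coefficients = stats::setNames(beta_load, colnames(L)))
}
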