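#' Specification of a per-CpG association model
#'
#' @param predictor Column of interest: `"diagnosis"` (pmTBI vs HC contrast
#'   derived from `group`) or any numeric sample-table column (e.g.
#'   `"depression_SA"`, `"PCSI_EC"`).
#' @param covariates Fixed-effect adjustment set; `"race"` expands to two
#'   dummies (White reference) and `"sex"` to a female indicator.
#' @param random_effect Grouping column for the random intercept (default
#'   `"family_id"`).
#' @return List of class `mwas_spec`.
#' @export
mwas_spec <- function(predictor = "diagnosis",
                      covariates = c("age", "sex", "bmi", "race", "buccal",
                                     "PC2", "PC3", "PC4"),
                      random_effect = "family_id") {
  if (predictor %in% covariates)
    stop("predictor of interest duplicated in covariates")
  structure(list(predictor = predictor, covariates = covariates,
                 random_effect = random_effect), class = "mwas_spec")
}

mwas_design <- function(spec, table) {
  X <- cbind(covariate_matrix(table, spec$predictor),
             drop_constant_cols(covariate_matrix(table, spec$covariates)))
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient fixed-effect design")
  X
}

#' Fit the mixed model for one response
#'
#' Random-intercept linear mixed model (REML via [lme4::lmer()]) of a
#' response on the predictor of interest plus covariates, with a Wald t-test
#' on the predictor and residual-convention degrees of freedom
#' (`n - n_fixed_effects`, intercept included). When every family is a
#' singleton the model reduces to ordinary least squares.
#'
#' @param y Per-sample response (probe betas, global methylation, or a
#'   clinical feature), aligned with `table` rows.
#' @param spec An [mwas_spec()].
#' @param table Sample table supplying predictor, covariates and family ids.
#' @return List: `estimate`, `t_stat`, `df`, `p`, `converged`.
#' @export
fit_probe_lmm <- function(y, spec, table) {
  X <- mwas_design(spec, table)
  fam <- table[[spec$random_effect]]
  if (length(unique(fam)) < 2) stop("need at least 2 families")
  n <- length(y)
  p_fixed <- ncol(X) + 1
  df <- n - p_fixed
  if (stats::sd(y) == 0)
    return(list(estimate = 0, t_stat = 0, df = df, p = 1, converged = TRUE))
  if (all(table(fam) == 1)) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(cbind(1, X))))
    est <- fit$coefficients[2]
    se <- sqrt(s2 * XtXinv[2, 2])
  } else {
    d <- data.frame(.y = y, X, .fam = fam, check.names = FALSE)
    form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                                  collapse = " + "),
                                    "+ (1 | .fam)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lme4::lmer(form, data = d, REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(estimate = NA_real_, t_stat = NA_real_, df = df,
                  p = NA_real_, converged = FALSE))
    est <- lme4::fixef(fit)[2]
    se <- sqrt(diag(as.matrix(stats::vcov(fit)))[2])
  }
  t_stat <- unname(est / se)
  list(estimate = unname(est), t_stat = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df), converged = TRUE)
}

#' Methylome-wide association study
#'
#' One mixed-model fit per probe (the fitted structure is reused across
#' probes via [lme4::refit()]), Wald t on the predictor of interest,
#' residual-convention df, BH q-values over converged probes, output sorted
#' by ascending p. Non-converged probes are flagged and excluded from the
#' BH denominator.
#'
#' @param betas Preprocessed probes x samples beta matrix.
#' @param spec An [mwas_spec()].
#' @param table Sample table aligned with `colnames(betas)`.
#' @param annotation Optional probe annotation; when given, a Manhattan table
#'   (`chrom`, `pos`, `neglog10_p`) is attached as attribute `"manhattan"`.
#' @return Data frame `probe_id`, `estimate`, `t_stat`, `df`, `p`, `q`,
#'   `converged`, sorted by p, with attributes `"qq"` (expected vs observed
#'   -log10 p under the uniform null) and `"sample_ids"`.
#' @export
run_mwas <- function(betas, spec, table, annotation = NULL) {
  stopifnot(ncol(betas) == nrow(table))
  X <- mwas_design(spec, table)
  fam <- table[[spec$random_effect]]
  m <- nrow(betas)
  est <- t_stat <- p <- rep(NA_real_, m)
  converged <- rep(TRUE, m)
  n <- ncol(betas)
  p_fixed <- ncol(X) + 1
  df <- n - p_fixed

  if (all(table(fam) == 1)) {
    # pure OLS fast path via one QR decomposition
    Xf <- cbind(1, X)
    qrx <- qr(Xf)
    XtXinv22 <- chol2inv(chol(crossprod(Xf)))[2, 2]
    coefs <- qr.coef(qrx, t(betas))
    res <- t(betas) - Xf %*% coefs
    s2 <- colSums(res^2) / df
    est <- coefs[2, ]
    t_stat <- est / sqrt(s2 * XtXinv22)
    p <- 2 * stats::pt(-abs(t_stat), df)
    zero_var <- apply(betas, 1, stats::sd) == 0
    est[zero_var] <- 0; t_stat[zero_var] <- 0; p[zero_var] <- 1
  } else {
    d <- data.frame(.y = betas[1, ], X, .fam = fam, check.names = FALSE)
    form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                                  collapse = " + "),
                                    "+ (1 | .fam)"))
    template <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE)))
    for (j in seq_len(m)) {
      y <- betas[j, ]
      if (stats::sd(y) == 0) { est[j] <- 0; t_stat[j] <- 0; p[j] <- 1; next }
      fit <- tryCatch(
        suppressMessages(suppressWarnings(lme4::refit(template, newresp = y))),
        error = function(e) NULL)
      if (is.null(fit)) { converged[j] <- FALSE; next }
      b <- lme4::fixef(fit)[2]
      se <- sqrt(diag(as.matrix(stats::vcov(fit)))[2])
      est[j] <- b
      t_stat[j] <- b / se
      p[j] <- 2 * stats::pt(-abs(t_stat[j]), df)
    }
  }

  out <- data.frame(probe_id = rownames(betas), estimate = est,
                    t_stat = t_stat, df = df, p = p, converged = converged,
                    stringsAsFactors = FALSE)
  out$q <- NA_real_
  out$q[out$converged] <- bh_fdr(out$p[out$converged])
  out <- out[order(out$p), c("probe_id", "estimate", "t_stat", "df", "p",
                             "q", "converged")]
  rownames(out) <- NULL
  ok <- stats::na.omit(out$p)
  attr(out, "qq") <- data.frame(
    expected = -log10(stats::ppoints(length(ok))),
    observed = -log10(sort(ok)))
  if (!is.null(annotation)) {
    idx <- match(out$probe_id, annotation$probe_id)
    attr(out, "manhattan") <- data.frame(probe_id = out$probe_id,
                                         chrom = annotation$chrom[idx],
                                         pos = annotation$pos[idx],
                                         neglog10_p = -log10(out$p))
  }
  attr(out, "sample_ids") <- colnames(betas)
  attr(out, "spec") <- spec
  out
}

#' Global methylation proxy
#'
#' Arithmetic mean beta across retained probes, per sample. Group-difference
#' testing delegates to [fit_probe_lmm()] with this mean as the response.
#'
#' @param betas Imputed probes x samples beta matrix.
#' @return Named per-sample mean beta.
#' @export
global_methylation <- function(betas) colMeans(betas)

#' Select top CpGs from an MWAS result
#'
#' @param result A [run_mwas()] result.
#' @param mode `"p_threshold"` (keep p < cutoff) or `"fdr"` (keep q < cutoff).
#' @param cutoff Threshold.
#' @return Probe ids ordered by ascending p, carrying the sample ids the MWAS
#'   was computed on as attribute `"computed_on"` (leakage guard for
#'   downstream predictors). Empty selections warn.
#' @export
select_top_cpgs <- function(result, mode = c("p_threshold", "fdr"), cutoff) {
  mode <- match.arg(mode)
  keep <- if (mode == "p_threshold") result$p < cutoff else result$q < cutoff
  keep[is.na(keep)] <- FALSE
  ids <- result$probe_id[keep]
  if (!length(ids)) warning("no probes pass the selection criterion")
  structure(ids, computed_on = attr(result, "sample_ids"))
}

#' Refuse feature sets whose selection saw test samples
#'
#' @param features Object carrying a `"computed_on"` attribute (sample ids).
#' @param test_ids Hold-out sample ids.
#' @return Invisibly `TRUE`; errors when the selection overlapped the test set.
#' @export
assert_no_leakage <- function(features, test_ids) {
  seen <- attr(features, "computed_on")
  if (!is.null(seen) && length(intersect(seen, test_ids)))
    stop("feature selection was computed on samples that overlap the test set")
  invisible(TRUE)
}
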