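#' Logit-scale helpers for beta values
#'
#' `logit` and `inv_logit` convert between methylation beta values and
#' M-values; `squeeze_beta` clamps values away from exact 0/1 (which can
#' arise from clipping) so the logit stays finite.
#'
#' @param p Beta values in \[0, 1\].
#' @param x M-values.
#' @param eps Clamping margin.
#' @return Transformed numeric object of the same shape.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @rdname logit
#' @export
squeeze_beta <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1 and mapped back to the input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\]. `NA`s are propagated and do
#'   not count towards `m`.
#' @return Numeric vector of adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation, p-value and mean squared error of predictions
#'
#' @param pred Predicted values.
#' @param obs Observed values (original outcome scale).
#' @return List with `r`, `p` (two-sided t-test on the correlation) and `mse`.
#'   A zero-variance prediction vector yields `r = NA`, `p = 1`.
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 3)
  mse <- mean((pred - obs)^2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(list(r = NA_real_, p = 1, mse = mse))
  }
  ct <- stats::cor.test(pred, obs, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, mse = mse)
}

# Expand a sample table into the fixed-effect design columns used throughout:
# race becomes two dummies (White reference), sex is female = 1.
covariate_matrix <- function(table, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "race") {
      cols[["race_aa"]] <- as.numeric(table$race == "African-American")
      cols[["race_other"]] <- as.numeric(table$race == "other")
    } else if (cv == "sex") {
      cols[["sex"]] <- as.numeric(table$sex == "F")
    } else if (cv == "diagnosis") {
      cols[["diagnosis"]] <- as.numeric(table$group == "pmTBI")
    } else {
      if (is.null(table[[cv]])) stop("unknown covariate: ", cv)
      cols[[cv]] <- as.numeric(table[[cv]])
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(table), ncol = 0))
  do.call(cbind, cols)
}

# Drop constant columns (e.g. an absent race level's dummy) so the design
# stays full rank in small cohorts.
drop_constant_cols <- function(X) {
  if (!ncol(X)) return(X)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X[, keep, drop = FALSE]
}
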