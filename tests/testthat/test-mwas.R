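# Brute-force step-up BH oracle: q_(i) = min_{j >= i} p_(j) * m / j on the
# sorted scale, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- sapply(seq_len(m), function(i) min(pmin(ps[i:m] * m / (i:m), 1)))
  q <- numeric(m)
  q[ord] <- qs
  q
}

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is permutation-equivariant and never below p", {
  set.seed(2)
  p <- runif(25)
  q <- bh_fdr(p)
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p - 1e-12))
})

test_that("the mixed model reduces to OLS when all families are singletons", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    tab <- make_table(n, n_families = n, seed = i)
    y <- rnorm(n, 0.5, 0.1)
    spec <- mwas_spec(predictor = "diagnosis",
                      covariates = c("age", "sex", "bmi"))
    fit <- fit_probe_lmm(y, spec, tab)
    ols <- summary(lm(y ~ I(tab$group == "pmTBI") + tab$age +
                        I(tab$sex == "F") + tab$bmi))
    expect_equal(fit$estimate, unname(coef(ols)[2, 1]), tolerance = 1e-6)
    expect_equal(fit$t_stat, unname(coef(ols)[2, 3]), tolerance = 1e-6)
    expect_equal(fit$p, unname(coef(ols)[2, 4]), tolerance = 1e-6)
    expect_equal(fit$df, n - 5)
  }
})

test_that("constant responses return a null result", {
  tab <- make_table(30)
  spec <- mwas_spec(covariates = c("age", "sex"))
  fit <- fit_probe_lmm(rep(0.5, 30), spec, tab)
  expect_equal(fit$estimate, 0)
  expect_equal(fit$p, 1)
})

test_that("a planted five-residual-SD diagnosis shift is detected", {
  set.seed(4)
  n <- 100
  tab <- make_table(n, n_families = 80, seed = 4)
  y <- rnorm(n, 0, 0.02) + 0.1 * (tab$group == "pmTBI")
  spec <- mwas_spec(covariates = c("age", "sex", "bmi"))
  fit <- fit_probe_lmm(y, spec, tab)
  expect_lt(fit$p, 1e-6)
})

test_that("the predictor test statistic is invariant to affine covariate rescaling", {
  set.seed(5)
  n <- 60
  tab <- make_table(n, n_families = 50, seed = 5)
  y <- rnorm(n, 0.5, 0.1)
  spec <- mwas_spec(covariates = c("age", "bmi"))
  f1 <- fit_probe_lmm(y, spec, tab)
  tab2 <- tab
  tab2$age <- 10 * tab2$age - 3
  tab2$bmi <- tab2$bmi / 7 + 100
  f2 <- fit_probe_lmm(y, spec, tab2)
  expect_equal(f1$t_stat, f2$t_stat, tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-6)
})

test_that("run_mwas ranks a planted probe first and treats duplicates identically", {
  set.seed(6)
  n <- 80
  tab <- make_table(n, n_families = 70, seed = 6)
  m <- 40
  b <- matrix(rnorm(m * n, 0.5, 0.05), m, n,
              dimnames = list(sprintf("p%03d", 1:m), tab$sample_id))
  b[1, ] <- b[1, ] + 0.08 * (tab$group == "pmTBI")
  b[2, ] <- b[1, ] # duplicate of the planted probe
  spec <- mwas_spec(covariates = c("age", "sex", "bmi"))
  res <- run_mwas(b, spec, tab)
  expect_setequal(res$probe_id[1:2], c("p001", "p002"))
  expect_equal(res$p[1], res$p[2], tolerance = 1e-10)
  expect_equal(min(res$q, na.rm = TRUE), res$q[1])
  expect_true(!is.unsorted(res$p))
  qq <- attr(res, "qq")
  expect_equal(nrow(qq), m)
})

test_that("top-CpG selection filters by threshold in ascending-p order", {
  res <- data.frame(probe_id = c("a", "b", "c"), p = c(0.2, 0.001, 0.04),
                    q = c(0.2, 0.003, 0.06), stringsAsFactors = FALSE)
  res <- res[order(res$p), ]
  attr(res, "sample_ids") <- c("s1", "s2")
  expect_identical(as.character(select_top_cpgs(res, "p_threshold", 0.05)),
                   c("b", "c"))
  expect_identical(as.character(select_top_cpgs(res, "fdr", 0.05)), "b")
  expect_identical(as.character(select_top_cpgs(res, "p_threshold", 1.0)),
                   c("b", "c", "a"))
  allnull <- res; allnull$p <- 1
  expect_warning(sel <- select_top_cpgs(allnull, "p_threshold", 0.05),
                 "no probes")
  expect_length(sel, 0)
  sel2 <- select_top_cpgs(res, "p_threshold", 0.05)
  expect_error(assert_no_leakage(sel2, c("s2", "s9")), "overlap")
  expect_true(assert_no_leakage(sel2, "s9"))
})

test_that("global methylation is the per-sample probe mean", {
  b <- random_betas(10, 4)
  expect_equal(global_methylation(b), colMeans(b))
  flat <- matrix(0.5, 3, 2, dimnames = list(paste0("p", 1:3), c("a", "b")))
  expect_equal(unname(global_methylation(flat)), c(0.5, 0.5))
  shifted <- b; shifted[, 2] <- shifted[, 2] + 0.1
  expect_equal(unname(global_methylation(shifted)[2] -
                        global_methylation(b)[2]), 0.1)
})
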