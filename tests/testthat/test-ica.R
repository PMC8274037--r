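test_that("pathway mapping honors the half-open 20 kb flank", {
  regions <- data.frame(gene = "G1", chrom = "chr1",
                        start = 1000000, end = 1050000)
  ann <- data.frame(
    probe_id = c("inside", "left_edge", "right_in", "right_out", "other_chr"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(1025000, 1000000 - 20000, 1050000 + 19999, 1050000 + 20000,
            1025000),
    stringsAsFactors = FALSE)
  got <- map_pathway_probes(regions, ann, flank = 20000)
  expect_identical(got, c("inside", "left_edge", "right_in"))
  expect_warning(map_pathway_probes(regions, ann[5, , drop = FALSE]),
                 "no probes")
})

test_that("mapping recovers exactly the planted pathway probes", {
  co <- tiny_cohort()
  got <- map_pathway_probes(co$regions, co$annotation)
  planted <- names(co$truth$probe_class)[co$truth$probe_class == "pathway"]
  expect_setequal(got, planted)
})

test_that("ICA recovers two Laplacian sources from a known mixing", {
  set.seed(10)
  p <- 3000; n <- 40
  S <- matrix(rexp(2 * p, sqrt(2)) * sample(c(-1, 1), 2 * p, TRUE), 2, p)
  S <- S / sqrt(rowSums(S^2))
  A <- matrix(c(3, 1, 1.5, -2.5), 2, 2) # known 2x2 mixing
  X <- matrix(rnorm(n * 2), n, 2) %*% A %*% S
  m <- fit_ica(X, 2, seed = 1)
  mc <- match_components(m$S, S)
  expect_true(all(mc$abs_cor >= 0.99))
})

test_that("an exact-rank decomposition reconstructs the data", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  S <- matrix(rexp(3 * 50, sqrt(2)) * sample(c(-1, 1), 150, TRUE), 3, 50)
  X <- A %*% S
  m <- fit_ica(X, 3, seed = 2)
  Xc <- sweep(X, 2, m$center)
  expect_lt(norm(Xc - m$A %*% m$S, "F") / norm(Xc, "F"), 1e-6)
  expect_equal(variance_retained(m, X), 1, tolerance = 1e-10)
})

test_that("sample order permutes loadings and leaves components unchanged", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3) %*%
    (matrix(rexp(3 * 80, sqrt(2)) * sample(c(-1, 1), 240, TRUE), 3, 80))
  m1 <- fit_ica(X, 3, seed = 3)
  perm <- sample(nrow(X))
  m2 <- fit_ica(X[perm, ], 3, seed = 3)
  # deflation stops within tolerance, so require equivalence, not identity
  expect_gt(min(diag(cor(t(m2$S), t(m1$S)))), 0.999)
  expect_gt(min(diag(cor(m2$A, m1$A[perm, ]))), 0.999)
})

test_that("projection reproduces training loadings and zeroes the center", {
  co <- tiny_cohort()
  planted <- names(co$truth$probe_class)[co$truth$probe_class == "pathway"]
  X <- t(logit(squeeze_beta(impute_probe_mean(
    mask_low_detection(co$betas, co$detection))[planted, ])))
  m <- suppressWarnings(fit_ica(X, 3, seed = 4))
  expect_equal(project_loadings(m, X), m$A, tolerance = 1e-8)
  center_row <- matrix(m$center, 1, dimnames = list("c", m$probe_ids))
  expect_equal(unname(drop(project_loadings(m, center_row))), rep(0, 3),
               tolerance = 1e-10)
  expect_error(project_loadings(m, X[, -1]), "missing")
})

test_that("variance retained equals the planted signal share", {
  set.seed(13)
  n <- 80; p <- 200; k <- 5
  A <- matrix(rnorm(n * k), n, k)
  S <- matrix(rexp(k * p, sqrt(2)) * sample(c(-1, 1), k * p, TRUE), k, p)
  S <- 3 * S / sqrt(rowSums(S^2))
  sig <- A %*% S
  noise <- matrix(rnorm(n * p, 0, 0.05), n, p)
  X <- sig + noise
  m <- suppressWarnings(fit_ica(X, k, seed = 5))
  Xc <- sweep(X, 2, colMeans(X))
  sig_c <- sweep(sig, 2, colMeans(sig))
  share <- sum(sig_c^2) / sum(Xc^2)
  expect_equal(variance_retained(m, X), share, tolerance = 0.01)
  expect_error(variance_retained(m, matrix(m$center, 2, p, byrow = TRUE)),
               "zero variance")
})

test_that("half-sample consistency finds an exact low-rank component count", {
  set.seed(14)
  n <- 60; p <- 150
  A <- matrix(rnorm(n * 3), n, 3)
  S <- matrix(rexp(3 * p, sqrt(2)) * sample(c(-1, 1), 3 * p, TRUE), 3, p)
  S <- S / sqrt(rowSums(S^2))
  X <- A %*% diag(c(5, 4, 3)) %*% S + matrix(rnorm(n * p, 0, 0.02), n, p)
  k <- suppressWarnings(estimate_component_number(X, 2:6, n_runs = 6, seed = 1))
  expect_equal(as.integer(k), 3)
  expect_warning(k1 <- estimate_component_number(
    matrix(rnorm(40 * 100), 40, 100), 2:4, n_runs = 4, seed = 1),
    "consistency floor")
  expect_true(as.integer(k1) %in% 2:4)
  kk <- suppressWarnings(estimate_component_number(X, 1, n_runs = 3, seed = 1))
  expect_equal(as.integer(kk), 1)
})

test_that("an ICA model round-trips through serialization", {
  co <- tiny_cohort()
  planted <- names(co$truth$probe_class)[co$truth$probe_class == "pathway"]
  X <- t(impute_probe_mean(mask_low_detection(co$betas,
                                              co$detection))[planted, 1:30])
  m <- suppressWarnings(fit_ica(X, 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  save_ica_model(m, path)
  m2 <- read_ica_model(path)
  expect_equal(m2$S, m$S, tolerance = 1e-12)
  expect_equal(m2$A, m$A, tolerance = 1e-12)
  expect_equal(m2$center, m$center, tolerance = 1e-12)
  expect_identical(m2$n_components, m$n_components)
  expect_equal(m2$seed, m$seed)
})
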