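test_that("detection masking uses a strict threshold", {
  b <- random_betas(4, 3)
  d <- matrix(0, 4, 3, dimnames = dimnames(b))
  d[1, 1] <- 0.06
  d[2, 2] <- 0.05 # boundary: retained
  out <- mask_low_detection(b, d, 0.05)
  expect_true(is.na(out[1, 1]))
  expect_false(is.na(out[2, 2]))
  expect_identical(mask_low_detection(b, matrix(0, 4, 3)), b)
  expect_error(mask_low_detection(b, d[, 1:2]), "shape")
})

test_that("sample missingness filter removes strictly above the cutoff", {
  b <- random_betas(200, 3)
  b[1:4, 1] <- NA            # 2% missing -> removed
  b[1:2, 2] <- NA            # exactly 1% -> retained
  res <- drop_high_missing_samples(b, 0.01)
  expect_identical(colnames(res$betas), c("s002", "s003"))
  expect_identical(res$report$removed_samples$sample_id, "s001")
  full <- drop_high_missing_samples(random_betas(200, 3), 0.01)
  expect_equal(ncol(full$betas), 3)
})

test_that("probe filters remove sex chromosomes, SNP and cross-hybridizing probes with reasons", {
  b <- random_betas(5, 100)
  b[4, 1:3] <- NA # 3% missing
  ann <- data.frame(probe_id = rownames(b),
                    chrom = c("chr1", "chrY", "chr2", "chr3", "chr4"),
                    pos = 1:5,
                    snp_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                    crosshyb_flag = FALSE, stringsAsFactors = FALSE)
  res <- drop_probes(b, ann, 0.01)
  expect_identical(rownames(res$betas), c("p001", "p005"))
  reasons <- res$report$removed_probes
  expect_identical(reasons$reason[reasons$probe_id == "p002"], "sex_chromosome")
  expect_identical(reasons$reason[reasons$probe_id == "p003"], "snp")
  expect_identical(reasons$reason[reasons$probe_id == "p004"], "probe_missingness")
  expect_error(drop_probes(b, ann[-1, ], 0.01), "unannotated")
})

test_that("quantile normalization equalizes sample distributions", {
  b <- matrix(c(0.1, 0.2, 0.3, 0.3, 0.4, 0.5), nrow = 3,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  out <- quantile_normalize(b)
  expect_equal(unname(out[, 1]), c(0.2, 0.3, 0.4))
  expect_equal(unname(out[, 2]), c(0.2, 0.3, 0.4))
  big <- random_betas(300, 5)
  qn <- quantile_normalize(big)
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  one <- quantile_normalize(matrix(c(0.2, 0.6), 1, 2,
                                   dimnames = list("p1", c("a", "b"))))
  expect_equal(unname(one[1, ]), c(0.4, 0.4))
})

test_that("probe-mean imputation fills exactly the missing cells", {
  b <- matrix(c(0.2, NA, 0.4, NA, 0.5, 0.5), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  out <- impute_probe_mean(b)
  expect_equal(out["p1", "b"], 0.3)
  expect_equal(unname(out["p2", ]), c(0.5, 0.5, 0.5))
  expect_identical(impute_probe_mean(random_betas(5, 4)), random_betas(5, 4))
  allna <- b; allna[1, ] <- NA
  expect_error(impute_probe_mean(allna), "all-missing")
})

test_that("batch adjustment removes a planted constant shift", {
  set.seed(42)
  m <- 300; n <- 60
  b <- random_betas(m, n, seed = 42)
  batch <- rep(c("A", "B"), each = n / 2)
  delta <- 0.05
  b[, batch == "B"] <- pmin(b[, batch == "B"] + delta, 1)
  adj <- adjust_batch(b, batch)
  # the estimate of the planted constant shift (per-probe sampling noise in
  # the batch means is not batch effect and is legitimately left in place)
  diff_after <- rowMeans(adj[, batch == "B"]) - rowMeans(adj[, batch == "A"])
  expect_lt(abs(mean(diff_after)), 0.1 * delta)
  expect_error(adjust_batch(b, rep("A", n)), "2 batches")
  expect_identical(adjust_batch(b, rep("A", n), allow_single = TRUE), b)
})

test_that("batch adjustment barely moves probe means on batch-free data", {
  b <- random_betas(300, 60, seed = 7)
  batch <- rep(c("A", "B", "C"), each = 20)
  adj <- adjust_batch(b, batch)
  expect_lt(max(abs(rowMeans(adj) - rowMeans(b))), 0.01)
})

test_that("cell deconvolution recovers reference endpoints and mixtures", {
  set.seed(2)
  m <- 120
  ref <- data.frame(probe_id = sprintf("p%03d", 1:m),
                    buccal = runif(m, 0.1, 0.9),
                    granulocyte = runif(m, 0.1, 0.9))
  w <- c(1, 0, 0.6, 0.25)
  B <- sapply(w, function(wi) wi * ref$buccal + (1 - wi) * ref$granulocyte)
  dimnames(B) <- list(ref$probe_id, paste0("s", seq_along(w)))
  est <- estimate_cell_proportions(B, ref)
  expect_equal(unname(est[1]), 1, tolerance = 1e-6)
  expect_equal(unname(est[2]), 0, tolerance = 1e-6)
  expect_equal(unname(est[3]), 0.6, tolerance = 0.02)
  expect_equal(unname(est[4]), 0.25, tolerance = 0.02)
  bad <- ref; bad$granulocyte <- bad$buccal
  expect_error(estimate_cell_proportions(B, bad), "identical")
})

test_that("cell deconvolution recovers noisy planted mixtures within MAE 0.05", {
  set.seed(3)
  m <- 200; n <- 100
  ref <- data.frame(probe_id = sprintf("p%03d", 1:m),
                    buccal = runif(m, 0.1, 0.9),
                    granulocyte = runif(m, 0.1, 0.9))
  w <- runif(n)
  B <- sapply(w, function(wi) {
    pmin(pmax(wi * ref$buccal + (1 - wi) * ref$granulocyte +
                rnorm(m, 0, 0.05), 0), 1)
  })
  dimnames(B) <- list(ref$probe_id, paste0("s", 1:n))
  est <- estimate_cell_proportions(B, ref)
  expect_lte(mean(abs(est - w)), 0.05)
})

test_that("principal components match a direct eigendecomposition oracle", {
  b <- random_betas(80, 30, seed = 5)
  pc <- compute_pcs(b, 4)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))
  # orthogonality of score vectors
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # eigenvalue oracle: eigen of the sample covariance over probes
  ev <- eigen(cov(t(b)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$eigenvalues, ev[1:4], tolerance = 1e-8)
  expect_equal(var(pc$scores[, 1]), pc$eigenvalues[1], tolerance = 1e-8)
  # rank-1 matrix: all but the first eigenvalue vanish
  r1 <- outer(runif(20), runif(10))
  dimnames(r1) <- list(paste0("p", 1:20), paste0("s", 1:10))
  pc1 <- compute_pcs(r1, 3)
  expect_lt(max(pc1$eigenvalues[2:3]), 1e-12)
})

test_that("PC outlier removal flags planted outliers and spares a Gaussian cloud", {
  b <- random_betas(150, 50, seed = 6)
  b[, 1] <- pmin(pmax(b[, 1] + 0.35, 0), 1) # gross outlier on PC1
  res <- remove_pc_outliers(b, n_pcs = 4, n_sd = 3)
  expect_true("s001" %in% res$report$removed_samples$sample_id)
  clean <- random_betas(150, 50, seed = 8)
  res2 <- remove_pc_outliers(clean, n_pcs = 4, n_sd = 3)
  expect_lte(nrow(res2$report$removed_samples), 2)
  res3 <- remove_pc_outliers(clean, n_pcs = 4, n_sd = Inf)
  expect_equal(ncol(res3$betas), 50)
})

test_that("the SD filter keeps strictly-above-threshold probes in order", {
  set.seed(9)
  b <- rbind(p1 = rnorm(50, 0.5, 0.05), p2 = rnorm(50, 0.5, 0.2),
             p3 = rep(0.4, 50))
  colnames(b) <- paste0("s", 1:50)
  expect_identical(select_variable_probes(b, 0.1), "p2")
  expect_identical(select_variable_probes(b, 0), c("p1", "p2"))
})

test_that("the full preprocessing chain is deterministic and telescopes", {
  co <- tiny_cohort()
  p1 <- preprocess_pipeline(co$betas, co$detection, co$samples,
                            co$annotation, co$cell_reference)
  p2 <- preprocess_pipeline(co$betas, co$detection, co$samples,
                            co$annotation, co$cell_reference)
  expect_identical(p1$betas, p2$betas)
  expect_identical(p1$report, p2$report)
  steps <- p1$report$steps
  for (unit in c("sample", "probe")) {
    ret <- steps$n_retained[steps$unit == unit]
    expect_true(all(diff(ret) <= 0))
  }
  # buccal fractions recover the planted mixture
  tru <- co$truth$cell_proportions[names(p1$buccal)]
  expect_lte(mean(abs(p1$buccal - tru)), 0.05)
})

test_that("sex-mismatch samples are removed by the predicted-sex comparison", {
  co <- tiny_cohort()
  samples <- co$samples
  samples$predicted_sex[3] <- setdiff(c("F", "M"), samples$sex[3])
  res <- drop_sex_mismatch(co$betas, samples)
  expect_identical(res$report$removed_samples$sample_id,
                   samples$sample_id[3])
})
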