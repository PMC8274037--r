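#' @name preprocess
#' @title Beta-value quality control and preprocessing
#' @description
#' The QC chain applied to a raw beta matrix (probes x samples, `NA` =
#' missing): detection-p masking, sample filters (predicted-sex mismatch,
#' missingness, PC outliers), probe filters (missingness, sex chromosomes,
#' SNP-coinciding, cross-hybridizing), quantile normalization, probe-mean
#' imputation, ComBat batch adjustment, reference-based cell-proportion
#' estimation, principal components and the variable-probe SD filter.
NULL

#' Mask entries with unreliable detection
#'
#' Entries whose detection p-value strictly exceeds `threshold` are set
#' missing; a value of exactly `threshold` is retained.
#'
#' @param betas Probes x samples beta matrix.
#' @param detection Detection p-value matrix of identical shape.
#' @param threshold Detection p-value cutoff (default 0.05).
#' @return Beta matrix with masked entries set `NA`.
#' @export
mask_low_detection <- function(betas, detection, threshold = 0.05) {
  if (!identical(dim(betas), dim(detection)))
    stop("beta and detection matrices have different shapes")
  betas[detection > threshold] <- NA
  betas
}

new_qc_report <- function() {
  list(steps = data.frame(step = character(), unit = character(),
                          n_removed = integer(), n_retained = integer(),
                          stringsAsFactors = FALSE),
       removed_samples = data.frame(sample_id = character(), reason = character(),
                                    stringsAsFactors = FALSE),
       removed_probes = data.frame(probe_id = character(), reason = character(),
                                   stringsAsFactors = FALSE))
}

log_qc_step <- function(report, step, unit, removed, retained, ids = NULL,
                        reasons = NULL) {
  report$steps <- rbind(report$steps,
                        data.frame(step = step, unit = unit,
                                   n_removed = length(removed),
                                   n_retained = retained,
                                   stringsAsFactors = FALSE))
  if (length(removed)) {
    add <- data.frame(id = removed,
                      reason = if (is.null(reasons)) step else reasons,
                      stringsAsFactors = FALSE)
    if (unit == "sample") {
      names(add) <- c("sample_id", "reason")
      report$removed_samples <- rbind(report$removed_samples, add)
    } else {
      names(add) <- c("probe_id", "reason")
      report$removed_probes <- rbind(report$removed_probes, add)
    }
  }
  report
}

#' Drop samples with excessive missingness
#'
#' @param betas Probes x samples beta matrix.
#' @param max_fraction Samples with missing fraction strictly greater than
#'   this are removed (default 0.01).
#' @param report An existing QC report to append to, or `NULL`.
#' @return List with `betas` (survivors, order preserved) and `report`.
#' @export
drop_high_missing_samples <- function(betas, max_fraction = 0.01, report = NULL) {
  stopifnot(max_fraction > 0, max_fraction < 1)
  if (is.null(report)) report <- new_qc_report()
  frac <- colMeans(is.na(betas))
  drop <- frac > max_fraction
  report <- log_qc_step(report, "sample_missingness", "sample",
                        colnames(betas)[drop], sum(!drop))
  list(betas = betas[, !drop, drop = FALSE], report = report)
}

#' Drop samples whose self-reported and methylation-predicted sex disagree
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample table with `sample_id`, `sex`, `predicted_sex`.
#' @param report QC report or `NULL`.
#' @return List with `betas` and `report`.
#' @export
drop_sex_mismatch <- function(betas, samples, report = NULL) {
  if (is.null(report)) report <- new_qc_report()
  tab <- samples[match(colnames(betas), samples$sample_id), ]
  drop <- !is.na(tab$predicted_sex) & tab$predicted_sex != tab$sex
  report <- log_qc_step(report, "sex_mismatch", "sample",
                        colnames(betas)[drop], sum(!drop))
  list(betas = betas[, !drop, drop = FALSE], report = report)
}

#' Drop failing probes
#'
#' Removes probes with missing fraction strictly above `max_fraction`, on sex
#' chromosomes, coinciding with SNPs, or flagged as cross-hybridizing. Each
#' removal is attributed to the first matching rule, in that order.
#'
#' @param betas Probes x samples beta matrix.
#' @param annotation Probe annotation with `probe_id`, `chrom`, `snp_flag`,
#'   `crosshyb_flag`.
#' @param max_fraction Missingness cutoff (default 0.01).
#' @param report QC report or `NULL`.
#' @return List with `betas` and `report`.
#' @export
drop_probes <- function(betas, annotation, max_fraction = 0.01, report = NULL) {
  if (is.null(report)) report <- new_qc_report()
  idx <- match(rownames(betas), annotation$probe_id)
  if (anyNA(idx)) stop("unannotated probes: ",
                       paste(utils::head(rownames(betas)[is.na(idx)]), collapse = ", "))
  ann <- annotation[idx, ]
  frac <- rowMeans(is.na(betas))
  reason <- rep(NA_character_, nrow(betas))
  reason[ann$crosshyb_flag] <- "cross_hybridizing"
  reason[ann$snp_flag] <- "snp"
  reason[ann$chrom %in% c("chrX", "chrY", "X", "Y")] <- "sex_chromosome"
  reason[frac > max_fraction] <- "probe_missingness"
  drop <- !is.na(reason)
  report <- log_qc_step(report, "probe_filters", "probe",
                        rownames(betas)[drop], sum(!drop),
                        reasons = reason[drop])
  list(betas = betas[!drop, , drop = FALSE], report = report)
}

#' Quantile-normalize samples
#'
#' Each sample's non-missing values are replaced by the mean-of-sorted-values
#' reference at matching ranks (ties averaged), via
#' [limma::normalizeQuantiles()]. Fully observed samples end up with
#' identical sorted value vectors.
#'
#' @param betas Probes x samples beta matrix (may contain `NA`).
#' @return Normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(betas) {
  if (ncol(betas) < 2) stop("quantile normalization needs at least 2 samples")
  if (any(colSums(!is.na(betas)) == 0)) stop("a sample has no observed values")
  if (nrow(betas) == 1) { # degenerate: every sample gets the reference mean
    out <- matrix(mean(betas, na.rm = TRUE), 1, ncol(betas))
    out[is.na(betas)] <- NA
    dimnames(out) <- dimnames(betas)
    return(out)
  }
  out <- limma::normalizeQuantiles(betas, ties = TRUE)
  dimnames(out) <- dimnames(betas)
  out
}

#' Impute missing entries with the probe mean
#'
#' @param betas Probes x samples beta matrix.
#' @return Matrix with each `NA` replaced by that probe's across-sample mean.
#' @export
impute_probe_mean <- function(betas) {
  nmiss <- rowSums(is.na(betas))
  if (any(nmiss == ncol(betas))) stop("all-missing probe; drop it first")
  if (!any(nmiss > 0)) return(betas)
  means <- rowMeans(betas, na.rm = TRUE)
  idx <- which(is.na(betas), arr.ind = TRUE)
  betas[idx] <- means[idx[, 1]]
  betas
}

#' Adjust batch (chip) effects with ComBat
#'
#' Parametric empirical-Bayes adjustment per probe per batch via
#' [sva::ComBat()]; output is clipped back to \[0, 1\].
#'
#' @param betas Probes x samples beta matrix, no missing values.
#' @param batch Per-sample batch labels (in column order).
#' @param allow_single If `TRUE`, a single batch returns the input unchanged
#'   instead of erroring.
#' @param mean_only If `TRUE` (default) only batch locations are adjusted;
#'   `FALSE` additionally applies the per-batch scale correction. Chip
#'   effects on beta values are predominantly location shifts, and rescaling
#'   near-boundary probes amplifies noise in downstream decompositions.
#' @return Adjusted beta matrix.
#' @export
adjust_batch <- function(betas, batch, allow_single = FALSE,
                         mean_only = TRUE) {
  stopifnot(length(batch) == ncol(betas))
  if (anyNA(betas)) stop("impute before batch adjustment")
  tb <- table(batch)
  if (length(tb) < 2) {
    if (allow_single) return(betas)
    stop("batch adjustment needs at least 2 batches")
  }
  if (any(tb < 2)) stop("singleton batch: ", names(tb)[tb < 2][1])
  # constant probes break ComBat's standardization; pass through unchanged
  v <- apply(betas, 1, stats::var)
  keep <- v > 0
  out <- betas
  adj <- suppressMessages(sva::ComBat(dat = betas[keep, , drop = FALSE],
                                      batch = as.factor(batch),
                                      mean.only = mean_only))
  out[keep, ] <- pmin(pmax(adj, 0), 1)
  out
}

#' Estimate buccal cell proportions by constrained least squares
#'
#' Per sample, solves `beta ~ w_b * ref_buccal + w_g * ref_granulocyte`
#' subject to `w >= 0`, `w_b + w_g <= 1` (quadratic program), and returns the
#' buccal weight.
#'
#' @param betas Probes x samples beta matrix (probe rownames required).
#' @param reference Data frame with `probe_id`, `buccal`, `granulocyte`
#'   reference mean-beta profiles.
#' @return Named per-sample buccal fraction in \[0, 1\].
#' @export
estimate_cell_proportions <- function(betas, reference) {
  shared <- intersect(rownames(betas), reference$probe_id)
  if (length(shared) < 10) stop("fewer than 10 probes shared with the reference")
  R <- as.matrix(reference[match(shared, reference$probe_id),
                           c("buccal", "granulocyte")])
  if (max(abs(R[, 1] - R[, 2])) < 1e-12)
    stop("reference profiles are identical; proportions unidentifiable")
  D <- crossprod(R)
  # constraints: w_b >= 0, w_g >= 0, -(w_b + w_g) >= -1
  Amat <- cbind(diag(2), c(-1, -1))
  bvec <- c(0, 0, -1)
  B <- betas[shared, , drop = FALSE]
  out <- vapply(seq_len(ncol(B)), function(j) {
    y <- B[, j]
    ok <- !is.na(y)
    dvec <- crossprod(R[ok, , drop = FALSE], y[ok])
    Dj <- crossprod(R[ok, , drop = FALSE])
    sol <- quadprog::solve.QP(Dj, dvec, Amat, bvec)
    min(1, max(0, sol$solution[1]))
  }, numeric(1))
  stats::setNames(out, colnames(betas))
}

#' Principal components of the beta matrix
#'
#' Column-centered SVD over samples. The sign of each PC is fixed so its
#' largest-magnitude probe loading is positive.
#'
#' @param betas Probes x samples beta matrix, no missing values.
#' @param k Number of components.
#' @return List with `scores` (samples x k), `eigenvalues` (variances of the
#'   scores, non-increasing) and `loadings` (probes x k).
#' @export
compute_pcs <- function(betas, k) {
  X <- t(betas) # samples x probes
  if (k > min(dim(X))) stop("k exceeds matrix rank bound")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  list(scores = scores, eigenvalues = pc$sdev[seq_len(k)]^2,
       loadings = loadings)
}

#' Remove principal-component outlier samples
#'
#' A sample is removed when, on any of the top `n_pcs` score vectors, its
#' score lies more than `n_sd` standard deviations from the median of that
#' score vector. Single pass; ties at exactly `n_sd` are retained.
#'
#' @param betas Probes x samples beta matrix, no missing values.
#' @param n_pcs Number of top PCs screened (default 4).
#' @param n_sd Distance threshold in SD units (default 3).
#' @param report QC report or `NULL`.
#' @return List with `betas`, `report` and the `scores` used.
#' @export
remove_pc_outliers <- function(betas, n_pcs = 4, n_sd = 3, report = NULL) {
  stopifnot(n_pcs >= 1)
  if (is.null(report)) report <- new_qc_report()
  k <- min(n_pcs, ncol(betas) - 1, nrow(betas))
  pcs <- compute_pcs(betas, k)
  out <- rep(FALSE, ncol(betas))
  for (j in seq_len(k)) {
    s <- pcs$scores[, j]
    out <- out | abs(s - stats::median(s)) > n_sd * stats::sd(s)
  }
  report <- log_qc_step(report, "pc_outlier", "sample",
                        colnames(betas)[out], sum(!out))
  list(betas = betas[, !out, drop = FALSE], report = report,
       scores = pcs$scores)
}

#' Select reliable, variable probes
#'
#' @param betas Imputed probes x samples beta matrix.
#' @param sd_threshold Probes with across-sample SD strictly greater than this
#'   are kept (default 0.1).
#' @return Probe ids, input order preserved.
#' @export
select_variable_probes <- function(betas, sd_threshold = 0.1) {
  sds <- apply(betas, 1, stats::sd)
  rownames(betas)[sds > sd_threshold]
}

#' Run the full preprocessing chain
#'
#' Order: detection-p masking, sex-mismatch and missingness sample filters,
#' PC-outlier sample removal (on an interim probe-mean-imputed copy), probe
#' filters, cell-proportion estimation (on the imputed pre-normalization
#' matrix, to stay on the reference's raw beta scale), quantile
#' normalization, imputation, ComBat batch adjustment, top PCs, SD filter.
#'
#' @param betas,detection Probes x samples matrices.
#' @param samples Sample table.
#' @param annotation Probe annotation table.
#' @param cell_reference Reference profiles for deconvolution (or `NULL` to
#'   skip; buccal proportions then come back as `NA`).
#' @param detection_p,sample_miss,probe_miss,sd_threshold,pc_outlier_sd,pc_outlier_n,n_pcs
#'   Thresholds; defaults are the pipeline's standard settings.
#' @return List with the processed matrix (`betas`), `variable_probes`,
#'   `samples` (filtered table with `buccal` and `PC1..PCk` columns appended),
#'   `pc` (scores/eigenvalues), `buccal`, and the QC `report`.
#' @export
preprocess_pipeline <- function(betas, detection, samples, annotation,
                                cell_reference = NULL,
                                detection_p = 0.05, sample_miss = 0.01,
                                probe_miss = 0.01, sd_threshold = 0.1,
                                pc_outlier_sd = 3, pc_outlier_n = 4,
                                n_pcs = 5) {
  report <- new_qc_report()
  b <- mask_low_detection(betas, detection, detection_p)
  st <- drop_sex_mismatch(b, samples, report)
  st <- drop_high_missing_samples(st$betas, sample_miss, st$report)
  # PC outliers are screened on an interim imputed copy of probes that can be
  # imputed; the matrix carried forward keeps its missing values
  interim <- st$betas[rowSums(is.na(st$betas)) < ncol(st$betas), , drop = FALSE]
  interim <- impute_probe_mean(interim)
  po <- remove_pc_outliers(interim, pc_outlier_n, pc_outlier_sd, st$report)
  b <- st$betas[, colnames(po$betas), drop = FALSE]
  report <- po$report

  pf <- drop_probes(b, annotation, probe_miss, report)
  # deconvolution compares samples against an external reference on the raw
  # beta scale, so it uses the pre-normalization (imputed) matrix
  buccal <- if (!is.null(cell_reference)) {
    estimate_cell_proportions(impute_probe_mean(pf$betas), cell_reference)
  } else stats::setNames(rep(NA_real_, ncol(pf$betas)), colnames(pf$betas))
  b <- quantile_normalize(pf$betas)
  b <- impute_probe_mean(b)
  tab <- samples[match(colnames(b), samples$sample_id), , drop = FALSE]
  b <- adjust_batch(b, tab$batch)

  pc <- compute_pcs(b, min(n_pcs, ncol(b) - 1))
  variable_probes <- select_variable_probes(b, sd_threshold)
  report <- log_qc_step(pf$report, "sd_filter", "probe",
                        setdiff(rownames(b), variable_probes),
                        length(variable_probes))

  tab$buccal <- unname(buccal)
  for (j in seq_len(ncol(pc$scores))) tab[[paste0("PC", j)]] <- pc$scores[, j]
  list(betas = b, variable_probes = variable_probes, samples = tab,
       pc = pc, buccal = buccal, report = report)
}
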