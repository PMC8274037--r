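#' Configuration for the synthetic pmTBI methylation cohort
#'
#' Builds the parameter list consumed by [generate_cohort()]. Defaults emulate
#' a two-group pediatric mild TBI cohort (110 patients, 87 age-matched
#' controls, 13 two-member families among the controls) assayed on a
#' methylation array, with planted batch effects, a two-cell-type mixture,
#' latent pathway methylation components, and linear-Gaussian outcome models.
#'
#' Methylation is simulated on the logit (M-value) scale as a sum of a
#' probe baseline (the logit of a buccal/granulocyte mixture), a per-probe
#' per-batch shift, a planted component signal on pathway probes, a family
#' random intercept and Gaussian noise, then squashed back to beta scale.
#'
#' @param n_pmtbi,n_hc Group sizes.
#' @param n_ec_pmtbi Number of patients returning at the early chronic (EC)
#'   visit (outcomes are `NA` for the rest).
#' @param n_two_member_families Number of sibling pairs (controls only).
#' @param n_probes Total probes, including QC decoys.
#' @param n_pathway_probes Probes mapped to the depression-pathway gene set.
#' @param n_prior_probes BDNF/APOE prior probes (moderate variance, not in the
#'   pathway set).
#' @param n_true_components Latent components planted on the pathway probes.
#' @param component_amplitudes Logit-scale amplitude of each component
#'   (recycled to `n_true_components`); descending values fix the planted
#'   variance ordering.
#' @param source_sparsity Fraction of pathway probes each component loads on
#'   (spike-and-slab Laplace source rows; methylation components
#'   characteristically involve a subset of CpGs).
#' @param pathway_noise_range Per-probe logit noise SD range for pathway
#'   probes, drawn uniformly; these sites are intermediately methylated and
#'   biologically variable, which is what carries them past the SD filter.
#' @param n_batches Number of chips/batches.
#' @param batch_shift_sd SD of the per-probe per-batch logit shift.
#' @param cell_reference_separation Logit-scale mean difference between the
#'   buccal and granulocyte reference profiles at cell-informative probes.
#' @param component_effect_weights Outcome units per loading SD, one per true
#'   component; applied to the quality-of-life outcome.
#' @param clinical_effect_weights Named vector of outcome-units-per-feature-unit
#'   weights on the symptom-burden outcome (the quality-of-life outcome uses
#'   `-0.8` times these).
#' @param noise_sd_outcome Residual SD of the outcome models. For the
#'   symptom-burden outcome the patient group's residual SD is inflated by
#'   `pcsi_noise_factor_pmtbi`, reproducing the marked variance heterogeneity
#'   of symptom scores (controls cluster near zero, patients spread widely).
#' @param pcsi_noise_factor_pmtbi Patient/control residual-SD ratio for the
#'   symptom outcome (default 2.2).
#' @param n_dx_probes Number of (non-pathway) probes carrying a planted
#'   diagnosis effect for the methylome-wide association stage.
#' @param dx_effect Logit-scale hypermethylation of patients at those probes.
#' @param family_sd_outcome,family_sd_meth SD of the shared family intercepts
#'   (outcome units and logit units respectively).
#' @param noise_sd_meth Logit-scale measurement noise SD.
#' @param missing_rate Fraction of beta entries set missing at random.
#' @param detection_fail_rate Fraction of detection p-values drawn above 0.05.
#' @param seed Integer seed; fully determines the cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pmtbi = 110,
                             n_hc = 87,
                             n_ec_pmtbi = 91,
                             n_two_member_families = 13,
                             n_probes = 2000,
                             n_pathway_probes = 223,
                             n_prior_probes = 13,
                             n_true_components = 5,
                             component_amplitudes = seq(8, 4.5, length.out = n_true_components),
                             source_sparsity = 0.3,
                             pathway_noise_range = c(0.45, 0.55),
                             n_batches = 4,
                             batch_shift_sd = 0.15,
                             cell_reference_separation = 2,
                             component_effect_weights = c(0, 0, 3, 3, -4),
                             clinical_effect_weights = c(age = -1.0,
                                                         prev_concussions = 2.0,
                                                         attention_acc = -2.0,
                                                         depression_SA = 0.5,
                                                         pain_SA = 1.5,
                                                         PCSI_SA = 0.15),
                             noise_sd_outcome = 5,
                             pcsi_noise_factor_pmtbi = 2.2,
                             n_dx_probes = 2,
                             dx_effect = 0.6,
                             family_sd_outcome = 2,
                             family_sd_meth = 0.1,
                             noise_sd_meth = 0.3,
                             missing_rate = 0.002,
                             detection_fail_rate = 0.001,
                             seed = 7) {
  cfg <- list(n_pmtbi = n_pmtbi, n_hc = n_hc, n_ec_pmtbi = n_ec_pmtbi,
              n_two_member_families = n_two_member_families,
              n_probes = n_probes, n_pathway_probes = n_pathway_probes,
              n_prior_probes = n_prior_probes,
              n_true_components = n_true_components,
              component_amplitudes = rep_len(component_amplitudes, n_true_components),
              source_sparsity = source_sparsity,
              pathway_noise_range = pathway_noise_range,
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              cell_reference_separation = cell_reference_separation,
              component_effect_weights = rep_len(component_effect_weights, n_true_components),
              clinical_effect_weights = clinical_effect_weights,
              noise_sd_outcome = noise_sd_outcome,
              pcsi_noise_factor_pmtbi = pcsi_noise_factor_pmtbi,
              n_dx_probes = n_dx_probes,
              dx_effect = dx_effect,
              family_sd_outcome = family_sd_outcome,
              family_sd_meth = family_sd_meth,
              noise_sd_meth = noise_sd_meth,
              missing_rate = missing_rate,
              detection_fail_rate = detection_fail_rate,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_pmtbi >= 1, cfg$n_hc >= 1, cfg$n_probes >= 1,
            cfg$n_pathway_probes >= 1, cfg$n_batches >= 1,
            cfg$n_ec_pmtbi <= cfg$n_pmtbi,
            cfg$n_true_components <= cfg$n_pathway_probes,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$detection_fail_rate >= 0, cfg$detection_fail_rate < 1,
            2 * cfg$n_two_member_families <= cfg$n_hc)
  n_decoys <- 25 + 10 + 30 + 20 + 10 # chrX, chrY, SNP, cross-hyb, high-missing
  if (cfg$n_probes < cfg$n_pathway_probes + cfg$n_prior_probes + n_decoys + 50)
    stop("n_probes too small to host pathway, prior, decoy and filler probes")
  planted_var_zero <- cfg$n_true_components == 0 ||
    all(cfg$component_amplitudes == 0)
  if (planted_var_zero && any(cfg$component_effect_weights != 0))
    stop("component_effect_weights are nonzero but the planted signal has zero variance")
  invisible(cfg)
}

rlaplace_unit <- function(n) {
  # iid Laplace with unit variance (scale 1/sqrt(2))
  stats::rexp(n, rate = sqrt(2)) * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates the four pipeline inputs (beta matrix, detection-p matrix, sample
#' sheet, probe annotation plus pathway gene regions) together with a truth
#' record holding the planted mixing/source matrices, batch assignments,
#' buccal proportions, family ids and outcome models, and the beta-scale
#' reference profiles for cell-type deconvolution.
#'
#' Probe classes: pathway probes (carry the planted component signal and are
#' placed inside or within 20 kb of the pathway gene regions), BDNF/APOE prior
#' probes (moderate variance, outside the pathway regions), QC decoys
#' (chrX/chrY, SNP-flagged, cross-hybridizing, high-missingness) and fillers,
#' a third of which are cell-informative.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `betas` (probes x samples, `NA` = missing),
#'   `detection` (same shape), `samples` (data frame), `annotation`
#'   (data frame), `regions` (data frame: gene, chrom, start, end; 0-based
#'   half-open), `truth` (list) and `cell_reference` (data frame).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_pmtbi + config$n_hc
  k <- config$n_true_components

  ## ---- samples, families, covariates -------------------------------------
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- c(rep("pmTBI", config$n_pmtbi), rep("HC", config$n_hc))
  hc_idx <- which(group == "HC")
  family_id <- character(n)
  family_id[group == "pmTBI"] <- sprintf("F%03d", seq_len(config$n_pmtbi))
  paired <- sample(hc_idx, 2 * config$n_two_member_families)
  fam_counter <- config$n_pmtbi
  for (j in seq_len(config$n_two_member_families)) {
    fam_counter <- fam_counter + 1
    family_id[paired[c(2 * j - 1, 2 * j)]] <- sprintf("F%03d", fam_counter)
  }
  singles_hc <- setdiff(hc_idx, paired)
  family_id[singles_hc] <- sprintf("F%03d", fam_counter + seq_along(singles_hc))

  batch <- sprintf("chip%02d", sample(rep_len(seq_len(config$n_batches), n)))
  age <- pmin(18, pmax(8, stats::rnorm(n, 14.9, 2.07)))
  sex <- ifelse(stats::runif(n) < 0.45, "F", "M")
  bmi <- pmin(45, pmax(14, stats::rnorm(n, 22.5, 5)))
  race <- sample(c("White", "African-American", "other"), n, replace = TRUE,
                 prob = c(0.83, 0.025, 0.145))
  is_tbi <- as.numeric(group == "pmTBI")
  buccal <- stats::rbeta(n, 5, 3)

  ## ---- planted components -------------------------------------------------
  A_std <- matrix(stats::rnorm(n * k), n, k)         # loadings, unit SD
  np <- config$n_pathway_probes
  S_true <- matrix(rlaplace_unit(k * np) *
                     (stats::runif(k * np) < config$source_sparsity), k, np)
  for (j in seq_len(k)) {                            # no all-zero source rows
    if (all(S_true[j, ] == 0))
      S_true[j, sample.int(np, 1)] <- rlaplace_unit(1)
  }
  S_true <- S_true / sqrt(rowSums(S_true^2))          # unit-norm source rows
  mixing <- A_std %*% diag(config$component_amplitudes, k, k)
  planted_signal <- mixing %*% S_true                 # samples x pathway probes

  ## ---- clinical features --------------------------------------------------
  depression_SA <- stats::rnorm(n, 50, 9) + 5 * is_tbi +
    1.5 * A_std[, min(3, k)] - 1.5 * A_std[, min(5, k)]
  depression_EC <- 25 + 0.5 * depression_SA + 2 * is_tbi + stats::rnorm(n, 0, 7)
  sleep_SA <- stats::rnorm(n, 50, 10) + 3 * is_tbi
  anxiety_SA <- stats::rnorm(n, 50, 10) + 2 * is_tbi
  pain_SA <- stats::rpois(n, lambda = ifelse(is_tbi == 1, 2, 0.3))
  prev_concussions <- stats::rpois(n, 0.4)
  loc <- ifelse(is_tbi == 1, stats::rbinom(n, 1, 0.2), 0)
  pta <- ifelse(is_tbi == 1, stats::rbinom(n, 1, 0.15), 0)
  rta <- ifelse(is_tbi == 1, stats::rbinom(n, 1, 0.1), 0)
  tobacco <- stats::rbinom(n, 1, 0.03 + 0.05 * is_tbi)
  alcohol <- stats::rbinom(n, 1, 0.08 + 0.07 * is_tbi)
  cannabis <- stats::rbinom(n, 1, 0.04 + 0.08 * is_tbi)
  attention_acc <- stats::rnorm(n) - 0.3 * is_tbi
  processing_speed <- stats::rnorm(n)
  working_memory <- stats::rnorm(n)
  visual_learning <- stats::rnorm(n)
  days_post_injury_SA <- ifelse(is_tbi == 1,
                                pmax(1, round(stats::rnorm(n, 7.3, 2.3))), 0)
  visit_interval <- round(stats::rnorm(n, 123, 14))
  zemek_risk <- pmax(0, pmin(12, round(3 + 0.8 * prev_concussions +
                                         0.5 * (sex == "F") +
                                         0.2 * (age - 12) + stats::rnorm(n, 0, 1.5))))
  PCSI_SA <- pmax(0, stats::rnorm(n, mean = ifelse(is_tbi == 1, 25, 6),
                                  sd = ifelse(is_tbi == 1, 26, 9)))
  PedsQL_SA <- pmax(0, pmin(100, stats::rnorm(n, 86 - 2 * is_tbi, 11)))

  ## ---- outcomes -----------------------------------------------------------
  cw <- config$clinical_effect_weights
  feat <- cbind(age = age, prev_concussions = prev_concussions,
                attention_acc = attention_acc, depression_SA = depression_SA,
                pain_SA = pain_SA, PCSI_SA = PCSI_SA, sleep_SA = sleep_SA,
                bmi = bmi)
  missing_w <- setdiff(names(cw), colnames(feat))
  if (length(missing_w)) stop("unknown clinical_effect_weights: ",
                              paste(missing_w, collapse = ", "))
  Fc <- scale(feat[, names(cw), drop = FALSE], center = TRUE, scale = FALSE)
  lin_pcsi <- drop(Fc %*% cw)
  qol_cw <- -0.8 * cw # quality of life loads on the same features, inverted
  lin_qol <- drop(Fc %*% qol_cw)
  comp_qol <- drop(A_std %*% config$component_effect_weights)

  fam_levels <- unique(family_id)
  fam_out <- stats::rnorm(length(fam_levels), 0, config$family_sd_outcome)
  names(fam_out) <- fam_levels
  fam_out_q <- stats::rnorm(length(fam_levels), 0, config$family_sd_outcome)
  names(fam_out_q) <- fam_levels

  pcsi_signal <- lin_pcsi
  qol_signal <- lin_qol + comp_qol
  pcsi_noise_sd <- config$noise_sd_outcome *
    ifelse(is_tbi == 1, config$pcsi_noise_factor_pmtbi, 1)
  PCSI_EC <- pmax(0, 10 + pcsi_signal + fam_out[family_id] +
                    stats::rnorm(n, 0, pcsi_noise_sd))
  PedsQL_EC <- pmax(0, pmin(100, 86 + qol_signal + fam_out_q[family_id] +
                              stats::rnorm(n, 0, config$noise_sd_outcome)))

  ec_return <- rep(TRUE, n)
  if (config$n_ec_pmtbi < config$n_pmtbi) {
    dropouts <- sample(seq_len(config$n_pmtbi),
                       config$n_pmtbi - config$n_ec_pmtbi)
    ec_return[dropouts] <- FALSE
    PCSI_EC[dropouts] <- NA
    PedsQL_EC[dropouts] <- NA
    depression_EC[dropouts] <- NA
  }

  samples <- data.frame(
    sample_id = sample_id, family_id = family_id, group = group,
    batch = batch, age = age, sex = sex, predicted_sex = sex, bmi = bmi,
    race = race, days_post_injury_SA = days_post_injury_SA,
    visit_interval = visit_interval, prev_concussions = prev_concussions,
    loc = loc, pta = pta, rta = rta, tobacco = tobacco, alcohol = alcohol,
    cannabis = cannabis, zemek_risk = zemek_risk,
    depression_SA = depression_SA, depression_EC = depression_EC,
    anxiety_SA = anxiety_SA, sleep_SA = sleep_SA, pain_SA = pain_SA,
    attention_acc = attention_acc, processing_speed = processing_speed,
    working_memory = working_memory, visual_learning = visual_learning,
    PCSI_SA = PCSI_SA, PCSI_EC = PCSI_EC, PedsQL_SA = PedsQL_SA,
    PedsQL_EC = PedsQL_EC, ec_return = ec_return,
    stringsAsFactors = FALSE)

  ## ---- probe classes and annotation --------------------------------------
  m <- config$n_probes
  n_chrx <- 25; n_chry <- 10; n_snp <- 30; n_xhyb <- 20; n_himiss <- 10
  n_special <- config$n_pathway_probes + config$n_prior_probes +
    n_chrx + n_chry + n_snp + n_xhyb + n_himiss
  n_fill <- m - n_special
  probe_class <- c(rep("pathway", config$n_pathway_probes),
                   rep("prior", config$n_prior_probes),
                   rep("chrX", n_chrx), rep("chrY", n_chry),
                   rep("snp", n_snp), rep("xhyb", n_xhyb),
                   rep("himiss", n_himiss), rep("filler", n_fill))
  probe_id <- sprintf("cg%08d", sample.int(9.9e7, m))

  # pathway gene regions live at >= 100 Mb so nothing else falls in a flank
  n_genes <- max(8, min(40, ceiling(config$n_pathway_probes / 6)))
  gene_chrom <- sprintf("chr%d", sample(1:22, n_genes, replace = TRUE))
  gene_start <- round(stats::runif(n_genes, 100e6, 140e6))
  gene_len <- round(stats::runif(n_genes, 5e3, 5e4))
  regions <- data.frame(gene = sprintf("DEPG%03d", seq_len(n_genes)),
                        chrom = gene_chrom, start = gene_start,
                        end = gene_start + gene_len, stringsAsFactors = FALSE)

  chrom <- character(m); pos <- integer(m); gene <- character(m)
  path_idx <- which(probe_class == "pathway")
  assign_gene <- sample(seq_len(n_genes), length(path_idx), replace = TRUE)
  for (i in seq_along(path_idx)) {
    g <- assign_gene[i]
    # inside the gene body or within the 20 kb flank (half-open on the right)
    lo <- regions$start[g] - 19999
    hi <- regions$end[g] + 19999
    chrom[path_idx[i]] <- regions$chrom[g]
    pos[path_idx[i]] <- round(stats::runif(1, lo, hi))
    gene[path_idx[i]] <- regions$gene[g]
  }
  other_idx <- which(probe_class != "pathway")
  chrom[other_idx] <- sprintf("chr%d", sample(1:22, length(other_idx), replace = TRUE))
  pos[other_idx] <- round(stats::runif(length(other_idx), 1e5, 9e7))
  chrom[probe_class == "chrX"] <- "chrX"
  chrom[probe_class == "chrY"] <- "chrY"
  gene[other_idx] <- ""
  prior_idx <- which(probe_class == "prior")
  gene[prior_idx] <- sample(c("BDNF", "APOE"), length(prior_idx), replace = TRUE)
  chrom[prior_idx] <- ifelse(gene[prior_idx] == "BDNF", "chr11", "chr19")

  annotation <- data.frame(
    probe_id = probe_id, chrom = chrom, pos = pos,
    island_relation = sample(c("Island", "N_Shore", "S_Shore", "OpenSea"),
                             m, replace = TRUE, prob = c(0.25, 0.1, 0.1, 0.55)),
    gene = gene,
    snp_flag = probe_class == "snp",
    crosshyb_flag = probe_class == "xhyb",
    stringsAsFactors = FALSE)

  ## ---- methylation matrix (logit-additive, beta-squashed) -----------------
  mu <- numeric(m)
  mu[probe_class == "pathway"] <- stats::rnorm(config$n_pathway_probes, 0, 0.25)
  mu[probe_class == "prior"] <- stats::rnorm(config$n_prior_probes, 0, 0.3)
  fill_like <- probe_class %in% c("filler", "chrX", "chrY", "snp", "xhyb", "himiss")
  n_fl <- sum(fill_like)
  mu[fill_like] <- sample(c(-3, 0, 3), n_fl, replace = TRUE,
                          prob = c(0.4, 0.2, 0.4)) + stats::rnorm(n_fl, 0, 0.8)

  cell_d <- numeric(m)
  fill_idx <- which(probe_class == "filler")
  cell_idx <- sample(fill_idx, round(length(fill_idx) / 3))
  mu[cell_idx] <- stats::rnorm(length(cell_idx), 0, 0.5)
  cell_d[cell_idx] <- sample(c(-1, 1), length(cell_idx), replace = TRUE) *
    config$cell_reference_separation
  ref_gran <- inv_logit(mu)
  ref_buccal <- inv_logit(mu + cell_d)

  # exact beta-scale mixture, expressed as a logit-additive base term
  mix <- ref_gran %o% rep(1, n) + (ref_buccal - ref_gran) %o% buccal
  base_logit <- logit(squeeze_beta(mix))

  batch_levels <- sort(unique(batch))
  batch_shift <- matrix(stats::rnorm(m * length(batch_levels), 0,
                                     config$batch_shift_sd),
                        m, length(batch_levels),
                        dimnames = list(NULL, batch_levels))
  fam_meth <- stats::rnorm(length(fam_levels), 0, config$family_sd_meth)
  names(fam_meth) <- fam_levels

  noise_sd_probe <- rep(config$noise_sd_meth, m)
  noise_sd_probe[probe_class == "pathway"] <-
    stats::runif(config$n_pathway_probes, config$pathway_noise_range[1],
                 config$pathway_noise_range[2])
  M <- base_logit + batch_shift[, batch] +
    rep(1, m) %o% fam_meth[family_id] +
    matrix(stats::rnorm(m * n), m, n) * noise_sd_probe
  M[path_idx, ] <- M[path_idx, ] + t(planted_signal)
  dx_idx <- integer(0)
  if (config$n_dx_probes > 0) { # hypermethylated in patients, for the MWAS
    dx_idx <- sample(which(probe_class == "filler" & cell_d == 0),
                     config$n_dx_probes)
    M[dx_idx, ] <- M[dx_idx, ] +
      rep(config$dx_effect, length(dx_idx)) %o% is_tbi
  }
  betas <- inv_logit(M)
  dimnames(betas) <- list(probe_id, sample_id)

  ## ---- missingness and detection p-values ---------------------------------
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(m * n) < config$missing_rate, m, n)
    betas[miss] <- NA
  }
  himiss_idx <- which(probe_class == "himiss")
  for (j in himiss_idx) {
    betas[j, sample(n, max(1, ceiling(0.03 * n)))] <- NA
  }
  detection <- matrix(stats::runif(m * n, 0, 0.049), m, n,
                      dimnames = list(probe_id, sample_id))
  if (config$detection_fail_rate > 0) {
    fail <- matrix(stats::runif(m * n) < config$detection_fail_rate, m, n)
    detection[fail] <- stats::runif(sum(fail), 0.051, 1)
  }

  cell_reference <- data.frame(probe_id = probe_id[cell_idx],
                               buccal = ref_buccal[cell_idx],
                               granulocyte = ref_gran[cell_idx],
                               stringsAsFactors = FALSE)

  truth <- list(
    mixing_matrix = structure(mixing, dimnames = list(sample_id, NULL)),
    source_matrix = structure(S_true,
                              dimnames = list(NULL, probe_id[path_idx])),
    loadings_std = structure(A_std, dimnames = list(sample_id, NULL)),
    planted_signal = structure(planted_signal,
                               dimnames = list(sample_id, probe_id[path_idx])),
    batch_assignments = stats::setNames(batch, sample_id),
    batch_shift = batch_shift,
    cell_proportions = stats::setNames(buccal, sample_id),
    family_ids = stats::setNames(family_id, sample_id),
    probe_class = stats::setNames(probe_class, probe_id),
    dx_probes = probe_id[dx_idx],
    planted_outcome_model = list(
      PCSI_EC = list(intercept = 10, clinical = cw,
                     components = rep(0, k)),
      PedsQL_EC = list(intercept = 86, clinical = qol_cw,
                       components = config$component_effect_weights)),
    outcome_signal = data.frame(sample_id = sample_id,
                                PCSI_EC = pcsi_signal,
                                PedsQL_EC = qol_signal,
                                stringsAsFactors = FALSE),
    config = config)

  list(betas = betas, detection = detection, samples = samples,
       annotation = annotation, regions = regions, truth = truth,
       cell_reference = cell_reference)
}

#' Write a synthetic cohort to the standard pipeline input files
#'
#' Beta and detection matrices as TSV (probe id first column), sample sheet as
#' CSV, probe annotation as TSV, gene regions as BED-like TSV (0-based
#' half-open) and the truth record as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(betas = file.path(dir, "betas.tsv"),
             detection = file.path(dir, "detection_p.tsv"),
             samples = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "probe_annotation.tsv"),
             regions = file.path(dir, "gene_regions.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix_tsv(cohort$betas, paths["betas"])
  write_matrix_tsv(cohort$detection, paths["detection"])
  utils::write.csv(cohort$samples, paths["samples"], row.names = FALSE)
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$regions, paths["regions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(paths)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a probes-by-samples TSV written by [write_matrix_tsv] conventions
#' @param path TSV with probe id in the first column.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
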