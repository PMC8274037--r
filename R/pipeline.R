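#' Pipeline configuration
#'
#' Bundles every threshold of the analysis chain with its standard default:
#' detection p 0.05, sample/probe missingness 0.01, SD filter 0.1, 20 kb
#' pathway flank, PPCS z 1.64, 70/30 split, alpha 0.05 and methylation PC
#' covariates 2-4.
#'
#' @param synthetic A [synthetic_config()] describing the cohort to simulate
#'   (or `NULL` when calling [run_pipeline()] with pre-built inputs).
#' @param detection_p,sample_miss,probe_miss,sd_threshold QC thresholds.
#' @param pc_outlier_sd,pc_outlier_n Sample PC-outlier rule.
#' @param flank Pathway mapping flank in bp.
#' @param pc_covariates Indices of methylation PCs used as covariates.
#' @param ica_candidates,ica_runs,ica_floor Component-count estimation
#'   settings.
#' @param lambda_grid_length Penalty grid resolution.
#' @param epsilon SVR tube half-width (scaled outcome).
#' @param split_fraction,alpha,z_threshold,pseudo Prediction/classification
#'   settings.
#' @param n_perm Permutations for the fitted-depression null.
#' @param seed Master seed for split/ICA/permutations.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            detection_p = 0.05, sample_miss = 0.01,
                            probe_miss = 0.01, sd_threshold = 0.1,
                            pc_outlier_sd = 3, pc_outlier_n = 4,
                            flank = 20000,
                            pc_covariates = c(2, 3, 4),
                            ica_candidates = 2:8, ica_runs = 8,
                            ica_floor = 0.8,
                            lambda_grid_length = 15,
                            epsilon = 0.1,
                            split_fraction = 0.7, alpha = 0.05,
                            z_threshold = 1.64, pseudo = 1,
                            n_perm = 199,
                            seed = 42) {
  structure(as.list(environment()), class = "pipeline_config")
}

model_feature_sets <- function() {
  list(
    model1 = c("age", "sex", "bmi", "visit_interval", "prev_concussions",
               "loc", "pta", "rta", "depression_SA", "sleep_SA", "pain_SA",
               "PCSI_SA", "processing_speed", "attention_acc",
               "visual_learning", "working_memory", "tobacco", "alcohol",
               "cannabis"),
    model4 = c("zemek_risk", "prev_concussions", "loc", "pta", "rta",
               "days_post_injury_SA"))
}

build_features <- function(table, features) {
  cols <- lapply(features, function(f) {
    if (f == "sex") as.numeric(table$sex == "F") else as.numeric(table[[f]])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(table$sample_id, features)
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generate, preprocess, test (MWAS + global methylation), factorize the
#' pathway probes, train/evaluate the five prediction models for both
#' outcomes, classify PPCS, and run the secondary analyses. All randomness
#' derives from the seeds in `config`; identical configurations give
#' identical reports.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-generated cohort (as from [generate_cohort()]);
#'   defaults to generating one from `config$synthetic`.
#' @return A run report: nested list with `qc`, `mwas`, `ica`, `models`,
#'   `ppcs`, `secondary` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config$synthetic)

  ## ---- preprocessing ------------------------------------------------------
  prep <- preprocess_pipeline(
    cohort$betas, cohort$detection, cohort$samples, cohort$annotation,
    cell_reference = cohort$cell_reference,
    detection_p = config$detection_p, sample_miss = config$sample_miss,
    probe_miss = config$probe_miss, sd_threshold = config$sd_threshold,
    pc_outlier_sd = config$pc_outlier_sd, pc_outlier_n = config$pc_outlier_n)
  tab <- prep$samples
  pc_names <- paste0("PC", config$pc_covariates)

  ## ---- MWAS: diagnosis on all retained probes ----------------------------
  spec_dx <- mwas_spec(predictor = "diagnosis",
                       covariates = c("age", "sex", "bmi", "race", "buccal",
                                      pc_names))
  mwas_dx <- run_mwas(prep$betas, spec_dx, tab, annotation = cohort$annotation)
  gm <- global_methylation(prep$betas)
  gm_test <- fit_probe_lmm(unname(gm), spec_dx, tab)

  ## ---- pathway ICA --------------------------------------------------------
  mapped <- intersect(
    map_pathway_probes(cohort$regions, cohort$annotation, config$flank),
    prep$variable_probes)
  tbi_ids <- tab$sample_id[tab$group == "pmTBI"]
  hc_ids <- tab$sample_id[tab$group == "HC"]
  # decomposition runs on M-values: the logit transform undoes the boundary
  # compression of the beta scale, keeping the mixture model additive
  meth_M <- logit(squeeze_beta(prep$betas[mapped, , drop = FALSE]))
  X_ica <- t(meth_M[, tbi_ids, drop = FALSE])
  k_hat <- estimate_component_number(X_ica, config$ica_candidates,
                                     n_runs = config$ica_runs,
                                     seed = config$seed,
                                     floor = config$ica_floor)
  ica <- fit_ica(X_ica, as.integer(k_hat), seed = config$seed)
  var_ret <- variance_retained(ica, X_ica)
  A_hc <- project_loadings(ica, t(meth_M[, hc_ids, drop = FALSE]))
  loadings_all <- rbind(ica$A, A_hc)[tab$sample_id[tab$sample_id %in%
                                                     c(tbi_ids, hc_ids)], ,
                                     drop = FALSE]

  ## ---- feature matrices ---------------------------------------------------
  fs <- model_feature_sets()
  clin <- build_features(tab, fs$model1)
  meth <- cbind(global_meth = gm[rownames(loadings_all)],
                loadings_all)
  prior_clin <- build_features(tab, fs$model4)
  ann <- cohort$annotation
  prior_ids <- intersect(
    ann$probe_id[ann$gene %in% c("BDNF", "APOE")], rownames(prep$betas))
  prior_sd <- apply(prep$betas[prior_ids, , drop = FALSE], 1, stats::sd)
  prior_ids <- prior_ids[prior_sd > 0.05]
  prior_meth <- t(prep$betas[prior_ids, , drop = FALSE])

  ## ---- prediction models --------------------------------------------------
  ec_ids <- tab$sample_id[tab$group == "pmTBI" & tab$ec_return &
                            !is.na(tab$PCSI_EC) & !is.na(tab$PedsQL_EC)]
  split <- split_train_test(tab[match(ec_ids, tab$sample_id), ],
                            fraction = config$split_fraction,
                            stratify_by = "sex", seed = config$seed)
  grid <- default_lambda_grid(length(split$train), config$lambda_grid_length)

  ppcs <- classify_ppcs(
    patient_scores = tab$PCSI_EC[match(ec_ids, tab$sample_id)],
    hc_scores = tab$PCSI_EC[tab$group == "HC" & !is.na(tab$PCSI_EC)],
    threshold = config$z_threshold, pseudo = config$pseudo, ids = ec_ids)

  run_outcome <- function(outcome) {
    y <- stats::setNames(tab[[outcome]], tab$sample_id)
    direction <- if (outcome == "PedsQL_EC") "lower_is_ppcs" else "higher_is_ppcs"
    tm <- function(feats, mode) {
      train_model(feats, y, split$train, split$test, selection_mode = mode,
                  lambda_grid = grid, epsilon = config$epsilon,
                  alpha = config$alpha)
    }
    m1 <- tm(clin, "select")
    m2 <- tm(meth, "select")
    union_feats <- c(m1$selected_features, m2$selected_features)
    m3 <- if (length(union_feats)) {
      tm(cbind(clin, meth)[, union_feats, drop = FALSE], "fixed")
    } else NULL
    m4 <- tm(prior_clin, "fixed")
    m5 <- if (ncol(prior_meth)) tm(prior_meth, "fixed") else NULL
    models <- list(model1 = m1, model2 = m2, model3 = m3, model4 = m4,
                   model5 = m5)
    lapply(models, function(m) {
      if (is.null(m)) return(NULL)
      add_auc <- function(side) {
        ids <- names(m$report[[side]]$predicted)
        lab <- ppcs$label[match(ids, ppcs$sample_id)]
        auc <- tryCatch(
          roc_auc(m$report[[side]]$predicted, lab, direction)$auc,
          error = function(e) NA_real_)
        auc
      }
      m$report$train$auc <- add_auc("train")
      m$report$test$auc <- add_auc("test")
      m
    })
  }
  models <- list(PCSI_EC = run_outcome("PCSI_EC"),
                 PedsQL_EC = run_outcome("PedsQL_EC"))

  ## ---- secondary analyses -------------------------------------------------
  sel_clin <- unique(c(models$PCSI_EC$model1$selected_features,
                       models$PedsQL_EC$model1$selected_features))
  # model covariates and features with trivially obvious group differences
  # (injury characteristics, symptom load) are not re-tested
  sel_clin <- setdiff(sel_clin, c("sex", "age", "bmi", "visit_interval",
                                  "loc", "pta", "rta", "PCSI_SA", "pain_SA",
                                  "days_post_injury_SA"))
  sec_a <- if (length(sel_clin)) do.call(rbind, lapply(sel_clin, function(f) {
    group_difference(as.numeric(tab[[f]]), "clinical", tab, target = f,
                     pcs = pc_names)
  })) else NULL
  if (!is.null(sec_a)) sec_a$q <- bh_fdr(sec_a$p)

  meth_feats <- cbind(global_meth = gm[rownames(loadings_all)], loadings_all)
  sec_b <- do.call(rbind, lapply(colnames(meth_feats), function(f) {
    group_difference(meth_feats[tab$sample_id, f], "methylation", tab,
                     target = f, pcs = pc_names)
  }))
  sec_b$q <- bh_fdr(sec_b$p)

  tbi_tab <- tab[tab$group == "pmTBI", , drop = FALSE]
  sec_c <- do.call(rbind, lapply(colnames(meth_feats), function(f) {
    do.call(rbind, lapply(c("PCSI_EC", "PedsQL_EC", "depression_EC"),
                          function(oc) {
      methylation_outcome_association(meth_feats[tbi_tab$sample_id, f], oc,
                                      tbi_tab, target = f, pcs = pc_names)
    }))
  }))
  sec_c$q <- stats::ave(sec_c$p, sec_c$outcome, FUN = bh_fdr)

  sec_d <- lapply(c(SA = "SA", EC = "EC"), function(v) {
    fd <- fitted_depression_score(loadings_all[tbi_tab$sample_id, , drop = FALSE],
                                  tbi_tab, visit = v, n_perm = config$n_perm,
                                  seed = config$seed)
    fd$fitted <- NULL
    fd
  })

  ## ---- report -------------------------------------------------------------
  summarize_model <- function(m) {
    if (is.null(m)) return(NULL)
    list(selected_features = m$selected_features,
         weights = m$weights, lambda = m$lambda,
         train = m$report$train[c("r", "p", "mse", "auc")],
         test = m$report$test[c("r", "p", "mse", "auc")])
  }
  cfg_json <- jsonlite::toJSON(list(config = unclass(config),
                                    synthetic = unclass(config$synthetic)),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  report <- list(
    qc = prep$report,
    counts = list(n_samples = ncol(prep$betas),
                  n_probes_retained = nrow(prep$betas),
                  n_variable_probes = length(prep$variable_probes),
                  n_pathway_mapped = length(mapped),
                  n_prior_probes = length(prior_ids),
                  n_ec_patients = length(ec_ids),
                  n_train = length(split$train), n_test = length(split$test)),
    mwas = list(top = utils::head(mwas_dx, 10),
                n_fdr_hits = sum(mwas_dx$q < 0.05, na.rm = TRUE),
                global_methylation = gm_test),
    ica = list(k = as.integer(k_hat),
               consistency = attr(k_hat, "consistency"),
               variance_retained = var_ret, r2 = ica$r2),
    ppcs = list(n_ppcs = sum(ppcs$label == "PPCS"),
                n_recovered = sum(ppcs$label == "recovered"),
                labels = ppcs),
    models = lapply(models, function(oc) lapply(oc, summarize_model)),
    split = split,
    secondary = list(a = sec_a, b = sec_b, c = sec_c, d = sec_d),
    provenance = list(seed = config$seed,
                      synthetic_seed = config$synthetic$seed,
                      thresholds = list(
                        detection_p = config$detection_p,
                        sample_miss = config$sample_miss,
                        probe_miss = config$probe_miss,
                        sd_threshold = config$sd_threshold,
                        flank = config$flank,
                        z_threshold = config$z_threshold,
                        split_fraction = config$split_fraction,
                        alpha = config$alpha,
                        pc_covariates = config$pc_covariates),
                      config_md5 = unname(tools::md5sum(tf))))
  unlink(tf)
  ## full objects for downstream analysis scripts
  attr(report, "objects") <- list(prep = prep, mwas = mwas_dx, ica = ica,
                                  loadings_all = loadings_all, models = models,
                                  cohort = cohort, features = list(
                                    clinical = clin, methylation = meth,
                                    prior_clin = prior_clin,
                                    prior_meth = prior_meth))
  report
}
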