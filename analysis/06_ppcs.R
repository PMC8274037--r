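# Persistent post-concussion symptom classification: symptom sums at
# follow-up are log10(x+1)-transformed, standardized against the control
# distribution, and thresholded at z > 1.64; predicted scores from the
# trained models are then evaluated as PPCS classifiers by ROC/AUC.

source("analysis/00_common.R")

rep <- get_report()
ppcs <- rep$ppcs$labels

message("PPCS classification at z > 1.64: ", rep$ppcs$n_ppcs, " PPCS / ",
        rep$ppcs$n_recovered, " recovered (",
        sprintf("%.1f%%", 100 * rep$ppcs$n_ppcs /
                  (rep$ppcs$n_ppcs + rep$ppcs$n_recovered)), " PPCS)")
message(sprintf("Control anchors: mean %.3f, SD %.3f (log10 scale)",
                attr(ppcs, "hc_mean"), attr(ppcs, "hc_sd")))

for (oc in names(rep$models)) {
  for (mn in c("model1", "model2", "model3")) {
    m <- rep$models[[oc]][[mn]]
    if (is.null(m) || is.na(m$test$auc)) next
    message(sprintf("%s %s: AUC train %.2f / test %.2f",
                    oc, mn, m$train$auc, m$test$auc))
  }
}

write_tsv(ppcs, "results/06_ppcs_labels.tsv")

# ROC points for the combined quality-of-life model on the test set
obj <- attr(rep, "objects")
m3 <- obj$models$PedsQL_EC$model3
if (!is.null(m3)) {
  pred <- m3$report$test$predicted
  lab <- ppcs$label[match(names(pred), ppcs$sample_id)]
  roc <- roc_auc(pred, lab, direction = "lower_is_ppcs")
  write_tsv(roc$roc, "results/06_pedsql_combined_test_roc.tsv")
  message(sprintf("Combined quality-of-life model, test AUC: %.2f", roc$auc))
}
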