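# Outcome prediction four months post-injury with sparse support-vector
# regression: five feature sets (clinical; methylation components; their
# union; prior clinical; prior BDNF/APOE CpGs), leave-one-out penalty
# tuning, significant-weight feature selection, 70/30 sex-stratified split.

source("analysis/00_common.R")

rep <- get_report()

rows <- list()
for (oc in names(rep$models)) {
  for (mn in names(rep$models[[oc]])) {
    m <- rep$models[[oc]][[mn]]
    if (is.null(m)) next
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oc, model = mn,
      n_features = length(m$selected_features),
      lambda = m$lambda,
      train_r = round(m$train$r, 3), train_p = signif(m$train$p, 3),
      train_mse = round(m$train$mse, 1),
      test_r = round(m$test$r, 3), test_p = signif(m$test$p, 3),
      test_mse = round(m$test$mse, 1),
      train_auc = round(m$train$auc, 3), test_auc = round(m$test$auc, 3))
  }
}
acc <- do.call(rbind, rows)
message("Prediction accuracies (train ", rep$counts$n_train,
        " / test ", rep$counts$n_test, "):")
print(acc, row.names = FALSE)

for (oc in names(rep$models)) {
  m3 <- rep$models[[oc]]$model3
  if (is.null(m3)) next
  w <- sort(m3$weights, decreasing = TRUE)
  message(oc, " combined-model weights (scaled features): ",
          paste(sprintf("%s=%.2f", names(w), w), collapse = ", "))
}

write_tsv(acc, "results/05_prediction_accuracy.tsv")
w3 <- rep$models$PedsQL_EC$model3
if (!is.null(w3)) {
  write_tsv(data.frame(feature = names(w3$weights),
                       weight = unname(w3$weights)),
            "results/05_pedsql_combined_weights.tsv")
}
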