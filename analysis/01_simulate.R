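# Generate the synthetic cohort that stands in for the (request-only)
# clinical dataset: 110 pediatric mTBI patients and 87 controls with family
# structure, chip batches, a buccal/granulocyte cell mixture, five latent
# methylation components on the depression-pathway CpGs, and outcome models
# that tie symptom burden and quality of life to clinical features and
# component loadings.

source("analysis/00_common.R")

co <- generate_cohort(synthetic_config(seed = 7))

message("Cohort: ", sum(co$samples$group == "pmTBI"), " patients, ",
        sum(co$samples$group == "HC"), " controls; ",
        length(unique(co$samples$family_id)), " families (",
        sum(table(co$samples$family_id) == 2), " sibling pairs)")
message("Probes: ", nrow(co$betas), " total, ",
        sum(co$truth$probe_class == "pathway"), " pathway, ",
        sum(co$truth$probe_class == "prior"), " BDNF/APOE prior, plus QC decoys")
message("Missing beta entries: ",
        sprintf("%.2f%%", 100 * mean(is.na(co$betas))))

by_group <- function(v) tapply(v, co$samples$group, function(x)
  sprintf("%.1f +/- %.1f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)))
message("PCSI at follow-up  HC ", by_group(co$samples$PCSI_EC)["HC"],
        " | pmTBI ", by_group(co$samples$PCSI_EC)["pmTBI"])
message("PedsQL at follow-up HC ", by_group(co$samples$PedsQL_EC)["HC"],
        " | pmTBI ", by_group(co$samples$PedsQL_EC)["pmTBI"])

paths <- write_cohort(co, "scratch/cohort")
message("Cohort input files written under scratch/cohort/")

demo <- data.frame(
  group = c("HC", "pmTBI"),
  n = as.integer(table(co$samples$group)[c("HC", "pmTBI")]),
  age = tapply(co$samples$age, co$samples$group,
               function(x) sprintf("%.1f +/- %.1f", mean(x), sd(x)))[c("HC", "pmTBI")],
  pcsi_ec = by_group(co$samples$PCSI_EC)[c("HC", "pmTBI")],
  pedsql_ec = by_group(co$samples$PedsQL_EC)[c("HC", "pmTBI")])
write_tsv(demo, "results/01_cohort_demographics.tsv")
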