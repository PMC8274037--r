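# Secondary analyses of the selected features: group differences of
# clinical features (mixed model a) and methylation features (model b),
# methylation-outcome associations within patients with partial R^2
# (model c), and the depression score fitted from the component loadings
# (model d) with a permutation null.

source("analysis/00_common.R")

rep <- get_report()
sec <- rep$secondary

if (!is.null(sec$a)) {
  message("(a) Group differences, selected clinical features:")
  print(sec$a, row.names = FALSE)
  write_tsv(sec$a, "results/07_secondary_a_clinical.tsv")
}
message("(b) Group differences, methylation features (none planted):")
print(sec$b, row.names = FALSE)
write_tsv(sec$b, "results/07_secondary_b_methylation.tsv")

sig_c <- sec$c[sec$c$q < 0.05, ]
message("(c) Methylation-outcome associations within patients: ",
        nrow(sig_c), " of ", nrow(sec$c), " pass FDR")
print(sig_c, row.names = FALSE)
write_tsv(sec$c, "results/07_secondary_c_associations.tsv")

for (v in names(sec$d)) {
  d <- sec$d[[v]]
  message(sprintf(
    "(d) Depression (%s) ~ 30-d loadings: r = %.2f, p = %.3g, R2 = %.1f%%, permutation p = %.3f",
    v, d$r, d$p, d$R2_percent, d$p_perm))
}
write_tsv(data.frame(visit = names(sec$d),
                     r = sapply(sec$d, `[[`, "r"),
                     p = sapply(sec$d, `[[`, "p"),
                     R2_percent = sapply(sec$d, `[[`, "R2_percent"),
                     p_perm = sapply(sec$d, `[[`, "p_perm")),
          "results/07_secondary_d_fitted_depression.tsv")
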