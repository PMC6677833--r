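#!/usr/bin/env Rscript
# Risk scores and outcome: a centroid-correlation (ROR-style) risk score
# whose coefficients load on the high-hazard TA-like subtype, cohort-tertile
# risk groups, Kaplan-Meier curves per subtype and per risk group, log-rank
# tests, and Harrell's concordance for subtype calls vs the risk grouping.

library(heterosub)

out <- file.path("results", "survival")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix(file.path("results", "cohort", "expression.tsv"))
centroids <- read_matrix(file.path("results", "cohort", "centroids.tsv"))
clinical <- read_clinical(file.path("results", "cohort", "clinical.tsv"))
calls <- read.delim(file.path("results", "classification", "calls.tsv"))

# high-confidence plus dominant-of-mixed, the inclusive rule used when
# survival power matters more than call purity
subtype <- dominant_subtype_table(calls, c("high", "mixed"))

# treatment filter (the whole simulated cohort is "treated")
clinical <- clinical[clinical$treatment == 1, , drop = FALSE]

# ROR-style score: positive weight on the high-hazard TA-like centroid
coefs <- c("stem-like" = -0.1, "goblet-like" = -0.2, "enterocyte" = -0.1,
           "inflammatory" = 0, "TA" = 0.5)
score <- ror_score(expr, centroids, coefs)
risk_groups <- assign_risk_groups(score, "tertile")
write.table(data.frame(sample = names(score), ror = score,
                       risk_group = risk_groups[names(score)]),
            file.path(out, "risk.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

for (grouping in list(subtype = subtype, risk = risk_groups)) {
  nm <- if (identical(grouping, subtype)) "subtype" else "risk"
  km <- kaplan_meier(clinical, grouping)
  for (g in names(km))
    write.table(km[[g]],
                file.path(out, paste0("km_", nm, "_",
                                      gsub("[^A-Za-z0-9]", "_", g), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  lr <- logrank_test(clinical, grouping)
  message(sprintf("log-rank (%s groups): chi-square = %.2f, dof = %d, p = %.3g",
                  nm, lr$statistic, lr$dof, lr$p))
}

# concordance: risk tertiles as an ordered predictor of survival
ci_risk <- concordance_index(clinical, risk_groups,
                             group_order = c("low", "intermediate", "high"))
message(sprintf("concordance of risk tertiles: C = %.3f (95%% CI %.3f-%.3f, %d usable pairs)",
                ci_risk$C, ci_risk$ci[1], ci_risk$ci[2],
                ci_risk$usable_pairs))

# concordance of the subtype calls themselves, ordered by their true hazard
ci_sub <- concordance_index(clinical, subtype,
                            group_order = c("goblet-like", "enterocyte",
                                            "stem-like", "inflammatory",
                                            "TA"))
message(sprintf("concordance of subtype calls: C = %.3f (95%% CI %.3f-%.3f)",
                ci_sub$C, ci_sub$ci[1], ci_sub$ci[2]))

summary_df <- data.frame(
  comparison = c("risk_tertiles", "subtype_calls"),
  C = c(ci_risk$C, ci_sub$C),
  ci_lo = c(ci_risk$ci[1], ci_sub$ci[1]),
  ci_hi = c(ci_risk$ci[2], ci_sub$ci[2]),
  usable_pairs = c(ci_risk$usable_pairs, ci_sub$usable_pairs))
write.table(summary_df, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
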