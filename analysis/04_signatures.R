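#!/usr/bin/env Rscript
# Signature scoring: per-sample mean expression of each embedded subtype
# signature block (the synthetic analogue of an immune-activity gene set),
# and Kruskal-Wallis association of every score with the subtype calls,
# BH-FDR across scores.

library(heterosub)

out <- file.path("results", "signatures")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix(file.path("results", "cohort", "expression.tsv"))
sets <- read_gmt(file.path("results", "cohort", "signatures.gmt"))
calls <- read.delim(file.path("results", "classification", "calls.tsv"))
subtype <- dominant_subtype_table(calls, "high")

scores <- lapply(sets, function(g) signature_mean_score(expr, g))
kw <- kruskal_wallis_by_group(scores, subtype)

write.table(data.frame(sample = colnames(expr),
                       do.call(cbind, scores), check.names = FALSE),
            file.path(out, "scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(kw, file.path(out, "kruskal_wallis.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(kw)))
  message(sprintf("%s: H = %.1f (dof %d), p = %.3g, FDR = %.3g",
                  kw$score[i], kw$H[i], kw$dof[i], kw$p[i], kw$fdr[i]))
message(sum(kw$fdr < 0.05), " of ", nrow(kw),
        " signatures associate with subtype at FDR < 0.05")
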