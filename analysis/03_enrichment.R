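#!/usr/bin/env Rscript
# Cross-classification: how do the centroid-based subtype calls relate to
# the cohort's secondary labeling (the stand-in for an independent subtype
# scheme)?  Overlap counts, one-sided hypergeometric enrichment per label
# pair with BH-FDR across the matrix, and an overall chi-square test.

library(heterosub)

out <- file.path("results", "enrichment")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

calls <- read.delim(file.path("results", "classification", "calls.tsv"))
clinical <- read_clinical(file.path("results", "cohort", "clinical.tsv"))

subtype <- dominant_subtype_table(calls, "high")
secondary <- setNames(clinical$secondary_label, clinical$sample)

tab <- crosstab(subtype, secondary)
enr <- hypergeometric_enrichment(tab)

write.table(data.frame(subtype = rownames(enr$counts), enr$counts,
                       check.names = FALSE),
            file.path(out, "crosstab.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(subtype = rownames(enr$fdr), enr$fdr,
                       check.names = FALSE),
            file.path(out, "enrichment_fdr.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(subtype = rownames(enr$neg_log10_fdr),
                       enr$neg_log10_fdr, check.names = FALSE),
            file.path(out, "enrichment_neg_log10_fdr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

diag_cells <- intersect(rownames(enr$fdr), colnames(enr$fdr))
sig <- sum(enr$fdr < 0.05)
message(sum(sapply(diag_cells, function(k) enr$fdr[k, k] < 0.05)), " of ",
        length(diag_cells), " matched-label cells enriched at FDR < 0.05 (",
        sig, " significant cells in total)")

chi <- chi_square_association(tab)
message(sprintf("overall association: chi-square = %.1f, dof = %d, p = %.3g",
                chi$statistic, chi$dof, chi$p))
writeLines(sprintf("statistic\tdof\tp\n%.6g\t%d\t%.6g",
                   chi$statistic, chi$dof, chi$p),
           file.path(out, "chi_square.tsv"))
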