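#!/usr/bin/env Rscript
# Simulate the study cohort: five heterocellular-style subtypes, 100 samples
# each, log2 expression built from subtype centroids plus Gaussian noise,
# 10% mixed samples, 5% signal-free samples, a secondary labeling that
# agrees with the true subtype 80% of the time, and subtype-dependent
# exponential survival in which the TA-like subtype carries a three-fold
# hazard (the poor-prognosis group downstream stages should rediscover).
# Writes the cohort in the standard formats under results/cohort/.

library(heterosub)

out <- file.path("results", "cohort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- generator_params(
  n_genes = 2000,
  n_signature_genes_per_subtype = 80,
  subtype_names = c("stem-like", "goblet-like", "enterocyte",
                    "inflammatory", "TA"),
  samples_per_subtype = 100,
  effect_size = 2,
  noise_sd = 0.5,
  frac_mixed = 0.10,
  mix_weight = 0.6,
  frac_null = 0.05,
  baseline_mean = 8,
  zero_rate_per_gene = 0.01,
  secondary_label_agreement = 0.8,
  hazard_by_subtype = c("stem-like" = 0.08, "goblet-like" = 0.08,
                        "enterocyte" = 0.08, "inflammatory" = 0.08,
                        "TA" = 0.24),
  censor_rate = 0.04,
  treatment_mode = "all",
  seed = 20260924
)

cohort <- generate_cohort(params)

write_matrix(cohort$expr, file.path(out, "expression.tsv"), "tsv")
write_matrix(cohort$expr, file.path(out, "expression.gct"), "gct")
write_matrix(cohort$centroids, file.path(out, "centroids.tsv"), "tsv")
write_clinical(cohort$clinical, file.path(out, "clinical.tsv"))
write.table(cohort$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# embed per-subtype signature gene sets (each subtype's elevated block) so
# the signature stage can score them later
blocks <- lapply(seq_along(params$subtype_names), function(k) {
  idx <- ((k - 1) * params$n_signature_genes_per_subtype + 1):
    (k * params$n_signature_genes_per_subtype)
  structure(rownames(cohort$centroids)[idx],
            description = paste0(params$subtype_names[k], " signature block"))
})
names(blocks) <- paste0("SIG_", gsub("[^A-Za-z0-9]", "_",
                                     toupper(params$subtype_names)))
write_gmt(blocks, file.path(out, "signatures.gmt"))

msg <- table(cohort$truth$role)
message("cohort: ", ncol(cohort$expr), " samples x ", nrow(cohort$expr),
        " genes (", msg[["pure"]], " pure, ", msg[["mixed"]], " mixed, ",
        msg[["null"]], " null); outputs in ", out)
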