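# Synthetic cohort generator: construction, determinism, and the
# statistical structure downstream stages assume.

test_that("centroid construction puts each subtype's block at baseline + effect", {
  p <- generator_params(n_genes = 50, n_signature_genes_per_subtype = 10,
                        effect_size = 2, baseline_mean = 8, seed = 3)
  cen <- generate_centroids(p)
  expect_identical(dim(cen), c(50L, 5L))
  # subtype k elevated exactly on its own disjoint block
  for (k in 1:5) {
    block <- ((k - 1) * 10 + 1):(k * 10)
    expect_true(all(cen[block, k] == 10))
    expect_true(all(cen[-block, k] == 8))
  }
  # distinct centroids are not perfectly correlated (direct-formula oracle)
  for (k in 2:5)
    expect_lt(pearson_brute(cen[, 1], cen[, k]), 1)
})

test_that("oversized signature blocks are rejected", {
  expect_error(generator_params(n_genes = 40,
                                n_signature_genes_per_subtype = 10),
               "exceeds n_genes")
  expect_error(generator_params(mix_weight = 0.5), "mix_weight")
  expect_error(generator_params(frac_mixed = 0.6, frac_null = 0.6),
               "frac_mixed \\+ frac_null")
})

test_that("identical params and seed give bit-identical cohorts", {
  p <- generator_params(n_genes = 60, n_signature_genes_per_subtype = 5,
                        samples_per_subtype = 8, frac_mixed = 0.2,
                        frac_null = 0.1, zero_rate_per_gene = 0.05,
                        seed = 42)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clinical, b$clinical)
})

test_that("noise-free pure samples equal their centroid exactly", {
  p <- generator_params(n_genes = 50, n_signature_genes_per_subtype = 10,
                        samples_per_subtype = 3, noise_sd = 0, seed = 1)
  co <- generate_cohort(p)
  for (i in seq_len(ncol(co$expr)))
    expect_equal(unname(co$expr[, i]),
                 unname(co$centroids[, co$truth$true_subtype[i]]))
})

test_that("signal-free cohorts correlate with no centroid", {
  p <- generator_params(n_genes = 200, n_signature_genes_per_subtype = 10,
                        samples_per_subtype = 40, frac_null = 1, seed = 9)
  co <- generate_cohort(p)
  expect_true(all(is.na(co$truth$true_subtype)))
  cors <- correlate_to_centroids(co$expr, co$centroids)
  expect_lt(abs(mean(cors)), 0.05)     # 200 samples x 5 centroids
})

test_that("roles are assigned in the stated fractions", {
  p <- generator_params(n_genes = 60, n_signature_genes_per_subtype = 5,
                        samples_per_subtype = 20, frac_mixed = 0.25,
                        frac_null = 0.10, seed = 5)
  co <- generate_cohort(p)
  tab <- table(co$truth$role)
  expect_equal(unname(tab[["mixed"]]), round(0.25 * 100))
  expect_equal(unname(tab[["null"]]), round(0.10 * 100))
  # mixed partners always differ from the dominant subtype
  mx <- co$truth[co$truth$role == "mixed", ]
  expect_true(all(mx$mix_partner != mx$true_subtype))
  expect_true(all(mx$mix_weight == p$mix_weight))
})

test_that("per-gene zero injection hits the designated gene at its rate", {
  rates <- rep(0, 100); rates[7] <- 0.5
  p <- generator_params(n_genes = 100, n_signature_genes_per_subtype = 5,
                        samples_per_subtype = 40, zero_rate_per_gene = rates,
                        seed = 21)
  co <- generate_cohort(p)           # 200 samples
  frac <- mean(co$expr[7, ] == 0)
  expect_gte(frac, 0.38)             # binomial 99% interval at n = 200
  expect_lte(frac, 0.62)
  expect_true(all(co$expr[-7, ] != 0))
})

test_that("clinical generation honours censoring, hazards and label agreement", {
  base <- list(n_genes = 30, n_signature_genes_per_subtype = 5,
               samples_per_subtype = 25, seed = 8)
  # censor_rate = 0: every event observed
  p0 <- do.call(generator_params, c(base, censor_rate = 0))
  co0 <- generate_cohort(p0)
  expect_true(all(co0$clinical$event == 1L))
  expect_true(all(co0$clinical$time > 0))
  # full agreement: secondary label copies the true subtype
  p1 <- do.call(generator_params,
                c(base, censor_rate = 0, secondary_label_agreement = 1))
  co1 <- generate_cohort(p1)
  expect_identical(co1$clinical$secondary_label, co1$truth$true_subtype)
  # treatment modes
  p2 <- do.call(generator_params, c(base, treatment_mode = "none"))
  expect_true(all(generate_cohort(p2)$clinical$treatment == 0L))
})

test_that("near-even mixtures are flagged mixed for most mixed samples", {
  # gap geometry: for these centroids the deterministic top-two correlation
  # gap is ~1.6 * (2w - 1) / (sd_s * sd_c); at w = 0.51 it sits well below
  # the 0.06 mixed threshold once the gene universe is large enough that
  # correlation sampling noise (~1/sqrt(G)) does not floor the gap.
  p <- generator_params(n_genes = 2000, n_signature_genes_per_subtype = 80,
                        samples_per_subtype = 40, frac_mixed = 1,
                        mix_weight = 0.51, noise_sd = 0.4, seed = 303)
  co <- generate_cohort(p)
  calls <- classify_cohort(co$expr, co$centroids)
  expect_gte(mean(calls$confidence == "mixed"), 0.8)
  # dominant subtype of flagged mixed samples is still informative
  mx <- calls$confidence == "mixed"
  expect_gt(mean(calls$dominant[mx] == co$truth$true_subtype[mx]), 0.5)
})
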