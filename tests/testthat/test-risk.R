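# Recurrence-score machinery: reference normalization, the 21-gene linear
# combination, centroid-correlation risk, and risk-group assignment.

model <- load_oncotype_model()

# matrix holding all 21 model genes, constant value v per sample
flat_oncotype_matrix <- function(values) {
  genes <- c(model$scored_genes, model$housekeeping)
  m <- matrix(rep(values, each = length(genes)), nrow = length(genes),
              dimnames = list(genes, paste0("s", seq_along(values))))
  m
}

test_that("the packaged model is internally consistent", {
  expect_length(model$housekeeping, 5L)
  expect_length(model$scored_genes, 16L)
  expect_length(intersect(model$scored_genes, model$housekeeping), 0L)
  expect_identical(sum(vapply(model$groups, function(g) length(g$genes),
                              integer(1))), 16L)
})

test_that("housekeeping normalization subtracts the per-sample mean", {
  # all 21 genes equal v: everything cancels to 0
  m <- flat_oncotype_matrix(c(3, 11))
  norm <- oncotype_reference_normalize(m, model)
  expect_true(all(norm == 0))

  # housekeeping (1,2,3,4,5) -> mean 3; scored gene 7 -> 4
  m2 <- flat_oncotype_matrix(0)
  m2[model$housekeeping, 1] <- 1:5
  m2[model$scored_genes, 1] <- 7
  norm2 <- oncotype_reference_normalize(m2, model)
  expect_true(all(norm2[, 1] == 4))

  # per-sample constant shift is removed
  set.seed(47)
  m3 <- flat_oncotype_matrix(rep(0, 3))
  m3[] <- rnorm(length(m3), mean = 8)
  shifted <- sweep(m3, 2, c(1.5, -2, 0.25), "+")
  expect_equal(oncotype_reference_normalize(shifted, model),
               oncotype_reference_normalize(m3, model))

  expect_error(oncotype_reference_normalize(m3[-match("ACTB", rownames(m3)),
                                               , drop = FALSE], model),
               "ACTB")
})

test_that("recurrence score reproduces an independent spreadsheet-style evaluation", {
  set.seed(57)
  m <- flat_oncotype_matrix(rep(0, 2))
  m[] <- rnorm(length(m), mean = 8, sd = 1.5)
  norm <- oncotype_reference_normalize(m, model)
  rs <- oncotype_recurrence_score(norm, model)

  # independent evaluation of the published combination, written out long-hand
  hand_rs <- function(x) {
    her2 <- 0.9 * x["GRB7"] + 0.1 * x["ERBB2"]
    er <- (0.8 * x["ESR1"] + 1.2 * x["PGR"] + x["BCL2"] + x["SCUBE2"]) / 4
    prolif <- mean(x[c("BIRC5", "MKI67", "MYBL2", "CCNB1", "AURKA")])
    inv <- mean(x[c("MMP11", "CTSL2")])
    0.47 * her2 - 0.34 * er + 1.04 * prolif + 0.10 * inv +
      0.05 * x["CD68"] - 0.08 * x["GSTM1"] - 0.07 * x["BAG1"]
  }
  expect_equal(as.numeric(rs), unname(c(hand_rs(norm[, 1]), hand_rs(norm[, 2]))))

  # linearity and homogeneity with thresholds off
  expect_equal(as.numeric(oncotype_recurrence_score(norm * 2, model)),
               as.numeric(rs) * 2)
  expect_true(all(oncotype_recurrence_score(norm * 0, model) == 0))
})

test_that("RS is invariant to any per-sample constant across all 21 genes", {
  set.seed(67)
  m <- flat_oncotype_matrix(rep(0, 4))
  m[] <- rnorm(length(m), mean = 8)
  shifted <- sweep(m, 2, rnorm(4, sd = 3), "+")
  rs0 <- oncotype_recurrence_score(oncotype_reference_normalize(m, model),
                                   model)
  rs1 <- oncotype_recurrence_score(
    oncotype_reference_normalize(shifted, model), model)
  expect_equal(as.numeric(rs1), as.numeric(rs0))
})

test_that("group floors only apply when requested", {
  m <- flat_oncotype_matrix(0)   # all normalized values 0
  norm <- oncotype_reference_normalize(m, model)
  expect_equal(as.numeric(oncotype_recurrence_score(norm, model)), 0)
  rs_floored <- oncotype_recurrence_score(norm, model,
                                          apply_group_thresholds = TRUE)
  # floors: her2 -> 8 (x0.47), proliferation -> 6.5 (x1.04)
  expect_equal(as.numeric(rs_floored), 0.47 * 8 + 1.04 * 6.5)
})

test_that("centroid-correlation risk is the coefficient-weighted correlation sum", {
  set.seed(87)
  cen <- matrix(rnorm(60, mean = 8), 30, 2,
                dimnames = list(sprintf("g%02d", 1:30), c("A", "B")))
  m <- cbind(s1 = cen[, "A"] + rnorm(30, sd = 0.1),
             s2 = cen[, "B"] + rnorm(30, sd = 0.1))
  rownames(m) <- rownames(cen)
  p <- classifier_params(center_genes = FALSE)
  coef <- c(A = 0.5, B = -0.3)
  sc <- ror_score(m, cen, coef, p)
  brute <- sapply(1:2, function(i)
    0.5 * pearson_brute(m[, i], cen[, "A"]) -
      0.3 * pearson_brute(m[, i], cen[, "B"]))
  expect_equal(unname(sc), brute)

  # zero coefficients -> zero scores; linearity in the coefficient vector
  expect_true(all(ror_score(m, cen, c(A = 0, B = 0), p) == 0))
  sc2 <- ror_score(m, cen, 2 * coef, p)
  expect_equal(unname(sc2), 2 * unname(sc))
  sA <- ror_score(m, cen, c(A = 1, B = 0), p)
  sB <- ror_score(m, cen, c(A = 0, B = 1), p)
  expect_equal(unname(0.5 * sA - 0.3 * sB), unname(sc))

  expect_error(ror_score(m, cen, c(A = 1, X = 2), p), "do not match")
})

test_that("risk grouping partitions the cohort in both modes", {
  scores <- setNames(c(10, 40, 25, 5, 33, 18, 27, 2, 50), paste0("s", 1:9))
  g <- assign_risk_groups(scores, "tertile")
  expect_identical(as.integer(table(g)[c("low", "intermediate", "high")]),
                   rep(3L, 3))
  # tertile boundaries reproduced by a brute-force sort
  srt <- sort(scores)
  expect_true(all(g[names(srt)[1:3]] == "low"))
  expect_true(all(g[names(srt)[7:9]] == "high"))

  gf <- assign_risk_groups(scores, "fixed", thresholds = c(18, 31))
  expect_identical(unname(gf["s3"]), "intermediate")   # score 25
  expect_identical(unname(gf["s4"]), "low")            # score 5
  expect_identical(unname(gf["s9"]), "high")           # score 50
  expect_identical(unname(gf["s6"]), "intermediate")   # score 18: >= t1
  expect_error(assign_risk_groups(scores, "fixed", thresholds = c(31, 18)),
               "increasing")

  tied <- setNames(rep(1, 5), paste0("s", 1:5))
  expect_warning(gt <- assign_risk_groups(tied, "tertile"), "single tertile")
  expect_length(unique(gt), 1L)
})
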