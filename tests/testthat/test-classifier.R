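# Centroid-correlation classification and confidence gating.

make_centroids <- function() {
  set.seed(12)
  matrix(rnorm(40 * 3, mean = 8), nrow = 40, ncol = 3,
         dimnames = list(sprintf("g%02d", 1:40), c("A", "B", "C")))
}

test_that("correlations match the direct Pearson formula, centering off", {
  cen <- make_centroids()
  set.seed(13)
  m <- matrix(rnorm(40 * 4, mean = 8), nrow = 40,
              dimnames = list(rownames(cen), paste0("s", 1:4)))
  p <- classifier_params(center_genes = FALSE)
  cors <- correlate_to_centroids(m, cen, p)
  for (i in 1:4) for (k in 1:3)
    expect_equal(cors[i, k], pearson_brute(m[, i], cen[, k]))
  expect_identical(attr(cors, "n_overlap"), 40L)
})

test_that("self- and affine-transformed profiles correlate at exactly 1", {
  cen <- make_centroids()
  m <- cbind(s1 = cen[, "B"], s2 = 3 * cen[, "B"] + 5)
  cors <- correlate_to_centroids(m, cen, classifier_params(center_genes = FALSE))
  expect_equal(unname(cors[, "B"]), c(1, 1))
})

test_that("hand-built toy profiles give the hand-computed correlations", {
  cen <- cbind(down = c(5, 4, 3, 2, 1), up = c(2, 4, 6, 8, 10),
               flatish = c(1, 1, 2, 1, 1))
  rownames(cen) <- paste0("g", 1:5)
  m <- matrix(1:5, ncol = 1, dimnames = list(paste0("g", 1:5), "s1"))
  cors <- correlate_to_centroids(m, cen, classifier_params(center_genes = FALSE))
  expect_equal(unname(cors[1, "down"]), -1)
  expect_equal(unname(cors[1, "up"]), 1)
})

test_that("median centering is applied per gene across samples", {
  cen <- make_centroids()
  set.seed(14)
  m <- matrix(rnorm(40 * 5, mean = 8), nrow = 40,
              dimnames = list(rownames(cen), paste0("s", 1:5)))
  cors <- correlate_to_centroids(m, cen, classifier_params())
  centered <- m - apply(m, 1, median)
  expect_equal(cors[3, 2],
               pearson_brute(centered[, 3], cen[, 2]))
})

test_that("insufficient centroid overlap is an error reporting the fraction", {
  cen <- make_centroids()
  m <- matrix(rnorm(10), nrow = 10,
              dimnames = list(rownames(cen)[1:10], "s1"))
  expect_error(correlate_to_centroids(m, cen), "25.0%")
})

test_that("gating follows the 0.15 / 0.06 thresholds with low precedence", {
  cors <- rbind(
    s_high  = c(0.80, 0.20, 0.10, 0.00, -0.10),
    s_low   = c(0.10, 0.05, 0.00, -0.05, -0.10),
    s_mixed = c(0.30, 0.25, 0.10, 0.05, 0.00),
    s_lowmx = c(0.14, 0.13, 0.00, 0.00, 0.00))  # gap < 0.06 AND max < 0.15
  colnames(cors) <- paste0("c", 1:5)
  calls <- call_subtypes(cors)
  expect_identical(calls$confidence, c("high", "low", "mixed", "low"))
  expect_identical(calls$best[1], "c1")
  expect_equal(calls$gap[1], 0.60)
  expect_identical(calls$dominant[3], "c1")   # dominant of a mixed sample
})

test_that("argmax ties break by centroid column order", {
  cors <- rbind(s = c(0.5, 0.5, 0.1))
  colnames(cors) <- c("first", "second", "third")
  expect_identical(call_subtypes(cors)$best, "first")
})

test_that("undefined correlations gate to low confidence with a warning", {
  cen <- make_centroids()
  m <- cbind(flat = rep(1, 40), ok = cen[, "A"])
  rownames(m) <- rownames(cen)
  cors <- correlate_to_centroids(m, cen, classifier_params(center_genes = FALSE))
  expect_true(all(is.na(cors["flat", ])))
  expect_warning(calls <- call_subtypes(cors), "undefined")
  expect_identical(calls$confidence, c("low", "high"))
})

test_that("every sample lands in exactly one confidence class (property)", {
  set.seed(77)
  for (rep in 1:50) {
    cors <- matrix(runif(5, -1, 1), nrow = 1,
                   dimnames = list("s", paste0("c", 1:5)))
    call <- call_subtypes(cors)
    expect_true(call$confidence %in% c("high", "mixed", "low"))
    # brute-force re-derivation of the gate
    r <- sort(cors[1, ], decreasing = TRUE)
    expected <- if (r[1] < 0.15) "low" else if (r[1] - r[2] < 0.06) "mixed"
      else "high"
    expect_identical(call$confidence, expected)
    expect_identical(call$best, names(r)[1])
  }
})

test_that("raising the low-confidence threshold never reduces low calls", {
  set.seed(88)
  cors <- matrix(runif(200, -0.5, 0.9), ncol = 5,
                 dimnames = list(paste0("s", 1:40), paste0("c", 1:5)))
  n_low <- sapply(c(0.05, 0.15, 0.30, 0.60), function(th)
    sum(call_subtypes(cors, classifier_params(
      low_confidence_max_corr = th))$confidence == "low"))
  expect_true(all(diff(n_low) >= 0))
})

test_that("dominant_subtype_table restricts to the requested classes", {
  calls <- data.frame(
    sample = sprintf("s%02d", 1:17),
    confidence = c(rep("high", 10), rep("mixed", 5), rep("low", 2)),
    dominant = rep(c("A", "B"), length.out = 17),
    stringsAsFactors = FALSE)
  expect_length(dominant_subtype_table(calls, "high"), 10L)
  both <- dominant_subtype_table(calls, c("high", "mixed"))
  expect_length(both, 15L)
  expect_identical(unname(both["s11"]), calls$dominant[11])
  all_low <- calls[calls$confidence == "low", ]
  expect_warning(empty <- dominant_subtype_table(all_low, "high"),
                 "no sample")
  expect_length(empty, 0L)
})

test_that("classifier recovers pure synthetic cohorts (oracle equivalence)", {
  p <- generator_params(n_genes = 300, n_signature_genes_per_subtype = 15,
                        samples_per_subtype = 12, effect_size = 2,
                        noise_sd = 0.5, seed = 101)
  co <- generate_cohort(p)
  calls <- classify_cohort(co$expr, co$centroids)
  expect_gte(mean(calls$confidence == "high" &
                    calls$best == co$truth$true_subtype), 0.95)
  # full brute-force re-computation of one sample's call
  centered <- co$expr - apply(co$expr, 1, median)
  r <- sapply(colnames(co$centroids), function(k)
    pearson_brute(centered[, 7], co$centroids[, k]))
  expect_equal(unname(unlist(calls[7, colnames(co$centroids)])), unname(r))
  expect_identical(calls$best[7], names(which.max(r)))
})
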