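#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic-cohort model.  A cohort
#' consists of K subtype centroids over a shared gene universe; each sample is
#' either *pure* (its own centroid plus i.i.d. Gaussian noise), *mixed* (a
#' convex combination of two centroids, emulating tumours with more than one
#' transcriptional programme), or *null* (baseline only, no subtype signal).
#' Clinical follow-up is exponential per subtype with independent exponential
#' censoring.
#'
#' All random draws are governed by a single integer seed with one
#' stream-splitting rule: expression-level draws (role assignment, mixing
#' partners, noise, zero injection) consume the stream seeded with `seed`;
#' clinical draws (secondary labels, event and censoring times, treatment
#' split) consume the stream seeded with `seed + 1`.  Centroid construction is
#' deterministic and uses no randomness.
#'
#' @param n_genes number of genes in the universe.
#' @param n_signature_genes_per_subtype size of each subtype's disjoint
#'   signature block; `K * n_signature_genes_per_subtype` must not exceed
#'   `n_genes`.
#' @param subtype_names ordered character vector of K >= 2 subtype names.
#' @param samples_per_subtype samples drawn per subtype.
#' @param effect_size log2 shift of a subtype's signature genes in its own
#'   centroid, above `baseline_mean`.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise (log2 units).
#' @param frac_mixed fraction in [0, 1] of samples built as convex centroid
#'   combinations.
#' @param mix_weight weight in (0.5, 1] on the dominant centroid of a mixed
#'   sample; > 0.5 guarantees a unique dominant centroid.
#' @param frac_null fraction in [0, 1] of signal-free samples;
#'   `frac_mixed + frac_null` must not exceed 1.
#' @param baseline_mean global baseline expression (log2 units).
#' @param zero_rate_per_gene per-gene probability of overwriting a value with
#'   exact 0 (the missing-value convention of log-transformed RSEM data);
#'   scalar or length-`n_genes` vector.
#' @param secondary_label_agreement probability that a sample's secondary
#'   categorical label copies its primary subtype; otherwise uniform over all
#'   subtype names.
#' @param hazard_by_subtype per-subtype exponential event rate (1/time units);
#'   scalar recycled to K.  Null samples use the mean rate.
#' @param censor_rate exponential censoring rate; 0 means no censoring.
#' @param treatment_mode `"all"` (every sample flagged treated), `"none"`, or
#'   `"split"` (random 50/50).
#' @param seed single integer governing all draws.
#'
#' @return a validated list of class `"generator_params"`.
#' @export
generator_params <- function(n_genes = 500L,
                             n_signature_genes_per_subtype = 20L,
                             subtype_names = c("stem-like", "goblet-like",
                                               "enterocyte", "inflammatory",
                                               "TA"),
                             samples_per_subtype = 100L,
                             effect_size = 2,
                             noise_sd = 0.5,
                             frac_mixed = 0,
                             mix_weight = 0.6,
                             frac_null = 0,
                             baseline_mean = 8,
                             zero_rate_per_gene = 0,
                             secondary_label_agreement = 0.8,
                             hazard_by_subtype = 0.1,
                             censor_rate = 0.05,
                             treatment_mode = c("all", "none", "split"),
                             seed = 1L) {
  treatment_mode <- match.arg(treatment_mode)
  K <- length(subtype_names)
  if (K < 2L) stop2("need at least 2 subtype names")
  if (anyDuplicated(subtype_names)) stop2("subtype names must be unique")
  for (nm in c("n_genes", "n_signature_genes_per_subtype",
               "samples_per_subtype")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop2(nm, " must be a positive integer")
  }
  if (K * n_signature_genes_per_subtype > n_genes)
    stop2("K * n_signature_genes_per_subtype exceeds n_genes")
  if (effect_size <= 0) stop2("effect_size must be strictly positive")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  assert_fraction(frac_mixed, "frac_mixed")
  assert_fraction(frac_null, "frac_null")
  if (frac_mixed + frac_null > 1) stop2("frac_mixed + frac_null must be <= 1")
  if (mix_weight <= 0.5 || mix_weight > 1)
    stop2("mix_weight must lie in (0.5, 1]")
  if (!length(zero_rate_per_gene) %in% c(1L, n_genes))
    stop2("zero_rate_per_gene must be scalar or length n_genes")
  if (any(zero_rate_per_gene < 0 | zero_rate_per_gene > 1))
    stop2("zero_rate_per_gene must lie in [0, 1]")
  assert_fraction(secondary_label_agreement, "secondary_label_agreement")
  if (!length(hazard_by_subtype) %in% c(1L, K))
    stop2("hazard_by_subtype must be scalar or length K")
  if (any(hazard_by_subtype <= 0)) stop2("hazards must be strictly positive")
  if (censor_rate < 0) stop2("censor_rate must be non-negative")
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop2("seed must be a single integer")

  structure(list(
    n_genes = as.integer(n_genes),
    n_signature_genes_per_subtype = as.integer(n_signature_genes_per_subtype),
    subtype_names = as.character(subtype_names),
    samples_per_subtype = as.integer(samples_per_subtype),
    effect_size = effect_size,
    noise_sd = noise_sd,
    frac_mixed = frac_mixed,
    mix_weight = mix_weight,
    frac_null = frac_null,
    baseline_mean = baseline_mean,
    zero_rate_per_gene = rep_len(zero_rate_per_gene, n_genes),
    secondary_label_agreement = secondary_label_agreement,
    hazard_by_subtype = stats::setNames(rep_len(hazard_by_subtype, K),
                                        subtype_names),
    censor_rate = censor_rate,
    treatment_mode = treatment_mode,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' Build the subtype centroid table
#'
#' Each subtype owns a disjoint block of `n_signature_genes_per_subtype`
#' consecutive genes whose centroid value is `baseline_mean + effect_size`;
#' all other genes sit at `baseline_mean`.  Construction is deterministic.
#'
#' @param params a [generator_params()] object.
#' @return numeric matrix, genes x subtypes, rownames `g0001...`, colnames the
#'   subtype names.
#' @export
generate_centroids <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  K <- length(params$subtype_names)
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  cen <- matrix(params$baseline_mean, nrow = params$n_genes, ncol = K,
                dimnames = list(genes, params$subtype_names))
  b <- params$n_signature_genes_per_subtype
  for (k in seq_len(K)) {
    block <- ((k - 1L) * b + 1L):(k * b)
    cen[block, k] <- params$baseline_mean + params$effect_size
  }
  cen
}

#' Simulate a cohort expression matrix with ground truth
#'
#' Pure samples are their own centroid plus `N(0, noise_sd)` i.i.d. per gene;
#' mixed samples are `mix_weight * centroid_a + (1 - mix_weight) * centroid_b`
#' plus noise with `a != b`; null samples are `baseline_mean` plus noise.
#' After assembly, each gene's values are overwritten with exact 0 with its
#' per-gene zero rate.  The truth table records the role, dominant subtype,
#' and mixing pair/weight of every sample.
#'
#' @param params a [generator_params()] object.
#' @param centroids matrix from [generate_centroids()] with a matching gene
#'   universe.
#' @return list with `expr` (genes x samples matrix) and `truth` (data frame:
#'   sample, true_subtype, role, mix_partner, mix_weight); the generator
#'   params are attached as attribute `"params"` of `truth`.
#' @export
generate_expression <- function(params, centroids) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.matrix(centroids) || nrow(centroids) != params$n_genes ||
      !identical(colnames(centroids), params$subtype_names))
    stop2("centroids do not match the generator params gene/subtype universe")

  set.seed(params$seed)
  K <- length(params$subtype_names)
  n <- K * params$samples_per_subtype
  samples <- sprintf("s%04d", seq_len(n))
  subtype <- rep(params$subtype_names, each = params$samples_per_subtype)

  n_mixed <- round(params$frac_mixed * n)
  n_null <- round(params$frac_null * n)
  role <- rep("pure", n)
  special <- sample.int(n, n_mixed + n_null)
  role[special[seq_len(n_mixed)]] <- "mixed"
  if (n_null > 0) role[special[n_mixed + seq_len(n_null)]] <- "null"

  mix_partner <- rep(NA_character_, n)
  expr <- matrix(NA_real_, nrow = params$n_genes, ncol = n,
                 dimnames = list(rownames(centroids), samples))
  for (i in seq_len(n)) {
    mu <- switch(role[i],
      pure = centroids[, subtype[i]],
      null = rep(params$baseline_mean, params$n_genes),
      mixed = {
        others <- setdiff(params$subtype_names, subtype[i])
        mix_partner[i] <- sample(others, 1L)
        params$mix_weight * centroids[, subtype[i]] +
          (1 - params$mix_weight) * centroids[, mix_partner[i]]
      })
    expr[, i] <- mu + stats::rnorm(params$n_genes, sd = params$noise_sd)
  }

  if (any(params$zero_rate_per_gene > 0)) {
    for (g in which(params$zero_rate_per_gene > 0)) {
      hit <- stats::runif(n) < params$zero_rate_per_gene[g]
      expr[g, hit] <- 0
    }
  }

  truth <- data.frame(
    sample = samples,
    true_subtype = ifelse(role == "null", NA_character_, subtype),
    role = role,
    mix_partner = mix_partner,
    mix_weight = ifelse(role == "mixed", params$mix_weight, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(truth, "params") <- params
  list(expr = expr, truth = truth)
}

#' Simulate clinical follow-up for a generated cohort
#'
#' Event times are exponential with the dominant subtype's hazard (null
#' samples use the mean hazard across subtypes); censoring times are
#' exponential with `censor_rate` (`Inf` when the rate is 0, so every event is
#' observed).  The secondary categorical label copies the sample's dominant
#' subtype with probability `secondary_label_agreement` and is otherwise
#' uniform over all subtype names; null samples always draw uniformly.
#'
#' @param params a [generator_params()] object.
#' @param truth truth table from [generate_expression()].
#' @return data frame: sample, time, event (1 = event observed), treatment
#'   (0/1), secondary_label.
#' @export
generate_clinical <- function(params, truth) {
  stopifnot(inherits(params, "generator_params"))
  if (!all(c("sample", "true_subtype", "role") %in% names(truth)))
    stop2("truth table is missing required columns")
  set.seed(params$seed + 1L)
  n <- nrow(truth)
  rate <- ifelse(is.na(truth$true_subtype),
                 mean(params$hazard_by_subtype),
                 params$hazard_by_subtype[truth$true_subtype])
  t_event <- stats::rexp(n, rate = rate)
  t_cens <- if (params$censor_rate > 0)
    stats::rexp(n, rate = params$censor_rate) else rep(Inf, n)

  agree <- stats::runif(n) < params$secondary_label_agreement &
    !is.na(truth$true_subtype)
  secondary <- ifelse(agree, truth$true_subtype,
                      sample(params$subtype_names, n, replace = TRUE))

  treatment <- switch(params$treatment_mode,
    all = rep(1L, n),
    none = rep(0L, n),
    split = stats::rbinom(n, 1L, 0.5))

  data.frame(
    sample = truth$sample,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    treatment = treatment,
    secondary_label = secondary,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_centroids()],
#' [generate_expression()], and [generate_clinical()] in sequence.
#'
#' @param params a [generator_params()] object.
#' @return list with `centroids`, `expr`, `truth`, `clinical`, `params`.
#' @export
generate_cohort <- function(params) {
  cen <- generate_centroids(params)
  ge <- generate_expression(params, cen)
  clin <- generate_clinical(params, ge$truth)
  list(centroids = cen, expr = ge$expr, truth = ge$truth, clinical = clin,
       params = params)
}
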