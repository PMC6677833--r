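# Microarray-adapted recurrence risk scores:
#  * OncotypeDX recurrence score (RS): 16 scored genes in named groups,
#    housekeeping-mean reference normalization, published group weights and
#    coefficients (Paik et al. 2004).  On microarray log2 data the RT-PCR
#    group floors and the 0-100 clinical rescaling do not apply, so the
#    default output is the unscaled linear combination with cohort-level
#    grouping.
#  * ROR-style score: coefficient-weighted sum of Pearson correlations to a
#    centroid set (Parker et al. 2009), reusing the classifier's correlation
#    machinery.
# All coefficients ship in editable YAML configs under inst/extdata/.

#' Load an OncotypeDX-style recurrence-score model
#'
#' @param path YAML model file; defaults to the packaged model
#'   (`oncotype_model.yaml`), which carries the published 21-gene
#'   configuration: 16 scored genes in 7 groups, 5 housekeeping genes, group
#'   weights, group coefficients, RT-PCR group floors, and the pinned probe
#'   for CD68.
#' @return list of class `"oncotype_model"` with elements `housekeeping`,
#'   `groups` (each: `coefficient`, `genes` = named weight vector, optional
#'   `threshold`), `pinned_probes`.
#' @export
load_oncotype_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "oncotype_model.yaml",
                                package = "heterosub", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$housekeeping) || is.null(cfg$groups))
    stop2("model config needs 'housekeeping' and 'groups'")
  groups <- lapply(cfg$groups, function(g) {
    list(coefficient = as.numeric(g$coefficient),
         genes = unlist(g$genes),
         threshold = if (!is.null(g$threshold)) as.numeric(g$threshold))
  })
  scored <- unlist(lapply(groups, function(g) names(g$genes)),
                   use.names = FALSE)
  if (anyDuplicated(scored))
    stop2("a scored gene appears in more than one group")
  hk <- as.character(cfg$housekeeping)
  if (length(intersect(scored, hk)))
    stop2("scored and housekeeping gene sets overlap")
  structure(list(housekeeping = hk, groups = groups,
                 scored_genes = scored,
                 pinned_probes = unlist(cfg$pinned_probes)),
            class = "oncotype_model")
}

#' Housekeeping-mean reference normalization
#'
#' Subtracts, per sample, the mean expression of the model's housekeeping
#' genes from each scored gene — the microarray analogue of the assay's
#' reference normalization.  All housekeeping and all scored genes must be
#' present (run [collapse_probes()] with the model's `pinned_probes` first
#' on probe-level data).
#'
#' @param m genes x samples log2 matrix (gene symbols as rownames).
#' @param model an [load_oncotype_model()] object.
#' @return scored-genes x samples matrix of reference-normalized values.
#' @export
oncotype_reference_normalize <- function(m, model = load_oncotype_model()) {
  assert_expression_matrix(m)
  miss_hk <- setdiff(model$housekeeping, rownames(m))
  if (length(miss_hk))
    stop2("housekeeping gene(s) missing from the matrix: ",
          paste(miss_hk, collapse = ", "), "; normalization is undefined")
  miss_sc <- setdiff(model$scored_genes, rownames(m))
  if (length(miss_sc))
    stop2("scored gene(s) missing from the matrix: ",
          paste(miss_sc, collapse = ", "))
  hk_mean <- colMeans(m[model$housekeeping, , drop = FALSE])
  sweep(m[model$scored_genes, , drop = FALSE], 2L, hk_mean)
}

#' Unscaled OncotypeDX recurrence score
#'
#' Group scores are weighted averages of their member genes (weights from
#' the model config); the unscaled RS is the published linear combination of
#' group scores.  With `apply_group_thresholds = TRUE` the RT-PCR group
#' floors (HER2 group at 8, proliferation group at 6.5) are applied — only
#' meaningful for data rescaled to the assay's reference-normalized scale,
#' hence off by default.
#'
#' @param normalized matrix from [oncotype_reference_normalize()].
#' @param model an [load_oncotype_model()] object.
#' @param apply_group_thresholds apply the published group floors; default
#'   `FALSE`.
#' @return named numeric vector, sample -> unscaled RS; the per-group scores
#'   are attached as attribute `"group_scores"` (groups x samples).
#' @export
oncotype_recurrence_score <- function(normalized,
                                      model = load_oncotype_model(),
                                      apply_group_thresholds = FALSE) {
  miss <- setdiff(model$scored_genes, rownames(normalized))
  if (length(miss))
    stop2("normalized table is missing scored gene(s): ",
          paste(miss, collapse = ", "))
  gs <- vapply(model$groups, function(g) {
    w <- g$genes
    score <- colSums(normalized[names(w), , drop = FALSE] * w) / sum(w)
    if (apply_group_thresholds && !is.null(g$threshold))
      score <- pmax(score, g$threshold)
    score
  }, numeric(ncol(normalized)))
  if (ncol(normalized) == 1L) gs <- matrix(gs, nrow = 1L,
                                           dimnames = list(
                                             colnames(normalized),
                                             names(model$groups)))
  coefs <- vapply(model$groups, `[[`, numeric(1L), "coefficient")
  rs <- drop(gs %*% coefs)
  names(rs) <- colnames(normalized)
  structure(rs, group_scores = t(gs))
}

#' Load ROR-style centroid coefficients
#'
#' @param path YAML file mapping subtype names to coefficients; defaults to
#'   the packaged subtype-correlation coefficients (`ror_coefficients.yaml`,
#'   Parker et al. 2009 ROR-S).
#' @return named numeric vector of per-centroid coefficients.
#' @export
load_ror_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ror_coefficients.yaml",
                                package = "heterosub", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  out <- unlist(cfg$coefficients)
  if (is.null(names(out)) || !is.numeric(out))
    stop2("coefficient config must map subtype names to numbers")
  out
}

#' Centroid-correlation (ROR-style) risk score
#'
#' Per sample, the score is the coefficient-weighted sum of Pearson
#' correlations to each centroid, with correlations computed exactly as in
#' the subtype classifier ([correlate_to_centroids()]).
#'
#' @param m genes x samples log2 matrix.
#' @param centroids genes x subtypes centroid matrix.
#' @param coefficients named numeric vector, one coefficient per centroid
#'   subtype (names must match `colnames(centroids)`).
#' @param params a [classifier_params()] object (centering and overlap rules).
#' @return named numeric vector, sample -> score.
#' @export
ror_score <- function(m, centroids, coefficients,
                      params = classifier_params()) {
  if (is.null(names(coefficients)))
    stop2("coefficients must be named by centroid subtype")
  if (!setequal(names(coefficients), colnames(centroids)))
    stop2("coefficient names do not match the centroid subtypes")
  cors <- correlate_to_centroids(m, centroids, params)
  if (anyNA(cors))
    warning("some samples have undefined centroid correlations; ",
            "their scores are NA")
  drop(cors[, names(coefficients), drop = FALSE] %*% coefficients)
}

#' Assign samples to risk groups
#'
#' Tertile mode splits the cohort into thirds of the score distribution:
#' each sample's average rank r (ties share their midpoint rank) maps to
#' group `ceiling(3 r / n)`, so tied scores always land in the same group.
#' Fixed mode applies two ordered cut points: score < t1 -> low,
#' t1 <= score < t2 -> intermediate, else high.
#'
#' @param scores named numeric vector, sample -> score.
#' @param mode `"tertile"` (default) or `"fixed"`.
#' @param thresholds numeric length-2 vector `c(t1, t2)` with t1 < t2;
#'   required for fixed mode.
#' @param group_names labels for the three groups, low to high risk.
#' @return named character vector, sample -> group.
#' @export
assign_risk_groups <- function(scores, mode = c("tertile", "fixed"),
                               thresholds = NULL,
                               group_names = c("low", "intermediate",
                                               "high")) {
  mode <- match.arg(mode)
  if (is.null(names(scores))) stop2("scores must be named by sample")
  if (anyNA(scores)) stop2("scores contain NA")
  if (length(group_names) != 3L) stop2("need exactly three group names")
  if (mode == "fixed") {
    if (is.null(thresholds) || length(thresholds) != 2L)
      stop2("fixed mode needs thresholds = c(t1, t2)")
    if (thresholds[1L] >= thresholds[2L])
      stop2("fixed thresholds must be strictly increasing")
    idx <- ifelse(scores < thresholds[1L], 1L,
                  ifelse(scores < thresholds[2L], 2L, 3L))
  } else {
    n <- length(scores)
    if (n < 3L) stop2("tertile mode needs >= 3 samples")
    r <- rank(scores, ties.method = "average")
    idx <- pmin(ceiling(3 * r / n), 3L)
    if (length(unique(idx)) == 1L)
      warning("all samples fall in a single tertile group (tied scores)")
  }
  stats::setNames(group_names[idx], names(scores))
}
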