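# Config-driven orchestration of the full analysis chain:
# simulate (or load) -> zero-filter -> classify -> cross-classification
# enrichment -> signature scores -> risk scores -> survival, with every
# stage's parameters and outputs recorded in a machine-readable manifest.

#' Run the full analysis chain
#'
#' The config is a named list (or path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{generator}{arguments for [generator_params()] — the cohort is
#'     simulated.  Mutually exclusive with `inputs`.}
#'   \item{inputs}{`matrix` (path), `matrix_format` ("tsv"/"gct"),
#'     `centroids` (path, tab-delimited gene column + one column per
#'     subtype), `clinical` (path).}
#'   \item{filter}{`max_zero_fraction` (default 0.30; `NULL` skips the zero
#'     filter).}
#'   \item{classifier}{arguments for [classifier_params()].}
#'   \item{include_confidence}{confidence classes carried into downstream
#'     stages; default `"high"`.}
#'   \item{signatures}{path to a GMT file, or a named list of gene vectors.}
#'   \item{enrichment}{`secondary_column`: clinical column holding the
#'     second labeling (default `"secondary_label"`).}
#'   \item{risk}{`ror_coefficients`: named list subtype -> coefficient for
#'     the centroid-correlation risk score; omitted = risk stage skipped.}
#'   \item{survival}{`treatment_filter`: keep only samples with this
#'     treatment flag value (`NULL` = all); `risk_group_order`: low-to-high
#'     order for concordance of risk groups.}
#'   \item{seed}{integer; overrides the generator seed.}
#' }
#' Identical config + seed gives identical outputs.  Each stage writes its
#' tables under `out_dir` and the run ends with `manifest.json` recording
#' the effective config, seed, per-stage outputs and timings.  A stage
#' failure aborts with the failing stage named; earlier outputs are
#' retained.
#'
#' @param config named list or path to a YAML config.
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop2("config must be a list or a YAML path")

  # -- validate before any compute ------------------------------------------
  if (is.null(config$generator) && is.null(config$inputs))
    stop2("config needs either 'generator' or 'inputs'")
  if (!is.null(config$inputs)) {
    for (field in c("matrix", "centroids", "clinical"))
      if (is.null(config$inputs[[field]]))
        stop2("config$inputs is missing '", field, "'")
    for (field in c("matrix", "centroids", "clinical")) {
      p <- config$inputs[[field]]
      if (!file.exists(p)) stop2("config$inputs$", field,
                                 " does not exist: ", p)
    }
  }
  if (is.character(config$signatures) &&
      !file.exists(config$signatures))
    stop2("signature GMT file does not exist: ", config$signatures)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "heterosub",
                   version = as.character(utils::packageVersion("heterosub")),
                   config = config, stages = list())
  t_path <- function(f) file.path(out_dir, f)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- c(res$meta, list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      3)))
    res$value
  }

  # -- data -----------------------------------------------------------------
  data <- run_stage("data", function() {
    if (!is.null(config$generator)) {
      gp_args <- config$generator
      if (!is.null(config$seed)) gp_args$seed <- config$seed
      params <- do.call(generator_params, gp_args)
      cohort <- generate_cohort(params)
      write_matrix(cohort$expr, t_path("expression.tsv"))
      write_matrix(cohort$centroids, t_path("centroids.tsv"))
      write_clinical(cohort$clinical, t_path("clinical.tsv"))
      utils::write.table(cohort$truth, t_path("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(value = cohort,
           meta = list(mode = "simulate", seed = params$seed,
                       n_samples = ncol(cohort$expr),
                       outputs = c("expression.tsv", "centroids.tsv",
                                   "clinical.tsv", "truth.tsv")))
    } else {
      fmt <- config$inputs$matrix_format %||% "tsv"
      expr <- read_matrix(config$inputs$matrix, fmt)
      cen <- as.matrix(utils::read.delim(config$inputs$centroids,
                                         row.names = 1L,
                                         check.names = FALSE))
      clin <- read_clinical(config$inputs$clinical)
      list(value = list(expr = expr, centroids = cen, clinical = clin,
                        truth = NULL),
           meta = list(mode = "load", n_samples = ncol(expr)))
    }
  })

  # -- preprocess -----------------------------------------------------------
  expr <- run_stage("preprocess", function() {
    zf <- if (!is.null(config$filter)) config$filter$max_zero_fraction
      else 0.30
    m <- data$expr
    removed <- 0L
    if (!is.null(zf)) {
      n0 <- nrow(m)
      m <- suppressMessages(filter_zero_heavy_genes(m, zf))
      removed <- n0 - nrow(m)
    }
    list(value = m, meta = list(max_zero_fraction = zf,
                                genes_removed = removed,
                                genes_kept = nrow(m)))
  })

  # -- classify -------------------------------------------------------------
  include <- config$include_confidence %||% "high"
  calls <- run_stage("classify", function() {
    cp <- do.call(classifier_params, config$classifier %||% list())
    calls <- classify_cohort(expr, data$centroids, cp)
    utils::write.table(calls, t_path("calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    props <- subtype_proportions(dominant_subtype_table(calls, include))
    utils::write.table(props, t_path("proportions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = calls,
         meta = list(params = unclass(cp),
                     include_confidence = include,
                     n_high = sum(calls$confidence == "high"),
                     n_mixed = sum(calls$confidence == "mixed"),
                     n_low = sum(calls$confidence == "low"),
                     outputs = c("calls.tsv", "proportions.tsv")))
  })
  subtype_map <- dominant_subtype_table(calls, include)

  # -- enrichment -----------------------------------------------------------
  run_stage("enrichment", function() {
    col <- (config$enrichment %||% list())$secondary_column %||%
      "secondary_label"
    if (!col %in% names(data$clinical))
      return(list(value = NULL, meta = list(skipped = paste0(
        "clinical table has no '", col, "' column"))))
    sec <- stats::setNames(as.character(data$clinical[[col]]),
                           data$clinical$sample)
    tab <- suppressMessages(crosstab(subtype_map, sec))
    enr <- hypergeometric_enrichment(tab)
    utils::write.table(data.frame(subtype = rownames(enr$fdr),
                                  enr$fdr, check.names = FALSE),
                       t_path("enrichment_fdr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    chi <- chi_square_association(tab)
    list(value = enr,
         meta = list(secondary_column = col, chi_square = chi,
                     outputs = "enrichment_fdr.tsv"))
  })

  # -- signatures -----------------------------------------------------------
  run_stage("signatures", function() {
    sigs <- config$signatures
    if (is.null(sigs))
      return(list(value = NULL, meta = list(skipped = "no signatures")))
    if (is.character(sigs)) sigs <- read_gmt(sigs)
    scores <- lapply(sigs, function(g)
      suppressMessages(signature_mean_score(expr, g)))
    kw <- kruskal_wallis_by_group(scores, subtype_map)
    sc_tab <- data.frame(sample = colnames(expr),
                         do.call(cbind, scores), check.names = FALSE)
    utils::write.table(sc_tab, t_path("signature_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(kw, t_path("signature_kruskal_wallis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(scores = scores, kw = kw),
         meta = list(n_signatures = length(sigs),
                     outputs = c("signature_scores.tsv",
                                 "signature_kruskal_wallis.tsv")))
  })

  # -- risk -----------------------------------------------------------------
  risk_groups <- run_stage("risk", function() {
    rc <- (config$risk %||% list())$ror_coefficients
    if (is.null(rc))
      return(list(value = NULL, meta = list(skipped = "no risk config")))
    coefs <- unlist(rc)
    cp <- do.call(classifier_params, config$classifier %||% list())
    score <- ror_score(expr, data$centroids, coefs, cp)
    groups <- assign_risk_groups(score, "tertile")
    utils::write.table(data.frame(sample = names(score), ror = score,
                                  risk_group = groups[names(score)]),
                       t_path("risk.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(value = groups, meta = list(coefficients = as.list(coefs),
                                     outputs = "risk.tsv"))
  })

  # -- survival -------------------------------------------------------------
  run_stage("survival", function() {
    sv <- config$survival %||% list()
    clin <- data$clinical
    if (!is.null(sv$treatment_filter) && "treatment" %in% names(clin))
      clin <- clin[clin$treatment == sv$treatment_filter, , drop = FALSE]
    if (nrow(clin) < 2L)
      return(list(value = NULL, meta = list(skipped = "too few samples")))
    km <- kaplan_meier(clin, subtype_map)
    for (grp in names(km))
      utils::write.table(km[[grp]],
                         t_path(paste0("km_", gsub("[^A-Za-z0-9]", "_", grp),
                                       ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    lr <- if (length(unique(subtype_map[
      intersect(names(subtype_map), clin$sample)])) >= 2L)
      logrank_test(clin, subtype_map) else NULL
    ci <- if (!is.null(risk_groups)) {
      ord <- sv$risk_group_order %||% c("low", "intermediate", "high")
      concordance_index(clin, risk_groups, group_order = ord)
    } else NULL
    list(value = list(km = km, logrank = lr, concordance = ci),
         meta = list(treatment_filter = sv$treatment_filter,
                     logrank = lr, concordance = ci))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, t_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}
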