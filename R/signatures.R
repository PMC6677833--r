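# Per-sample gene-signature mean scores and rank-based association of any
# per-sample score with a sample grouping.

#' Per-sample mean expression of a gene signature
#'
#' The score of a sample is the arithmetic mean of its expression over the
#' signature genes present in the matrix (no imputation of absent genes).
#' With `z_score = TRUE` each present gene is standardised across samples
#' first (mean 0, SD 1), which removes between-gene baseline differences; the
#' default averages raw log2 values.
#'
#' @param m genes x samples log2 matrix.
#' @param genes character vector of signature gene symbols (e.g. one element
#'   of [read_gmt()]).
#' @param min_fraction_present minimum fraction of signature genes that must
#'   be present in the matrix; default 0.5.
#' @param z_score standardise each gene across samples before averaging;
#'   default `FALSE`.
#' @return named numeric vector, sample -> score; the genes used are
#'   attached as attribute `"genes_used"`.
#' @export
signature_mean_score <- function(m, genes, min_fraction_present = 0.5,
                                 z_score = FALSE) {
  assert_expression_matrix(m)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop2("empty signature")
  present <- intersect(genes, rownames(m))
  frac <- length(present) / length(genes)
  if (frac < min_fraction_present)
    stop2(sprintf(paste0("only %d of %d signature genes present (%.0f%%; ",
                         "need >= %.0f%%); missing: %s"),
                  length(present), length(genes), 100 * frac,
                  100 * min_fraction_present,
                  paste(utils::head(setdiff(genes, present), 10L),
                        collapse = ", ")))
  if (length(present) < length(genes))
    message(length(genes) - length(present),
            " signature gene(s) absent from the matrix; ",
            "score computed over the remaining ", length(present))
  x <- m[present, , drop = FALSE]
  if (z_score) {
    sds <- row_sds(x)
    if (any(sds == 0)) stop2("z_score requested but some signature genes ",
                             "have zero variance")
    x <- (x - rowMeans(x)) / sds
  }
  structure(colMeans(x), genes_used = present)
}

#' Kruskal-Wallis association of per-sample scores with a grouping
#'
#' Rank-based Kruskal-Wallis test (tie-corrected, chi-square approximation)
#' of each score against the group labels, over the samples shared by score
#' and grouping.  When several scores are tested against the same grouping,
#' Benjamini-Hochberg FDR across scores is reported alongside the raw p.
#'
#' @param scores a named numeric vector (one score) or a named list of such
#'   vectors / a samples x scores matrix (several scores).
#' @param groups sample -> label mapping with >= 2 distinct labels over the
#'   shared samples.
#' @return data frame with one row per score: `score`, `H`, `dof`, `p`,
#'   `fdr`, `n`.
#' @export
kruskal_wallis_by_group <- function(scores, groups) {
  g <- as_label_map(groups, "groups")
  if (is.numeric(scores) && !is.matrix(scores))
    scores <- list(score = scores)
  if (is.matrix(scores)) {
    scores <- stats::setNames(
      lapply(seq_len(ncol(scores)), function(j) scores[, j]),
      colnames(scores) %||% paste0("score", seq_len(ncol(scores))))
  }
  res <- lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    if (is.null(names(s))) stop2("each score vector must be named by sample")
    common <- intersect(names(s), names(g))
    grp <- factor(g[common])
    if (length(common) < 2L || nlevels(grp) < 2L)
      stop2("score '", nm, "': need >= 2 groups with samples in common")
    if (all(s[common] == s[common][1L])) {
      # all-tied degenerate case: H = 0 under the tie-correction convention
      warning("score '", nm, "' is constant across samples; H = 0")
      return(data.frame(score = nm, H = 0, dof = nlevels(grp) - 1L, p = 1,
                        n = length(common), stringsAsFactors = FALSE))
    }
    kt <- stats::kruskal.test(s[common], grp)
    data.frame(score = nm, H = unname(kt$statistic),
               dof = as.integer(kt$parameter), p = unname(kt$p.value),
               n = length(common), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- benjamini_hochberg(out$p)
  out[, c("score", "H", "dof", "p", "fdr", "n")]
}
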