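# Cross-classification association between two sample labelings: overlap
# counts, one-sided hypergeometric over-representation per label pair,
# Benjamini-Hochberg FDR across all cells, and an overall chi-square test.

#' Cross-tabulate two sample labelings
#'
#' Counts are computed over the intersection of samples present in both
#' mappings; the intersection size is reported via `message()`.
#'
#' @param labels_a,labels_b sample -> label mappings (named character vector
#'   or two-column data frame `sample`, `label`).
#' @return integer matrix of counts (A labels x B labels) with row/column
#'   margins and the grand total attached as attributes `"row_margin"`,
#'   `"col_margin"`, `"N"`.
#' @export
crosstab <- function(labels_a, labels_b) {
  a <- as_label_map(labels_a, "labels_a")
  b <- as_label_map(labels_b, "labels_b")
  common <- intersect(names(a), names(b))
  if (!length(common))
    stop2("the two labelings share no samples")
  message("cross-tabulating ", length(common), " shared sample(s)")
  tab <- table(a[common], b[common])
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  structure(counts,
            row_margin = rowSums(counts),
            col_margin = colSums(counts),
            N = sum(counts))
}

#' One-sided hypergeometric enrichment of a cross-tabulation
#'
#' For each cell (a, b) with overlap k, computes the over-representation
#' probability P(X >= k) where X is hypergeometric with population N (all
#' shared samples), success count the row margin of a, and draw count the
#' column margin of b.  P values are then Benjamini-Hochberg adjusted across
#' all cells of the matrix jointly.
#'
#' @param tab count matrix from [crosstab()].
#' @return list of matrices: `counts`, `p` (raw one-sided p), `fdr`
#'   (BH-adjusted across all cells), `neg_log10_fdr` (for heatmaps).
#' @export
hypergeometric_enrichment <- function(tab) {
  if (!is.matrix(tab) || any(tab < 0) || any(tab != round(tab)))
    stop2("tab must be a non-negative integer count matrix")
  N <- sum(tab)
  rm_ <- rowSums(tab)
  cm_ <- colSums(tab)
  p <- matrix(NA_real_, nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab)))
      # P(X >= k): upper tail of Hypergeom(m = row margin, n = N - m,
      # k draws = column margin)
      p[i, j] <- stats::phyper(tab[i, j] - 1L, rm_[i], N - rm_[i], cm_[j],
                               lower.tail = FALSE)
  fdr <- matrix(benjamini_hochberg(as.vector(p)), nrow = nrow(p),
                dimnames = dimnames(p))
  list(counts = tab, p = p, fdr = fdr,
       neg_log10_fdr = -log10(fdr))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; input
#' order is preserved.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop2("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop2("p values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Overall chi-square association between two labelings
#'
#' Pearson chi-square test of independence without continuity correction;
#' degrees of freedom (rows - 1)(cols - 1).  A warning is issued when any
#' expected count falls below 5.
#'
#' @param tab count matrix from [crosstab()].
#' @return list with `statistic`, `dof`, `p`.
#' @export
chi_square_association <- function(tab) {
  if (!is.matrix(tab)) stop2("tab must be a count matrix")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop2("chi-square needs at least a 2 x 2 table")
  if (sum(tab) == 0) stop2("empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("some expected counts are < 5; chi-square approximation is weak")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic),
       dof = unname(res$parameter),
       p = unname(res$p.value))
}
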