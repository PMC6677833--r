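# Nearest-centroid subtype classification by Pearson correlation with
# three-way confidence gating:
#   low   : maximum centroid correlation < low_confidence_max_corr (0.15)
#   mixed : not low, but first - second correlation gap < mixed_gap (0.06)
#   high  : everything else
# Low takes precedence over mixed.  The "dominant" subtype of a sample is the
# argmax-correlation subtype regardless of confidence.

#' Classifier gating parameters
#'
#' @param low_confidence_max_corr samples whose maximum centroid correlation
#'   falls below this are called low-confidence; default 0.15.
#' @param mixed_gap samples whose first-minus-second correlation gap falls
#'   below this (and that are not low-confidence) are called mixed; default
#'   0.06.
#' @param center_genes subtract each gene's median across cohort samples
#'   before correlating; default `TRUE` (centroid sets of the PAM family are
#'   built on centered data).
#' @param min_centroid_overlap minimum fraction of centroid genes that must
#'   be present in the matrix; default 0.80.
#' @return list of class `"classifier_params"`.
#' @export
classifier_params <- function(low_confidence_max_corr = 0.15,
                              mixed_gap = 0.06,
                              center_genes = TRUE,
                              min_centroid_overlap = 0.80) {
  if (low_confidence_max_corr < -1 || low_confidence_max_corr > 1)
    stop2("low_confidence_max_corr must lie in [-1, 1]")
  if (mixed_gap < 0) stop2("mixed_gap must be >= 0")
  assert_fraction(min_centroid_overlap, "min_centroid_overlap")
  if (min_centroid_overlap == 0) stop2("min_centroid_overlap must be > 0")
  structure(list(low_confidence_max_corr = low_confidence_max_corr,
                 mixed_gap = mixed_gap,
                 center_genes = isTRUE(center_genes),
                 min_centroid_overlap = min_centroid_overlap),
            class = "classifier_params")
}

#' Correlate every sample with every subtype centroid
#'
#' Pearson correlation over the genes shared between the matrix and the
#' centroid table, after optional per-gene median centering of the matrix
#' across its samples.  A sample with zero variance over the overlap genes
#' yields `NA` correlations (it is gated to low confidence downstream).
#'
#' @param m genes x samples log2 matrix.
#' @param centroids genes x subtypes centroid matrix (unique gene rownames,
#'   subtype colnames, no missing values).
#' @param params a [classifier_params()] object.
#' @return samples x subtypes correlation matrix; the overlap gene count is
#'   attached as attribute `"n_overlap"`.
#' @export
correlate_to_centroids <- function(m, centroids,
                                   params = classifier_params()) {
  assert_expression_matrix(m)
  if (!is.matrix(centroids) || is.null(rownames(centroids)) ||
      is.null(colnames(centroids)))
    stop2("centroids must be a gene x subtype matrix with dimnames")
  if (anyNA(centroids)) stop2("centroid table contains missing values")
  if (ncol(centroids) < 2L) stop2("need >= 2 centroid subtypes")

  overlap <- intersect(rownames(centroids), rownames(m))
  frac <- length(overlap) / nrow(centroids)
  if (frac < params$min_centroid_overlap)
    stop2(sprintf(paste0("only %.1f%% of centroid genes found in the matrix ",
                         "(need >= %.0f%%)"),
                  100 * frac, 100 * params$min_centroid_overlap))
  if (length(overlap) < 3L) stop2("need >= 3 overlapping genes")

  x <- m[overlap, , drop = FALSE]
  if (params$center_genes)
    x <- x - apply(x, 1L, stats::median)
  cors <- suppressWarnings(stats::cor(x, centroids[overlap, , drop = FALSE],
                                      method = "pearson"))
  attr(cors, "n_overlap") <- length(overlap)
  cors
}

#' Gate correlations into subtype calls
#'
#' @param correlations samples x subtypes matrix from
#'   [correlate_to_centroids()].
#' @param params a [classifier_params()] object.
#' @return data frame with one row per sample: the per-subtype correlations,
#'   `best`, `second`, `gap`, `confidence` (`high`/`mixed`/`low`) and
#'   `dominant` (= `best`; the subtype reported for mixed samples).  Argmax
#'   ties are broken by centroid column order.  Samples with undefined
#'   correlations are flagged low with a warning.
#' @export
call_subtypes <- function(correlations, params = classifier_params()) {
  if (!is.matrix(correlations) || ncol(correlations) < 2L)
    stop2("correlations must be a samples x subtypes matrix")
  subtypes <- colnames(correlations)
  n <- nrow(correlations)
  best <- second <- rep(NA_character_, n)
  gap <- maxcor <- rep(NA_real_, n)
  confidence <- rep(NA_character_, n)
  n_undef <- 0L

  for (i in seq_len(n)) {
    r <- correlations[i, ]
    if (anyNA(r)) {
      n_undef <- n_undef + 1L
      confidence[i] <- "low"
      if (!all(is.na(r))) {
        b <- which.max(replace(r, is.na(r), -Inf))
        best[i] <- subtypes[b]
        maxcor[i] <- r[b]
      }
      next
    }
    b <- which.max(r)                       # ties -> first (column order)
    best[i] <- subtypes[b]
    maxcor[i] <- r[b]
    s <- which.max(replace(r, b, -Inf))
    second[i] <- subtypes[s]
    gap[i] <- r[b] - r[s]
    confidence[i] <-
      if (r[b] < params$low_confidence_max_corr) "low"
      else if (gap[i] < params$mixed_gap) "mixed"
      else "high"
  }
  if (n_undef > 0L)
    warning(n_undef, " sample(s) had undefined correlations; ",
            "flagged low confidence")

  out <- data.frame(sample = rownames(correlations) %||%
                      as.character(seq_len(n)),
                    correlations,
                    best = best, second = second,
                    max_corr = maxcor, gap = gap,
                    confidence = confidence,
                    dominant = best,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a cohort against a centroid set
#'
#' Convenience wrapper: [correlate_to_centroids()] then [call_subtypes()].
#'
#' @inheritParams correlate_to_centroids
#' @return the call table of [call_subtypes()].
#' @export
classify_cohort <- function(m, centroids, params = classifier_params()) {
  call_subtypes(correlate_to_centroids(m, centroids, params), params)
}

#' Restrict calls to confident samples
#'
#' @param calls call table from [call_subtypes()].
#' @param include confidence classes to keep: `c("high")` (default) or
#'   `c("high", "mixed")`.  Mixed samples contribute their dominant subtype;
#'   low-confidence samples are never included.
#' @return named character vector, sample -> subtype.
#' @export
dominant_subtype_table <- function(calls, include = "high") {
  if (!all(include %in% c("high", "mixed")))
    stop2("include must be a subset of c('high', 'mixed')")
  sel <- calls$confidence %in% include
  if (!any(sel)) {
    warning("no sample in the requested confidence classes")
    return(stats::setNames(character(0), character(0)))
  }
  stats::setNames(calls$dominant[sel], calls$sample[sel])
}

#' Subtype composition of a cohort
#'
#' Tabulates per-subtype counts and rounded percentages — the numbers a
#' pie-chart legend reports.
#'
#' @param x either a sample -> subtype mapping (named character vector or
#'   two-column data frame) or an already-tabulated named count vector.
#' @return data frame with columns `subtype`, `n`, `percent` (rounded to
#'   whole percent), sorted by decreasing count; the total sample count is
#'   attached as attribute `"total_n"`.
#' @export
subtype_proportions <- function(x) {
  counts <- if (is.numeric(x)) {
    if (is.null(names(x))) stop2("count vector must be named by subtype")
    x
  } else {
    tab <- table(as_label_map(x, "subtype mapping"))
    stats::setNames(as.numeric(tab), names(tab))
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop2("no samples to tabulate")
  out <- data.frame(subtype = names(counts),
                    n = as.integer(counts),
                    percent = round(100 * counts / total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$subtype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_n") <- as.integer(total)
  out
}
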