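# Gene filtering, variable-gene selection, and probe-to-gene collapse.
# Missingness convention throughout: an exact numeric 0 is a missing value
# (log-transformed RSEM emits 0 for absent measurements); genes are filtered,
# never imputed.

#' Remove genes with too many zero (missing) values
#'
#' Drops every gene whose fraction of exactly-zero values is *strictly*
#' greater than `max_zero_fraction`; a gene with zeros in exactly the cutoff
#' fraction of samples is retained.  The sample set is unchanged.
#'
#' @param m genes x samples numeric matrix.
#' @param max_zero_fraction maximum tolerated zero fraction, default 0.30.
#' @return the filtered matrix; removed genes are reported via `message()`.
#' @export
filter_zero_heavy_genes <- function(m, max_zero_fraction = 0.30) {
  assert_expression_matrix(m)
  assert_fraction(max_zero_fraction, "max_zero_fraction")
  zero_frac <- rowMeans(m == 0)
  drop <- zero_frac > max_zero_fraction
  if (all(drop))
    stop2("all ", nrow(m), " genes exceed the zero-fraction cutoff ",
          max_zero_fraction, "; empty matrix")
  if (any(drop))
    message("removed ", sum(drop), " gene(s) with >",
            round(100 * max_zero_fraction), "% zero values: ",
            paste(utils::head(rownames(m)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
  m[!drop, , drop = FALSE]
}

#' Select highly variable genes by standard-deviation cutoff
#'
#' Retains genes whose sample standard deviation (n - 1 denominator) is
#' *strictly* greater than `sd_cutoff`, preserving input gene order.
#'
#' @param m genes x samples numeric matrix with >= 2 samples.
#' @param sd_cutoff non-negative SD threshold (e.g. 2 for a stringent list,
#'   1.5 for a broader one).
#' @return the filtered matrix; an empty result triggers a warning, not an
#'   error.
#' @export
select_variable_genes <- function(m, sd_cutoff) {
  assert_expression_matrix(m)
  if (ncol(m) < 2L) stop2("need >= 2 samples to compute a standard deviation")
  if (!is.numeric(sd_cutoff) || length(sd_cutoff) != 1L || sd_cutoff < 0)
    stop2("sd_cutoff must be a single non-negative number")
  keep <- row_sds(m) > sd_cutoff
  if (!any(keep)) warning("no gene passes SD > ", sd_cutoff)
  m[keep, , drop = FALSE]
}

#' Collapse probes to genes
#'
#' For each gene, keeps the mapped probe with the largest sample standard
#' deviation and re-labels its row with the gene symbol.  Ties are broken by
#' the lexicographically smaller probe id.  Probes pinned in `overrides`
#' represent their gene regardless of SD (used when a gene must be read from
#' one specific probe).  Probes absent from the map are dropped with a
#' reported count.
#'
#' @param m probes x samples numeric matrix.
#' @param map data frame with columns `probe`, `gene` (many probes to one
#'   gene), or a named character vector (names = probes, values = genes).
#' @param overrides optional named character vector: names = gene symbols,
#'   values = the probe id pinned for that gene.
#' @return genes x samples matrix with one row per mapped gene present in
#'   `m`.
#' @export
collapse_probes <- function(m, map, overrides = NULL) {
  assert_expression_matrix(m)
  if (is.data.frame(map)) {
    if (!all(c("probe", "gene") %in% names(map)))
      stop2("probe map needs columns 'probe' and 'gene'")
    map <- stats::setNames(as.character(map$gene), as.character(map$probe))
  }
  if (anyDuplicated(names(map)))
    stop2("probe map assigns some probe to more than one gene")
  mapped <- intersect(rownames(m), names(map))
  if (!length(mapped))
    stop2("no probe of the matrix appears in the probe-gene map")
  n_unmapped <- nrow(m) - length(mapped)
  if (n_unmapped > 0L)
    message("dropped ", n_unmapped, " unmapped probe(s)")

  sds <- row_sds(m[mapped, , drop = FALSE])
  genes <- unname(map[mapped])
  pick <- character(0)
  for (g in unique(genes)) {
    probes <- mapped[genes == g]
    if (!is.null(overrides) && g %in% names(overrides) &&
        overrides[[g]] %in% probes) {
      pick[g] <- overrides[[g]]
      next
    }
    p_sd <- sds[probes]
    best <- probes[p_sd == max(p_sd)]
    pick[g] <- sort(best)[1L]          # lexicographic tie-break
  }
  out <- m[unname(pick), , drop = FALSE]
  rownames(out) <- names(pick)
  out
}
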