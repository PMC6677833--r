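# Internal validators shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_expression_matrix <- function(m, arg = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.numeric(m))
    stop2(arg, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop2(arg, " must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop2(arg, " has duplicate feature identifiers")
  if (anyDuplicated(colnames(m)))
    stop2(arg, " has duplicate sample identifiers")
  invisible(m)
}

#' @noRd
assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop2(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}

# Sample SD with the n-1 denominator, zero-variance rows allowed.
row_sds <- function(m) {
  apply(m, 1L, stats::sd)
}

# Named label vector from a two-column mapping or a named vector.
as_label_map <- function(x, arg = "labels") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop2(arg, " data frame needs columns: sample, label")
    out <- as.character(x[[2L]])
    names(out) <- as.character(x[[1L]])
  } else {
    if (is.null(names(x))) stop2(arg, " must be a named vector (sample -> label)")
    out <- as.character(x)
    names(out) <- names(x)
  }
  if (anyDuplicated(names(out))) stop2(arg, " has duplicated sample ids")
  out
}
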