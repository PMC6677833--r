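# Readers and writers for the plain-text formats the analysis consumes:
# tab-delimited expression matrices, GCT 1.2, GMT gene-set collections, and
# tab-delimited clinical tables.

#' Read an expression matrix
#'
#' Reads a genes x samples log2 expression matrix from a tab-delimited file
#' (feature id in the first column, sample ids in the header) or a GCT 1.2
#' file (`#1.2` version line, then a `rows<TAB>columns` declaration, then a
#' header with `Name`, `Description` and sample ids).  Duplicate feature rows
#' are collapsed by keeping the row with the highest sample standard
#' deviation (ties broken by first occurrence); the collapse is reported via
#' `message()`.  `NA` tokens are rejected: missingness in this pipeline is
#' encoded as exact 0, and anything unparseable is an error.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"gct"`.
#' @return numeric matrix with unique feature rownames and sample colnames.
#' @export
read_matrix <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[1L]) != "#1.2")
      stop2("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop2("malformed GCT dimension line in ", path)
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            colClasses = "character")
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
      stop2("GCT declares ", dims[1L], " x ", dims[2L], " but file contains ",
            nrow(df), " x ", ncol(df) - 2L)
    ids <- df[[1L]]
    vals <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop2("matrix file needs a feature column plus ",
                             "at least one sample column: ", path)
    ids <- df[[1L]]
    vals <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(colnames(vals)))
    stop2("duplicate sample identifiers in ", path)

  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(NULL, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop2("non-numeric value '", vals[[j]][bad[1L]], "' at row '",
            ids[bad[1L]], "', column '", colnames(vals)[j], "' in ", path)
    m[, j] <- x
  }
  rownames(m) <- ids
  collapse_duplicate_features(m)
}

# Keep, for each duplicated feature id, the copy with the largest sample SD.
collapse_duplicate_features <- function(m) {
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (!length(dup)) return(m)
  keep <- rep(TRUE, nrow(m))
  for (id in dup) {
    rows <- which(rownames(m) == id)
    sds <- apply(m[rows, , drop = FALSE], 1L, stats::sd)
    keep[rows[-which.max(sds)]] <- FALSE
  }
  message("collapsed ", sum(!keep), " duplicate feature row(s) for ",
          length(dup), " identifier(s), keeping the highest-SD copy")
  m[keep, , drop = FALSE]
}

#' Write an expression matrix
#'
#' @param m genes x samples numeric matrix.
#' @param path output file.
#' @param format `"tsv"` (feature ids in a leading `feature` column) or
#'   `"gct"` (GCT 1.2; the Description column repeats the feature id).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  assert_expression_matrix(m)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = rownames(m),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-delimited.  Duplicate members within a line are dropped with a
#' warning; a line with fewer than three fields is a parse error naming the
#' line number.
#'
#' @param path GMT file.
#' @return named list of character vectors; each element carries its
#'   description as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop2("GMT line ", i, " has ", length(f), " field(s); need at least ",
            "name, description, one member")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT set '", f[1L], "' has duplicated members; de-duplicated")
      members <- unique(members)
    }
    sets[[f[1L]]] <- structure(members, description = f[2L])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors (optionally carrying a
#'   `"description"` attribute).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-delimited with a header.  Required columns: `sample`, `time`, `event`
#' (1 = event observed, 0 = censored).  Any further columns (treatment flag,
#' auxiliary labels) are preserved verbatim.  Negative times and event values
#' outside \{0, 1\} are errors naming the offending row.
#'
#' @param path file to read.
#' @return data frame with typed `time` (numeric) and `event` (integer).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample", "time", "event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop2("clinical table is missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop2("duplicate sample ids in ", path)
  df$time <- suppressWarnings(as.numeric(df$time))
  bad <- which(is.na(df$time) | df$time < 0)
  if (length(bad))
    stop2("invalid (negative or non-numeric) time at row ", bad[1L],
          " (sample '", df$sample[bad[1L]], "')")
  ev <- suppressWarnings(as.numeric(df$event))
  bad <- which(is.na(ev) | !ev %in% c(0, 1))
  if (length(bad))
    stop2("event value '", df$event[bad[1L]], "' at row ", bad[1L],
          " (sample '", df$sample[bad[1L]], "') is not 0/1")
  df$event <- as.integer(ev)
  df
}

#' Write a clinical table
#'
#' @param clin data frame with at least `sample`, `time`, `event`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
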