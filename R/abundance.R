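#' Construct an abundance table
#'
#' A taxa-by-samples matrix of non-negative abundances, either raw read
#' counts or per-sample relative abundances. This is the central container
#' consumed by rarefaction, diversity and network inference.
#'
#' @param values numeric matrix, taxa as rows, samples as columns.
#' @param taxon_ids character vector of unique taxon identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param unit_kind `"counts"` (non-negative reads) or `"relative"`
#'   (every sample column sums to 1 within 1e-9).
#'
#' @return an `abundance_table`: a numeric matrix with row/column names and
#'   a `unit_kind` attribute.
#' @export
abundance_table <- function(values,
                            taxon_ids = rownames(values),
                            sample_ids = colnames(values),
                            unit_kind = c("counts", "relative")) {
  unit_kind <- match.arg(unit_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("abundance values must be numeric", call. = FALSE)
  }
  if (is.null(taxon_ids) || is.null(sample_ids)) {
    stop("taxon_ids and sample_ids are required (or set dimnames)", call. = FALSE)
  }
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  dup_t <- unique(taxon_ids[duplicated(taxon_ids)])
  if (length(dup_t)) {
    stop("duplicate taxon_ids: ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample_ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("non-numeric or missing abundance value", call. = FALSE)
  if (any(values < 0)) stop("negative abundance", call. = FALSE)
  dimnames(values) <- list(taxon_ids, sample_ids)
  if (unit_kind == "relative" && ncol(values) > 0) {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad)) {
      stop("relative abundance columns must sum to 1: ",
           paste(sample_ids[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(values, unit_kind = unit_kind, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "unit_kind")))
  if (nrow(x) && ncol(x)) {
    print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE]))
    if (nrow(x) > 6L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

# Subsetting keeps the class and unit (a subset of counts is still counts).
#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, unit_kind = attr(x, "unit_kind"),
                     class = c("abundance_table", "matrix", "array"))
  }
  out
}

unit_kind <- function(x) attr(x, "unit_kind")

#' Read an abundance table from a delimited text file
#'
#' The file must have a header row; the first column holds taxon ids
#' (`orientation = "taxa_rows"`, default) or sample ids
#' (`orientation = "samples_rows"`, in which case the table is transposed
#' after reading).
#'
#' @param path file path to a TSV/CSV table.
#' @param orientation `"taxa_rows"` or `"samples_rows"`.
#' @param unit_kind passed to [abundance_table()].
#' @param sep field separator, tab by default.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                                 unit_kind = "counts", sep = "\t") {
  orientation <- match.arg(orientation)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in '%s' at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1L]), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("expected at least one id column and one data column", call. = FALSE)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate ids in first column: ", paste(dup, collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric abundance '%s' at row '%s', column '%s'",
                 raw[bad[1L], bad[2L]], ids[bad[1L]], colnames(raw)[bad[2L]]),
         call. = FALSE)
  }
  if (orientation == "samples_rows") vals <- t(vals)
  abundance_table(vals, unit_kind = unit_kind)
}

#' Write an abundance table to a TSV file
#'
#' Taxa in rows, header row of sample ids, first column `taxon_id`.
#' Integer counts are written exactly; reals at full precision.
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  vals <- unclass(x)
  fmt <- if (all(vals == round(vals))) {
    format(vals, scientific = FALSE, trim = TRUE)
  } else {
    matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  }
  out <- data.frame(taxon_id = rownames(vals), fmt, check.names = FALSE)
  colnames(out) <- c("taxon_id", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample-to-group assignment)
#'
#' @param path two-column delimited file with header `sample_id`, `group`
#'   (extra columns are ignored; `group_column` selects the grouping column).
#' @param groups optional character vector: the declared finite label set.
#'   When given, any other label is an error.
#' @param group_column name of the column holding the group label.
#' @param sep field separator.
#' @return data.frame with columns `sample_id` and `group`.
#' @export
read_metadata <- function(path, groups = NULL, group_column = "group", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "", quote = "\"")
  if (!"sample_id" %in% colnames(df)) stop("metadata needs a 'sample_id' column", call. = FALSE)
  if (!group_column %in% colnames(df)) {
    stop("metadata has no '", group_column, "' column", call. = FALSE)
  }
  out <- data.frame(sample_id = df[["sample_id"]], group = df[[group_column]],
                    stringsAsFactors = FALSE)
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup)) stop("duplicated sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (!is.null(groups)) {
    bad <- setdiff(unique(out$group), groups)
    if (length(bad)) {
      stop("group labels outside the declared set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out
}

#' Write sample metadata to a TSV file
#' @param metadata data.frame with `sample_id` and `group`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("sample_id", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that every sample of a table is covered by the metadata
#'
#' @param x an [abundance_table()].
#' @param metadata data.frame from [read_metadata()].
#' @return invisibly `TRUE`; errors listing missing sample ids otherwise.
#' @export
validate_samples <- function(x, metadata) {
  missing <- setdiff(colnames(x), metadata$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
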