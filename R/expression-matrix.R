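#' Expression tables
#'
#' An expression table holds platform expression values for M miRNAs across
#' N samples. Only within-sample orderings of the values are ever used
#' downstream, so the values may be on any positive scale (raw intensity,
#' log intensity, normalised units); no transform is applied at read time.
#'
#' The tidy representation is a tibble whose first column, `mirna`, holds the
#' miRNA identifiers and whose remaining columns are one numeric column per
#' sample. Most functions in the package accept either this tibble form or a
#' plain numeric matrix with miRNA rownames and sample colnames.
#'
#' @param x A data frame (first column = miRNA ids, remaining columns numeric
#'   samples) or a numeric matrix with rownames and colnames.
#' @return `as_expr_tbl()` returns a tibble of class `mir_expr`;
#'   `expr_values()` returns the underlying named numeric matrix.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("miR-a", "miR-b", "miR-c"),
#'                                        c("s1", "s2")))
#' tbl <- as_expr_tbl(m)
#' expr_values(tbl)
#' @name mir_expr
NULL

new_expr_tbl <- function(df) {
  structure(as_tibble(df), class = c("mir_expr", class(as_tibble(df))))
}

#' @rdname mir_expr
#' @export
as_expr_tbl <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs miRNA rownames and sample colnames")
    }
    df <- tibble(mirna = rownames(x))
    df <- dplyr::bind_cols(df, as_tibble(x, .name_repair = "minimal"))
  } else if (is.data.frame(x)) {
    df <- as_tibble(x)
    names(df)[1] <- "mirna"
    df$mirna <- as.character(df$mirna)
  } else {
    abort("cannot interpret input as an expression table")
  }
  validate_expr_tbl(df)
  new_expr_tbl(df)
}

#' @rdname mir_expr
#' @export
expr_values <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

validate_expr_tbl <- function(df) {
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate miRNA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "reopairs_format_error")
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
          class = "reopairs_format_error")
  }
  for (s in samples) {
    v <- df[[s]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric values in sample column '", s, "'"),
            class = "reopairs_parse_error")
    }
    bad <- !is.finite(v)
    if (any(bad)) {
      abort(paste0("non-finite or missing value for miRNA '",
                   ids[which(bad)[1]], "', sample '", s,
                   "' (missing values are rejected: the ordering of an ",
                   "unobserved value is undefined)"),
            class = "reopairs_parse_error")
    }
  }
  invisible(df)
}

strip_quotes <- function(x) {
  sub('^"(.*)"$', "\\1", x)
}

parse_expr_lines <- function(lines, what = "expression table") {
  lines <- lines[seq_len(max(c(0, which(nzchar(trimws(lines))))))]
  if (length(lines) < 2) {
    abort(paste0(what, ": need a header line and at least one miRNA row"),
          class = "reopairs_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- strip_quotes(fields[[1]])
  samples <- header[-1]  # first header cell (row-label heading) is ignored
  n <- length(samples)
  rows <- fields[-1]
  ids <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    f <- strip_quotes(rows[[i]])
    if (length(f) != n + 1L) {
      abort(paste0(what, ": row ", i + 1L, " has ", length(f),
                   " fields, expected ", n + 1L),
            class = "reopairs_format_error")
    }
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- !is.finite(v)
    if (any(bad)) {
      j <- which(bad)[1]
      abort(paste0(what, ": cannot parse value '", f[-1][j],
                   "' for miRNA '", f[1], "', sample '", samples[j], "'"),
            class = "reopairs_parse_error")
    }
    vals[i, ] <- v
  }
  rownames(vals) <- ids
  colnames(vals) <- samples
  as_expr_tbl(vals)
}

#' Read an expression table
#'
#' Reads a miRNA-by-sample expression table from tab-separated text. Two
#' dialects are supported:
#'
#' * `"plain_tsv"`: a header row of sample ids (the first header cell is
#'   ignored) followed by one row per miRNA.
#' * `"geo_series_matrix"`: a GEO series-matrix export; only the data block
#'   between the literal lines `!series_matrix_table_begin` and
#'   `!series_matrix_table_end` is consumed, and quoted fields are unquoted.
#'
#' Row and column order are preserved as written. Duplicate ids, non-numeric
#' cells, and missing values are errors.
#'
#' @param path Path to the file.
#' @param dialect `"plain_tsv"` (default) or `"geo_series_matrix"`.
#' @return A [mir_expr] tibble.
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("plain_tsv",
                                               "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readr::read_lines(path)
  if (dialect == "geo_series_matrix") {
    begin <- which(trimws(strip_quotes(lines)) == "!series_matrix_table_begin")
    end <- which(trimws(strip_quotes(lines)) == "!series_matrix_table_end")
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      abort(paste0("series-matrix table delimiters not found in ", path),
            class = "reopairs_format_error")
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  parse_expr_lines(lines, what = basename(path))
}

#' Write an expression table as plain TSV
#'
#' @param x A [mir_expr] tibble or named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  m <- expr_values(x)
  df <- data.frame(mirna = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
print.mir_expr <- function(x, ...) {
  cat("# Expression table:", nrow(x), "miRNAs x", ncol(x) - 1L, "samples\n")
  NextMethod()
}
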