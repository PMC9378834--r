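#' Read a sample label file
#'
#' Labels are a two-column TSV (`sample_id`, `label`) assigning each sample
#' to the case (cancer) or control (non-cancer) class. Tokens are matched
#' case-insensitively against a declared vocabulary and normalised to
#' `"case"` / `"control"`.
#'
#' @param path Path to the TSV file. A header row is detected when the first
#'   line reads `sample_id<TAB>label`.
#' @param case_tokens,control_tokens Accepted spellings for each class.
#' @return A tibble with columns `sample_id`, `label` (values `"case"` or
#'   `"control"`).
#' @export
read_labels <- function(path,
                        case_tokens = c("case", "cancer", "tumor", "ovc"),
                        control_tokens = c("control", "non-cancer",
                                           "noncancer", "normal", "healthy")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort(paste0("label file row ", bad[1], " does not have two columns"),
          class = "reopairs_format_error")
  }
  sample_id <- vapply(fields, `[[`, "", 1L)
  token <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(c(sample_id[1], token[1])),
                c("sample_id", "label"))) {
    sample_id <- sample_id[-1]
    token <- token[-1]
  }
  if (anyDuplicated(sample_id)) {
    abort(paste0("duplicated sample id(s) in label file: ",
                 paste(unique(sample_id[duplicated(sample_id)]),
                       collapse = ", ")),
          class = "reopairs_format_error")
  }
  lab <- rep(NA_character_, length(token))
  lab[tolower(token) %in% tolower(case_tokens)] <- "case"
  lab[tolower(token) %in% tolower(control_tokens)] <- "control"
  if (anyNA(lab)) {
    abort(paste0("unknown label token '", token[which(is.na(lab))[1]],
                 "'; accepted tokens: ",
                 paste(c(case_tokens, control_tokens), collapse = ", ")),
          class = "reopairs_format_error")
  }
  tibble(sample_id = sample_id, label = lab)
}

#' Write a sample label file
#'
#' @param labels A tibble with columns `sample_id`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  readr::write_tsv(labels[, c("sample_id", "label")], path)
  invisible(path)
}

#' Split an expression table into case and control cohorts
#'
#' @param x Expression table ([mir_expr] tibble or matrix).
#' @param labels Label tibble as returned by [read_labels()].
#' @return A list with elements `controls` and `cases`, each a [mir_expr]
#'   tibble. Samples absent from `labels` are dropped with a warning.
#' @export
split_cohorts <- function(x, labels) {
  m <- expr_values(x)
  known <- colnames(m) %in% labels$sample_id
  if (!all(known)) {
    warn(paste0(sum(!known), " sample(s) without a label were dropped"))
    m <- m[, known, drop = FALSE]
  }
  lab <- labels$label[match(colnames(m), labels$sample_id)]
  if (!any(lab == "control") || !any(lab == "case")) {
    abort("both a case and a control sample are required")
  }
  list(controls = as_expr_tbl(m[, lab == "control", drop = FALSE]),
       cases = as_expr_tbl(m[, lab == "case", drop = FALSE]))
}
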