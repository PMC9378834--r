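#' Single-sample pair-panel classifiers
#'
#' An `ssc_classifier` is an ordered panel of oriented miRNA pairs together
#' with the majority-reversed voting rule: each pair is stored in its control
#' orientation (`a` above `b`, i.e. E_a > E_b in controls), a pair votes
#' "reversed" in a sample when E_a < E_b there, and the sample is called a
#' case when more than half of the usable pairs vote reversed. Panels are
#' used with an odd number of pairs so that tie votes cannot arise for
#' tie-free expression values.
#'
#' @param pairs A data frame with character columns `a` and `b` (control
#'   orientation), one row per panel pair, in panel order.
#' @param name Free-text panel name.
#' @param vote_rule Decision rule tag; only `"majority_reversed"` is defined.
#' @return A tibble of class `ssc_classifier` with columns `a`, `b` and
#'   attributes `name` and `vote_rule`.
#' @examples
#' ssc_classifier(data.frame(a = c("x", "y", "z"), b = c("u", "v", "w")),
#'                name = "toy")
#' @export
ssc_classifier <- function(pairs, name = "classifier",
                           vote_rule = "majority_reversed") {
  pairs <- as_tibble(pairs)[, c("a", "b")]
  pairs$a <- as.character(pairs$a)
  pairs$b <- as.character(pairs$b)
  if (nrow(pairs) == 0 || any(!nzchar(pairs$a)) || any(!nzchar(pairs$b))) {
    abort("classifier needs at least one pair with nonempty miRNA ids")
  }
  if (any(pairs$a == pairs$b)) {
    abort("a pair cannot relate a miRNA to itself")
  }
  key <- unordered_key(pairs$a, pairs$b)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate pair(s) in panel: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (nrow(pairs) %% 2L == 0L) {
    warn(paste0("panel '", name, "' has an even number of pairs (",
                nrow(pairs), "); majority voting requires an odd panel"))
  }
  if (!identical(vote_rule, "majority_reversed")) {
    abort("only the 'majority_reversed' vote rule is defined")
  }
  structure(pairs, class = c("ssc_classifier", class(pairs)),
            name = name, vote_rule = vote_rule)
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read / write a classifier definition
#'
#' Classifiers are serialised as a small JSON document
#' `{"name": ..., "vote_rule": "majority_reversed",
#'   "pairs": [{"a": ..., "b": ...}, ...]}`; the write/read round trip is
#' lossless.
#'
#' @param path Path to a classifier JSON file.
#' @return [read_classifier()] returns an [ssc_classifier()].
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("name", "vote_rule", "pairs") %in% names(doc))) {
    abort("classifier document needs fields: name, vote_rule, pairs",
          class = "reopairs_format_error")
  }
  ssc_classifier(as_tibble(doc$pairs), name = doc$name,
                 vote_rule = doc$vote_rule)
}

#' @rdname read_classifier
#' @param classifier An [ssc_classifier()].
#' @export
write_classifier <- function(classifier, path) {
  doc <- list(name = attr(classifier, "name"),
              vote_rule = attr(classifier, "vote_rule"),
              pairs = as.data.frame(classifier[, c("a", "b")]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Published serum miRNA pair panels
#'
#' Loads one of the two published serum panels bundled with the package:
#' `"13-miRPairs"` (ovarian cancer vs non-cancer serum, 13 pairs over
#' 20 miRNAs) or `"17-miRPairs"` (ovarian cancer vs other cancers,
#' 17 pairs).
#'
#' @param name Panel name.
#' @return An [ssc_classifier()].
#' @examples
#' bundled_classifier("13-miRPairs")
#' @export
bundled_classifier <- function(name = c("13-miRPairs", "17-miRPairs")) {
  name <- match.arg(name)
  file <- switch(name,
                 "13-miRPairs" = "classifier_13_mirpairs.json",
                 "17-miRPairs" = "classifier_17_mirpairs.json")
  read_classifier(system.file("extdata", file, package = "reopairs",
                              mustWork = TRUE))
}

#' @export
print.ssc_classifier <- function(x, ...) {
  cat("# Pair-panel classifier '", attr(x, "name"), "': ", nrow(x),
      " pairs, vote rule ", attr(x, "vote_rule"), "\n", sep = "")
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.ssc_classifier <- function(x, ...) {
  tibble(rank = seq_len(nrow(x)), a = x$a, b = x$b)
}

#' @exportS3Method generics::glance
glance.ssc_classifier <- function(x, ...) {
  tibble(name = attr(x, "name"), n_pairs = nrow(x),
         n_mirnas = length(unique(c(x$a, x$b))),
         vote_rule = attr(x, "vote_rule"))
}
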