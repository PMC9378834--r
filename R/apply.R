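#' Majority-reversed vote on a single sample
#'
#' Applies a pair-panel classifier to one sample in isolation. Each panel
#' pair (stored in control orientation `a` over `b`) votes "reversed" when
#' E_a < E_b strictly in the sample and "conforming" when E_a > E_b
#' strictly; an exact tie votes neither way. The sample is labelled `case`
#' when reversed votes exceed half of the usable panel, and `control`
#' otherwise (so exact half-votes, possible only with ties or skipped
#' pairs, resolve conservatively to control).
#'
#' The vote depends only on within-sample orderings: it is invariant under
#' any strictly increasing transform of the sample's values, and never on
#' any other sample.
#'
#' @param sample A named numeric vector of expression values, or a one-sample
#'   expression table.
#' @param classifier An [ssc_classifier()].
#' @param permissive If `FALSE` (default), a panel miRNA missing from the
#'   sample is an error; if `TRUE` the affected pair is skipped, the usable
#'   panel shrinks accordingly, and a warning is issued.
#' @return A one-row tibble: `sample_id`, `votes_reversed`,
#'   `votes_conforming`, `n_usable`, `score` (= votes_reversed / n_usable,
#'   the ROC-ranking statistic), `label`.
#' @export
vote <- function(sample, classifier, permissive = FALSE) {
  if (is.data.frame(sample) || is.matrix(sample)) {
    m <- expr_values(sample)
    if (ncol(m) != 1L) abort("vote() takes a single sample; see classify_matrix()")
    out <- classify_matrix(m, classifier, permissive = permissive)
    return(out)
  }
  stopifnot(is.numeric(sample), !is.null(names(sample)))
  m <- matrix(sample, ncol = 1, dimnames = list(names(sample), "sample"))
  classify_matrix(m, classifier, permissive = permissive)
}

#' Classify every sample of a cohort
#'
#' Batch application of [vote()]: one independent majority-reversed vote per
#' sample (column). Results never depend on the other samples present.
#'
#' @param x Expression table ([mir_expr] tibble or matrix).
#' @inheritParams vote
#' @return A tibble with one row per sample, columns as in [vote()], in
#'   column order of `x`.
#' @export
classify_matrix <- function(x, classifier, permissive = FALSE) {
  m <- expr_values(x)
  panel <- as_tibble(classifier)[, c("a", "b")]
  present <- panel$a %in% rownames(m) & panel$b %in% rownames(m)
  if (!all(present)) {
    miss <- unique(c(panel$a, panel$b))
    miss <- miss[!miss %in% rownames(m)]
    if (!permissive) {
      abort(paste0("panel miRNA(s) missing from the expression table: ",
                   paste(miss, collapse = ", "),
                   " (use permissive = TRUE to skip affected pairs)"),
            class = "reopairs_lookup_error")
    }
    warn(paste0(sum(!present), " panel pair(s) skipped; missing miRNA(s): ",
                paste(miss, collapse = ", ")))
    panel <- panel[present, , drop = FALSE]
  }
  n_usable <- nrow(panel)
  if (n_usable == 0) abort("no usable panel pairs for this expression table")
  A <- m[match(panel$a, rownames(m)), , drop = FALSE]
  B <- m[match(panel$b, rownames(m)), , drop = FALSE]
  reversed <- unname(colSums(A < B))
  conforming <- unname(colSums(A > B))
  tibble(sample_id = colnames(m),
         votes_reversed = as.integer(reversed),
         votes_conforming = as.integer(conforming),
         n_usable = n_usable,
         score = reversed / n_usable,
         label = ifelse(reversed > n_usable / 2, "case", "control"))
}

# Printed coefficients of the published 10-miRNA linear diagnostic index
# (expression-level model used as a comparator to the rank-based panels).
yokoi_coefficients <- c(
  "miR-320a"    =  0.581,
  "miR-665"     =  0.691,
  "miR-3184-5p" = -0.704,
  "miR-6717-5p" = -0.313,
  "miR-4459"    = -1.302,
  "miR-6076"    =  0.729,
  "miR-3195"    =  0.676,
  "miR-1275"    =  0.716,
  "miR-3185"    =  0.672,
  "miR-4640-5p" = -0.384
)
yokoi_intercept <- -9.375

#' Linear 10-miRNA diagnostic index
#'
#' The published expression-level comparator model: a fixed linear score
#' over ten serum miRNAs, diagnostic index =
#' 0.581 x miR-320a + 0.691 x miR-665 - 0.704 x miR-3184-5p
#' - 0.313 x miR-6717-5p - 1.302 x miR-4459 + 0.729 x miR-6076
#' + 0.676 x miR-3195 + 0.716 x miR-1275 + 0.672 x miR-3185
#' - 0.384 x miR-4640-5p - 9.375, calling ovarian cancer when the index is
#' >= 0 and non-cancer when it is < 0. Unlike the pair-panel vote, this
#' score depends on absolute expression values and is *not* invariant under
#' monotonic transforms.
#'
#' @param x Expression table containing all ten model miRNAs, or a named
#'   numeric vector for a single sample.
#' @return A tibble with one row per sample: `sample_id`, `index`, `label`
#'   (`"case"` iff index >= 0).
#' @export
yokoi_index <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  m <- expr_values(x)
  need <- names(yokoi_coefficients)
  miss <- setdiff(need, rownames(m))
  if (length(miss)) {
    abort(paste0("missing miRNA(s) for the 10-miRNA index: ",
                 paste(miss, collapse = ", "),
                 "; required: ", paste(need, collapse = ", ")),
          class = "reopairs_lookup_error")
  }
  idx <- as.numeric(crossprod(m[need, , drop = FALSE],
                              yokoi_coefficients)) + yokoi_intercept
  tibble(sample_id = colnames(m),
         index = idx,
         label = ifelse(idx >= 0, "case", "control"))
}
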