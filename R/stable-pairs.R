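#' Count samples with a strict within-sample ordering
#'
#' For a pair of miRNAs (a, b), counts the samples in which the expression of
#' `a` strictly exceeds the expression of `b`. Exact ties count toward
#' neither orientation: the "bigger or smaller" relation is undefined at
#' equality.
#'
#' @param x Expression table ([mir_expr] tibble or named numeric matrix).
#' @param a,b miRNA identifiers present in `x`.
#' @return Integer count m, with 0 <= m <= N.
#' @export
ordering_count <- function(x, a, b) {
  m <- expr_values(x)
  if (a == b) abort("a and b must name different miRNAs")
  for (id in c(a, b)) {
    if (!id %in% rownames(m)) {
      abort(paste0("miRNA '", id, "' not found in expression table"),
            class = "reopairs_lookup_error")
    }
  }
  sum(m[a, ] > m[b, ])
}

# Accumulate the M x M matrix of strict-ordering counts C[i, j] =
# #{samples s : E_i(s) > E_j(s)}. One pass over samples; memory is bounded by
# a constant number of M x M tables (never a per-pair sample list), so the
# enumeration stays feasible at thousands of miRNAs.
reo_count_matrix <- function(m) {
  M <- nrow(m)
  counts <- matrix(0L, M, M, dimnames = list(rownames(m), rownames(m)))
  for (s in seq_len(ncol(m))) {
    v <- m[, s]
    counts <- counts + outer(v, v, ">")
  }
  counts
}

#' Mine miRNA pairs with stable orderings in a control cohort
#'
#' Examines all M(M-1)/2 unordered miRNA pairs and keeps those whose
#' majority orientation holds strictly in more than `threshold` of the
#' cohort's N samples (strict `>`: a pair at exactly the threshold is not
#' stable). Each kept pair is stored in its majority (control) orientation
#' `a` over `b`, with `stability` = m/N, where m counts samples with
#' E_a > E_b strictly and the denominator is the full cohort size.
#'
#' Because only orderings are used, the result is invariant to any strictly
#' increasing transform applied per sample.
#'
#' @param x Control-cohort expression table.
#' @param threshold Stability cutoff in (0, 1); 0.95 by default.
#' @return A tibble of class `stable_pairs` with columns `a`, `b`,
#'   `stability`, sorted lexicographically by (`a`, `b`), and attributes
#'   `threshold` and `cohort_size`.
#' @export
mine_stable_pairs <- function(x, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single number in (0, 1)",
          class = "reopairs_parameter_error")
  }
  m <- expr_values(x)
  N <- ncol(m)
  if (N < 1L) abort("cohort has no samples")
  counts <- reo_count_matrix(m)
  up <- upper.tri(counts)
  idx <- which(up, arr.ind = TRUE)
  ids <- rownames(m)
  c_ij <- counts[up]               # rows i < j: count of E_i > E_j
  c_ji <- t(counts)[up]            # count of E_j > E_i
  maj_first <- c_ij >= c_ji        # ties in counts resolved lexicographically
  a <- ifelse(maj_first, ids[idx[, "row"]], ids[idx[, "col"]])
  b <- ifelse(maj_first, ids[idx[, "col"]], ids[idx[, "row"]])
  stability <- pmax(c_ij, c_ji) / N
  keep <- stability > threshold
  out <- tibble(a = a[keep], b = b[keep], stability = stability[keep])
  out <- dplyr::arrange(out, .data$a, .data$b)
  structure(out, class = c("stable_pairs", class(out)),
            threshold = threshold, cohort_size = N)
}

# Proportion of samples in m showing the stored orientation a > b, per pair.
# Chunked over pairs to bound memory at `chunk` x N logicals.
pair_orientation_prop <- function(pairs, m, chunk = 50000L) {
  ia <- match(pairs$a, rownames(m))
  ib <- match(pairs$b, rownames(m))
  n <- nrow(pairs)
  prop <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    prop[sel] <- rowMeans(m[ia[sel], , drop = FALSE] >
                            m[ib[sel], , drop = FALSE])
  }
  prop
}

#' Retain stable pairs across a second control cohort
#'
#' Keeps the pairs whose stored orientation also holds strictly in more than
#' `threshold` of a second cohort's samples. Orientation is fixed at mining
#' time and never flipped here. Pairs referencing a miRNA absent from the
#' new cohort are dropped (and counted in the `n_missing` attribute), not
#' treated as an error.
#'
#' @param stable A `stable_pairs` tibble (or any tibble with columns
#'   `a`, `b`).
#' @param x Second control-cohort expression table.
#' @param threshold Stability cutoff in (0, 1); 0.95 by default.
#' @return A `stable_pairs` tibble restricted to the retained pairs, with
#'   `stability` recomputed on the new cohort and attributes `threshold`,
#'   `cohort_size`, `n_missing`.
#' @export
retain_in_cohort <- function(stable, x, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single number in (0, 1)",
          class = "reopairs_parameter_error")
  }
  m <- expr_values(x)
  present <- stable$a %in% rownames(m) & stable$b %in% rownames(m)
  n_missing <- sum(!present)
  if (n_missing > 0) {
    inform(paste0(n_missing, " pair(s) referenced a miRNA absent from the ",
                  "cohort and were dropped"))
  }
  pairs <- as_tibble(stable)[present, c("a", "b")]
  prop <- pair_orientation_prop(pairs, m)
  keep <- prop > threshold
  out <- tibble(a = pairs$a[keep], b = pairs$b[keep],
                stability = prop[keep])
  out <- dplyr::arrange(out, .data$a, .data$b)
  structure(out, class = c("stable_pairs", class(out)),
            threshold = threshold, cohort_size = ncol(m),
            n_missing = n_missing)
}

#' Read / write a stable-pair table
#'
#' Stable-pair sets are serialised as TSV with columns `a`, `b`,
#' `stability`, `cohort_size`.
#'
#' @param pairs A `stable_pairs` tibble.
#' @param path File path.
#' @return `read_stable_pairs()` returns a `stable_pairs` tibble.
#' @export
write_stable_pairs <- function(pairs, path) {
  df <- as_tibble(pairs)[, c("a", "b", "stability")]
  df$cohort_size <- attr(pairs, "cohort_size") %||% NA_integer_
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_stable_pairs
#' @export
read_stable_pairs <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          a = "c", b = "c", stability = "d",
                          cohort_size = "i"))
  out <- df[, c("a", "b", "stability")]
  structure(out, class = c("stable_pairs", class(out)),
            cohort_size = df$cohort_size[1])
}

#' @export
print.stable_pairs <- function(x, ...) {
  cat("# Stable pairs:", nrow(x), "pairs",
      if (!is.null(attr(x, "threshold")))
        paste0("(stability > ", attr(x, "threshold"), ", N = ",
               attr(x, "cohort_size"), ")"),
      "\n")
  NextMethod()
}
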