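#' Contingency counts for reversal testing
#'
#' For each control-stable pair in its stored orientation (E_a > E_b in
#' controls), tabulates the 2 x 2 contingency of strict orderings:
#' `n1` / `n2` controls with E_a > E_b / E_a < E_b and `m1` / `m2` cases
#' with E_a > E_b / E_a < E_b. Exact ties fall in neither column, so
#' n1 + n2 and m1 + m2 may be smaller than the cohort sizes.
#'
#' @param pairs A tibble with columns `a`, `b` (stored control orientation),
#'   e.g. from [mine_stable_pairs()] or [retain_in_cohort()].
#' @param controls,cases Expression tables for the two cohorts.
#' @return A `pair_stats` tibble: the input pair columns plus `n1`, `n2`,
#'   `m1`, `m2` and `reversal_rate` = m2 / (m1 + m2) (NA when m1 + m2 = 0).
#' @export
contingency_counts <- function(pairs, controls, cases) {
  mc <- expr_values(controls)
  mx <- expr_values(cases)
  pairs <- as_tibble(pairs)
  missing <- setdiff(unique(c(pairs$a, pairs$b)),
                     intersect(rownames(mc), rownames(mx)))
  if (length(missing)) {
    abort(paste0("miRNA(s) absent from a cohort: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "reopairs_lookup_error")
  }
  count_dir <- function(m, ia, ib, chunk = 50000L) {
    n <- length(ia)
    gt <- integer(n)
    lt <- integer(n)
    for (start in seq(1L, n, by = chunk)) {
      sel <- start:min(start + chunk - 1L, n)
      A <- m[ia[sel], , drop = FALSE]
      B <- m[ib[sel], , drop = FALSE]
      gt[sel] <- rowSums(A > B)
      lt[sel] <- rowSums(A < B)
    }
    list(gt = gt, lt = lt)
  }
  cc <- count_dir(mc, match(pairs$a, rownames(mc)),
                  match(pairs$b, rownames(mc)))
  cx <- count_dir(mx, match(pairs$a, rownames(mx)),
                  match(pairs$b, rownames(mx)))
  out <- pairs
  out$n1 <- cc$gt
  out$n2 <- cc$lt
  out$m1 <- cx$gt
  out$m2 <- cx$lt
  out$reversal_rate <- ifelse(out$m1 + out$m2 > 0,
                              out$m2 / (out$m1 + out$m2), NA_real_)
  structure(out, class = c("pair_stats", class(out)))
}

#' Fisher's exact reversal test
#'
#' Tests, per pair, whether cases are enriched for the reversed ordering
#' E_a < E_b relative to controls. The default one-sided p-value is the
#' exact hypergeometric tail P(X >= m2) conditional on the table margins
#' (identical to `fisher.test(alternative = "greater")` on the table
#' rows (n1, n2) / (m1, m2), but vectorised); `"two.sided"` delegates to
#' [stats::fisher.test()].
#'
#' @param stats A `pair_stats` tibble with columns `n1`, `n2`, `m1`, `m2`.
#' @param alternative `"greater"` (one-sided toward reversal, default) or
#'   `"two.sided"`.
#' @return The input with a `p_value` column appended.
#' @export
fisher_reversal_test <- function(stats,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  need <- c("n1", "n2", "m1", "m2")
  stopifnot(all(need %in% names(stats)))
  tot <- stats$n1 + stats$n2 + stats$m1 + stats$m2
  if (any(tot == 0)) {
    abort("all four counts are zero for at least one pair; the test is undefined",
          class = "reopairs_undefined_test")
  }
  if (alternative == "greater") {
    # X ~ Hypergeom(reversed total = n2 + m2, conforming total = n1 + m1,
    #               draws = tie-free cases m1 + m2); p = P(X >= m2)
    p <- phyper(stats$m2 - 1L, stats$n2 + stats$m2, stats$n1 + stats$m1,
                stats$m1 + stats$m2, lower.tail = FALSE)
  } else {
    p <- vapply(seq_len(nrow(stats)), function(i) {
      stats::fisher.test(matrix(c(stats$n1[i], stats$n2[i],
                                  stats$m1[i], stats$m2[i]),
                                2, 2, byrow = TRUE))$p.value
    }, numeric(1))
  }
  out <- stats
  out$p_value <- pmin(p, 1)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), clipped to 1 and order-preserving in the p ranks.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Select candidate diagnostic pairs
#'
#' Keeps the significantly reversed pairs: BH q-value below `q_threshold`
#' and reversal rate (fraction of tie-free cases showing E_a < E_b) at
#' least `reversal_threshold`. The result is sorted by reversal rate
#' (descending), then q (ascending), then (`a`, `b`) lexicographically.
#' A `q_value` column is computed with [bh_adjust()] if not already present.
#'
#' @param stats A `pair_stats` tibble with `p_value` (and optionally
#'   `q_value`) columns.
#' @param q_threshold FDR cutoff; pairs must have q < `q_threshold`
#'   (default 0.05).
#' @param reversal_threshold Minimum case reversal rate, inclusive
#'   (default 0.70).
#' @return A `candidate_pairs` tibble with attributes `q_threshold` and
#'   `reversal_threshold`.
#' @export
select_candidates <- function(stats, q_threshold = 0.05,
                              reversal_threshold = 0.70) {
  out <- as_tibble(stats)
  if (!"q_value" %in% names(out)) {
    stopifnot("p_value" %in% names(out))
    out$q_value <- bh_adjust(out$p_value)
  }
  keep <- !is.na(out$reversal_rate) &
    out$q_value < q_threshold &
    out$reversal_rate >= reversal_threshold
  out <- out[keep, , drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$reversal_rate),
                        .data$q_value, .data$a, .data$b)
  structure(out, class = c("candidate_pairs", class(out)),
            q_threshold = q_threshold,
            reversal_threshold = reversal_threshold)
}

#' Read / write a pair-statistics table
#'
#' @param stats A `pair_stats` / `candidate_pairs` tibble.
#' @param path File path (TSV with columns a, b, n1, n2, m1, m2, p_value,
#'   q_value, reversal_rate).
#' @return `read_pair_stats()` returns a `pair_stats` tibble.
#' @export
write_pair_stats <- function(stats, path) {
  keep <- intersect(c("a", "b", "stability", "n1", "n2", "m1", "m2",
                      "p_value", "q_value", "reversal_rate"), names(stats))
  readr::write_tsv(as_tibble(stats)[, keep], path)
  invisible(path)
}

#' @rdname write_pair_stats
#' @export
read_pair_stats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  structure(as_tibble(df), class = c("pair_stats", class(as_tibble(df))))
}
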