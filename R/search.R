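#' Case samples covered by a reversed pair
#'
#' A pair "covers" a case sample when the sample shows the reversed ordering
#' E_a < E_b strictly. Coverage proportion is the size of this set over the
#' number of case samples.
#'
#' @param pair A length-2 character vector `c(a, b)` or a one-row data frame
#'   with columns `a`, `b` (control orientation).
#' @param cases Case-cohort expression table.
#' @return Character vector of covered case sample ids.
#' @export
pair_coverage <- function(pair, cases) {
  if (is.data.frame(pair)) pair <- c(pair$a[1], pair$b[1])
  m <- expr_values(cases)
  for (id in pair) {
    if (!id %in% rownames(m)) {
      abort(paste0("miRNA '", id, "' not found in case cohort"),
            class = "reopairs_lookup_error")
    }
  }
  colnames(m)[m[pair[1], ] < m[pair[2], ]]
}

# Logical pairs x samples indicator of the reversed ordering E_a < E_b.
reversal_matrix <- function(pairs, m) {
  ia <- match(pairs$a, rownames(m))
  ib <- match(pairs$b, rownames(m))
  if (anyNA(ia) || anyNA(ib)) {
    abort("candidate pair references a miRNA absent from the cohort",
          class = "reopairs_lookup_error")
  }
  R <- m[ia, , drop = FALSE] < m[ib, , drop = FALSE]
  rownames(R) <- unordered_key(pairs$a, pairs$b)
  R
}

# Deterministic candidate preference used for every tie-break: smaller q,
# then higher reversal rate, then lexicographic (a, b).
candidate_preference <- function(candidates) {
  q <- candidates$q_value %||% rep(0, nrow(candidates))
  r <- candidates$reversal_rate %||% rep(0, nrow(candidates))
  order(q, -r, candidates$a, candidates$b)
}

#' Grow a coverage combination around a pivot pair
#'
#' Starting from a pivot pair, greedily adds candidate pairs so as to
#' maximise, at each step, the joint coverage of case samples — the fraction
#' of cases in which at least one member pair shows the reversed ordering
#' (union semantics). Growth stops when no remaining candidate strictly
#' increases coverage. Ties between equally good additions are broken by
#' smaller q-value, then higher reversal rate, then lexicographic (a, b).
#'
#' `mode = "intersection"` instead scores a combination by the fraction of
#' cases in which every member is reversed; it is provided for sensitivity
#' analysis (adding a pair can then never increase coverage, so combinations
#' degenerate to the pivot alone).
#'
#' @param pivot A length-2 character vector `c(a, b)` or one-row data frame;
#'   must be one of the candidate pairs.
#' @param candidates A `candidate_pairs` tibble (columns `a`, `b`, and for
#'   tie-breaking `q_value`, `reversal_rate`).
#' @param cases Case-cohort expression table.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return A tibble of member pairs in addition order (pivot first) with
#'   attributes `coverage` (final proportion) and `coverage_history`.
#' @export
grow_combination <- function(pivot, candidates, cases,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.data.frame(pivot)) pivot <- c(pivot$a[1], pivot$b[1])
  candidates <- as_tibble(candidates)
  m <- expr_values(cases)
  R <- reversal_matrix(candidates, m)
  pivot_idx <- which(candidates$a == pivot[1] & candidates$b == pivot[2])
  if (length(pivot_idx) != 1L) {
    abort("pivot must be exactly one of the candidate pairs")
  }
  pref <- integer(nrow(candidates))
  pref[candidate_preference(candidates)] <- seq_len(nrow(candidates))

  members <- pivot_idx
  covered <- R[pivot_idx, ]
  history <- mean(covered)
  remaining <- setdiff(seq_len(nrow(candidates)), pivot_idx)
  while (length(remaining) > 0) {
    if (mode == "union") {
      gains <- rowSums(R[remaining, !covered, drop = FALSE])
    } else {
      gains <- rowSums(R[remaining, , drop = FALSE] &
                         rep(covered, each = length(remaining))) -
        sum(covered)
    }
    best_gain <- max(gains)
    if (best_gain <= 0) break
    tied <- remaining[gains == best_gain]
    add <- tied[which.min(pref[tied])]
    members <- c(members, add)
    covered <- covered | R[add, ]
    history <- c(history, mean(covered))
    remaining <- setdiff(remaining, add)
  }
  out <- candidates[members, , drop = FALSE]
  structure(out, class = c("pair_combination", class(out)),
            coverage = mean(covered), coverage_history = history,
            pivot = pivot)
}

#' Grow one combination per candidate pivot
#'
#' @param candidates A `candidate_pairs` tibble.
#' @param cases Case-cohort expression table.
#' @inheritParams grow_combination
#' @return A list of combinations, one per candidate pair (in candidate
#'   order).
#' @export
build_combinations <- function(candidates, cases,
                               mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  candidates <- as_tibble(candidates)
  purrr::map(seq_len(nrow(candidates)), function(i) {
    grow_combination(c(candidates$a[i], candidates$b[i]), candidates, cases,
                     mode = mode)
  })
}

#' Rank candidate pairs by occurrence frequency across combinations
#'
#' Counts how many combinations each candidate pair occurs in and ranks the
#' pairs by frequency (descending), breaking ties by smaller q-value, then
#' higher reversal rate, then lexicographic (a, b).
#'
#' @param combinations A list of combinations from [build_combinations()].
#' @return A `ranked_pairs` tibble with columns `a`, `b`, `frequency`, plus
#'   any `q_value` / `reversal_rate` columns carried from the candidates.
#' @export
rank_by_frequency <- function(combinations) {
  if (length(combinations) == 0) {
    return(structure(tibble(a = character(), b = character(),
                            frequency = integer()),
                     class = c("ranked_pairs", "tbl_df", "tbl", "data.frame")))
  }
  all_members <- dplyr::bind_rows(lapply(combinations, as_tibble))
  counted <- dplyr::summarise(
    dplyr::group_by(all_members, .data$a, .data$b),
    frequency = dplyr::n(),
    dplyr::across(dplyr::any_of(c("q_value", "reversal_rate", "stability")),
                  dplyr::first),
    .groups = "drop")
  q <- counted$q_value %||% rep(0, nrow(counted))
  r <- counted$reversal_rate %||% rep(0, nrow(counted))
  counted <- counted[order(-counted$frequency, q, -r, counted$a, counted$b), ]
  structure(counted, class = c("ranked_pairs", class(counted)))
}

#' Evaluate a top-n voting panel on the training cohorts
#'
#' Forms the panel of the `n` highest-ranked pairs, classifies the case and
#' control cohorts with the majority-reversed voting rule, and returns the
#' evaluation index sqrt(PPV x NPV). If PPV or NPV is undefined (a zero
#' denominator: no positive or no negative calls), the index is 0 with a
#' warning.
#'
#' @param ranked A `ranked_pairs` tibble.
#' @param n Odd panel size, `n <= nrow(ranked)`.
#' @param cases,controls Expression tables for the training cohorts.
#' @return The evaluation index in `[0, 1]`.
#' @export
evaluate_top_n <- function(ranked, n, cases, controls) {
  if (n %% 2L == 0L) {
    abort("panel size n must be odd for majority voting",
          class = "reopairs_parameter_error")
  }
  if (n > nrow(ranked)) {
    abort("n exceeds the number of ranked pairs",
          class = "reopairs_parameter_error")
  }
  panel <- ssc_classifier(as_tibble(ranked)[seq_len(n), c("a", "b")],
                          name = paste0("top-", n))
  pred_case <- classify_matrix(cases, panel)
  pred_ctrl <- classify_matrix(controls, panel)
  tp <- sum(pred_case$label == "case")
  fn <- sum(pred_case$label == "control")
  fp <- sum(pred_ctrl$label == "case")
  tn <- sum(pred_ctrl$label == "control")
  if (tp + fp == 0 || tn + fn == 0) {
    warn(paste0("top-", n, " panel makes no ",
                if (tp + fp == 0) "positive" else "negative",
                " calls; evaluation index set to 0"))
    return(0)
  }
  sqrt((tp / (tp + fp)) * (tn / (tn + fn)))
}

#' Select the final voting panel
#'
#' Evaluates every odd panel size n from 1 to `min(max_top, nrow(ranked))`
#' with [evaluate_top_n()] on the training cohorts and picks the smallest n
#' attaining the maximal evaluation index sqrt(PPV x NPV).
#'
#' @inheritParams evaluate_top_n
#' @param max_top Largest panel size considered (default 31).
#' @param name Name given to the selected classifier.
#' @return An object of class `ssc_selection`: a list with elements
#'   `report` (tibble of `n`, `eval_index`), `chosen_n`, and `classifier`
#'   (the selected [ssc_classifier()]). `tidy()` returns the report;
#'   `glance()` the chosen row.
#' @export
select_classifier <- function(ranked, cases, controls, max_top = 31,
                              name = "ssc") {
  stopifnot(nrow(ranked) >= 1)
  ns <- seq(1L, min(max_top, nrow(ranked)), by = 2L)
  idx <- vapply(ns, function(n) evaluate_top_n(ranked, n, cases, controls),
                numeric(1))
  chosen <- ns[which.max(idx)]  # which.max returns the first (smallest) maximiser
  classifier <- ssc_classifier(as_tibble(ranked)[seq_len(chosen),
                                                 c("a", "b")],
                               name = name)
  structure(list(report = tibble(n = ns, eval_index = idx),
                 chosen_n = chosen,
                 eval_index = max(idx),
                 classifier = classifier),
            class = "ssc_selection")
}

#' @export
print.ssc_selection <- function(x, ...) {
  cat("# Panel selection over odd n in 1..", max(x$report$n), "\n", sep = "")
  cat("# chosen n =", x$chosen_n,
      sprintf("(eval index sqrt(PPV*NPV) = %.4f)\n", x$eval_index))
  print(x$classifier)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ssc_selection <- function(x, ...) {
  dplyr::mutate(x$report, chosen = .data$n == x$chosen_n)
}

#' @exportS3Method generics::glance
glance.ssc_selection <- function(x, ...) {
  tibble(chosen_n = x$chosen_n, eval_index = x$eval_index,
         n_evaluated = nrow(x$report))
}
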