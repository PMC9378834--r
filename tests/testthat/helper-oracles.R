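# Independent brute-force oracles: naive per-sample loops and closed forms,
# written without reference to the package internals they check.

o_ordering_count <- function(m, a, b) {
  n <- 0L
  for (s in seq_len(ncol(m))) {
    if (m[a, s] > m[b, s]) n <- n + 1L
  }
  n
}

# Exhaustive double-loop enumeration of stable pairs (majority orientation,
# strict threshold), returned sorted lexicographically.
o_stable_pairs <- function(m, threshold) {
  ids <- rownames(m)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      mij <- o_ordering_count(m, ids[i], ids[j])
      mji <- o_ordering_count(m, ids[j], ids[i])
      if (mij >= mji) {
        a <- ids[i]; b <- ids[j]; stab <- mij / ncol(m)
      } else {
        a <- ids[j]; b <- ids[i]; stab <- mji / ncol(m)
      }
      if (stab > threshold) {
        out[[length(out) + 1L]] <- data.frame(a = a, b = b,
                                              stability = stab)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      stability = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$a, res$b), , drop = FALSE]
}

o_contingency <- function(mc, mx, a, b) {
  c(n1 = o_ordering_count(mc, a, b), n2 = o_ordering_count(mc, b, a),
    m1 = o_ordering_count(mx, a, b), m2 = o_ordering_count(mx, b, a))
}

o_coverage <- function(m, a, b) {
  covered <- character()
  for (s in seq_len(ncol(m))) {
    if (m[a, s] < m[b, s]) covered <- c(covered, colnames(m)[s])
  }
  covered
}

# One-sided exact tail: sum of hypergeometric point masses at least as
# extreme as m2 in the reversal direction.
o_fisher_tail <- function(n1, n2, m1, m2) {
  K <- n2 + m2          # reversed-column total
  nd <- m1 + m2         # case-row total
  x_max <- min(K, nd)
  sum(stats::dhyper(m2:x_max, K, n1 + m1, nd))
}

# Hand step-up BH: q_(i) = min_{j >= i} p_(j) * n / j, clipped at 1.
o_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Independent greedy trace on explicit coverage sets; ties broken by
# smaller q, then higher reversal rate, then lexicographic (a, b).
o_greedy <- function(pivot_i, cand, covsets) {
  pref <- integer(nrow(cand))
  pref[order(cand$q_value, -cand$reversal_rate, cand$a, cand$b)] <-
    seq_len(nrow(cand))
  members <- pivot_i
  covered <- covsets[[pivot_i]]
  remaining <- setdiff(seq_along(covsets), pivot_i)
  while (length(remaining)) {
    gains <- vapply(remaining,
                    function(i) length(setdiff(covsets[[i]], covered)),
                    integer(1))
    if (max(gains) == 0L) break
    tied <- remaining[gains == max(gains)]
    add <- tied[which.min(pref[tied])]
    members <- c(members, add)
    covered <- union(covered, covsets[[add]])
    remaining <- setdiff(remaining, add)
  }
  members
}

# O(n^2) pairwise AUC: case-beats-control comparisons, ties count one half.
o_auc <- function(scores_case, scores_ctrl) {
  tot <- 0
  for (x in scores_case) {
    for (y in scores_ctrl) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(scores_case) * length(scores_ctrl))
}
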