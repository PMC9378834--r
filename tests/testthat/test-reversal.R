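pair_tbl <- function(a = "A", b = "B") tibble::tibble(a = a, b = b)

test_that("contingency counts match per-sample loops and exclude ties", {
  mc <- matrix(c(2, 1), 2, 10, dimnames = list(c("A", "B"), paste0("c", 1:10)))
  mx <- matrix(c(1, 2), 2, 5, dimnames = list(c("A", "B"), paste0("x", 1:5)))
  st <- contingency_counts(pair_tbl(), mc, mx)
  expect_equal(unlist(st[c("n1", "n2", "m1", "m2")], use.names = FALSE),
               c(10L, 0L, 0L, 5L))
  expect_equal(st$reversal_rate, 1)

  # identical cohorts give proportional counts
  st2 <- contingency_counts(pair_tbl(), mc, mc)
  expect_equal(st2$n1 / (st2$n1 + st2$n2), st2$m1 / (st2$m1 + st2$m2))

  set.seed(14)
  for (rep in 1:10) {
    mc <- rand_expr(2, 30, prefix = "p")
    mx <- rand_expr(2, 20, prefix = "p")
    got <- contingency_counts(tibble::tibble(a = "p01", b = "p02"), mc, mx)
    want <- o_contingency(mc, mx, "p01", "p02")
    expect_equal(unlist(got[c("n1", "n2", "m1", "m2")], use.names = FALSE),
                 unname(want))
  }

  expect_error(contingency_counts(pair_tbl("A", "Z"), mc, mx),
               class = "reopairs_lookup_error")
})

test_that("one-sided reversal p-values equal the exact hypergeometric tail", {
  # the published leading pair: counts reconstructed from the printed
  # control/case proportions (0.981, 0.095) at cohort sizes 2,000 / 200
  st <- tibble::tibble(a = "miR-6893-5p", b = "miR-1290",
                       n1 = 1962, n2 = 38, m1 = 19, m2 = 181)
  p <- fisher_reversal_test(st)$p_value
  expect_lt(p, 2.2e-16)
  expect_equal(p, o_fisher_tail(1962, 38, 19, 181))

  # complete separation: closed-form point mass 1 / choose(10, 5)
  st2 <- tibble::tibble(a = "A", b = "B", n1 = 5, n2 = 0, m1 = 0, m2 = 5)
  expect_equal(fisher_reversal_test(st2)$p_value, 1 / choose(10, 5))
  expect_equal(fisher_reversal_test(st2)$p_value, o_fisher_tail(5, 0, 0, 5))

  # balanced margins carry no evidence of reversal
  st3 <- tibble::tibble(a = "A", b = "B", n1 = 10, n2 = 10, m1 = 10, m2 = 10)
  expect_equal(fisher_reversal_test(st3)$p_value, o_fisher_tail(10, 10, 10, 10))
  expect_gt(fisher_reversal_test(st3)$p_value, 0.5)

  expect_error(fisher_reversal_test(tibble::tibble(a = "A", b = "B", n1 = 0,
                                                   n2 = 0, m1 = 0, m2 = 0)),
               class = "reopairs_undefined_test")
})

test_that("reversal p-values agree with fisher.test and stay in (0, 1]", {
  set.seed(77)
  for (rep in 1:25) {
    counts <- as.list(sample(0:40, 4, replace = TRUE))
    names(counts) <- c("n1", "n2", "m1", "m2")
    if (sum(unlist(counts)) == 0) counts$n1 <- 1L
    st <- tibble::tibble(a = "A", b = "B", !!!counts)
    p1 <- fisher_reversal_test(st)$p_value
    p_ref <- stats::fisher.test(matrix(unlist(counts), 2, 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(p1, p_ref, tolerance = 1e-12)
    expect_equal(p1, o_fisher_tail(counts$n1, counts$n2,
                                   counts$m1, counts$m2),
                 tolerance = 1e-12)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
    p2 <- fisher_reversal_test(st, alternative = "two.sided")$p_value
    expect_equal(p2, stats::fisher.test(matrix(unlist(counts), 2, 2,
                                               byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(8)
  for (rep in 1:10) {
    p <- stats::runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, o_bh(p))
    expect_true(all(q <= 1) && all(q >= p))
    expect_true(all(diff(q[order(p)]) >= 0))  # monotone in the p ranks
  }
})

test_that("candidate selection applies both thresholds and sorts deterministically", {
  st <- tibble::tibble(
    a = c("A", "B", "C", "D"), b = c("x", "y", "z", "w"),
    n1 = 100, n2 = 2,
    m1 = c(25, 35, 10, 10), m2 = c(75, 65, 90, 90),
    p_value = c(1e-10, 1e-12, 1e-20, 1e-8))
  st$reversal_rate <- st$m2 / (st$m1 + st$m2)
  cand <- select_candidates(st, q_threshold = 0.05,
                            reversal_threshold = 0.70)
  expect_identical(cand$a, c("C", "D", "A"))  # 0.9 (q asc), then 0.75
  expect_false("B" %in% cand$a)               # reversal 0.65 < 0.70
  expect_true(all(cand$q_value < 0.05 & cand$reversal_rate >= 0.70))

  # boundary: reversal exactly 0.70 is kept (>= semantics)
  st_b <- tibble::tibble(a = "E", b = "v", n1 = 50, n2 = 0, m1 = 30, m2 = 70,
                         p_value = 1e-9, reversal_rate = 0.70)
  expect_equal(nrow(select_candidates(st_b)), 1L)

  # loosening either threshold never removes a candidate
  tight <- select_candidates(st, 0.01, 0.80)
  loose_q <- select_candidates(st, 0.10, 0.80)
  loose_r <- select_candidates(st, 0.01, 0.60)
  expect_true(all(paste(tight$a, tight$b) %in% paste(loose_q$a, loose_q$b)))
  expect_true(all(paste(tight$a, tight$b) %in% paste(loose_r$a, loose_r$b)))
})

test_that("planted reversed pairs are recovered as candidates", {
  sim <- generate_cohorts(sim_config(seed = 404))
  st <- mine_stable_pairs(sim$controls, 0.95)
  stats <- fisher_reversal_test(contingency_counts(st, sim$controls,
                                                   sim$cases))
  cand <- select_candidates(stats)
  expect_true(all(paste(sim$truth$a, sim$truth$b) %in%
                    paste(cand$a, cand$b)))
})
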