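# In-code fixtures shared across tests.

rand_expr <- function(M, N, seed = NULL, prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(round(stats::runif(M * N, 1, 100), 3), M, N)
  dimnames(m) <- list(sprintf("%s%02d", prefix, seq_len(M)),
                      sprintf("s%02d", seq_len(N)))
  m
}

# A matrix whose per-miRNA baselines are well separated, so orderings are
# stable up to the given noise.
layered_expr <- function(M, N, gap = 2, noise = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- seq_len(M) * gap + matrix(stats::rnorm(M * N, sd = noise), M, N)
  dimnames(m) <- list(sprintf("g%02d", seq_len(M)),
                      sprintf("s%02d", seq_len(N)))
  m
}

write_plain_tsv <- function(m, path) {
  lines <- c(paste(c("mirna", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)),
                    function(i) paste(c(rownames(m)[i],
                                        format(m[i, ], trim = TRUE)),
                                      collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  path
}

# Build a candidate table + case matrix in which each candidate pair's
# reversal set is exactly a prescribed set of samples. miRNA pairs are
# disjoint; sample s shows E_a < E_b for pair i iff s is in covsets[[i]].
cases_from_covsets <- function(covsets, n_samples, q = NULL, rev = NULL) {
  k <- length(covsets)
  samples <- sprintf("s%02d", seq_len(n_samples))
  m <- matrix(0, 2 * k, n_samples,
              dimnames = list(sprintf("m%02d", seq_len(2 * k)), samples))
  for (i in seq_len(k)) {
    a <- 2 * i - 1
    b <- 2 * i
    m[a, ] <- 2   # control orientation: a over b
    m[b, ] <- 1
    m[b, samples %in% covsets[[i]]] <- 3  # reversed in covered samples
  }
  cand <- tibble::tibble(
    a = sprintf("m%02d", 2 * seq_len(k) - 1),
    b = sprintf("m%02d", 2 * seq_len(k)),
    q_value = if (is.null(q)) rep(1e-6, k) else q,
    reversal_rate = if (is.null(rev)) lengths(covsets) / n_samples else rev)
  list(cand = cand, cases = m)
}

# The ten miRNAs of the linear comparator model, in its printed order.
yokoi_mirnas <- c("miR-320a", "miR-665", "miR-3184-5p", "miR-6717-5p",
                  "miR-4459", "miR-6076", "miR-3195", "miR-1275",
                  "miR-3185", "miR-4640-5p")
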