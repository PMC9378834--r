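test_that("plain TSV expression tables round-trip losslessly", {
  m <- rand_expr(10, 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_s3_class(back, "mir_expr")
  expect_identical(rownames(expr_values(back)), rownames(m))
  expect_identical(colnames(expr_values(back)), colnames(m))
  expect_equal(unname(expr_values(back)), unname(m))

  # small hand-written table preserves values and order as written
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "mA\t1.5\t2", "mB\t3\t4", "mC\t5\t0.25"), p2)
  tbl <- read_expression_matrix(p2)
  expect_equal(dim(expr_values(tbl)), c(3L, 2L))
  expect_equal(expr_values(tbl)["mC", "s2"], 0.25)
})

test_that("GEO series-matrix dialect reads only the delimited table block", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c('!Series_title\t"a tiny series"',
               '!Series_platform_id\t"GPL00000"',
               "!series_matrix_table_begin",
               '"ID_REF"\t"GSM1"\t"GSM2"\t"GSM3"',
               '"miR-1"\t5\t6\t7',
               '"miR-2"\t1\t2\t3',
               '"miR-3"\t9\t8\t7',
               '"miR-4"\t0.5\t0.25\t4',
               "!series_matrix_table_end",
               ""), p)
  tbl <- read_expression_matrix(p, dialect = "geo_series_matrix")
  m <- expr_values(tbl)
  expect_equal(dim(m), c(4L, 3L))
  expect_identical(rownames(m), c("miR-1", "miR-2", "miR-3", "miR-4"))
  expect_identical(colnames(m), c("GSM1", "GSM2", "GSM3"))
  # independent check of one row against a direct text parse
  raw <- strsplit(readLines(p)[8], "\t")[[1]]
  expect_equal(unname(m["miR-4", ]), as.numeric(raw[-1]))

  # missing delimiters are a format error
  p_bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!Series_title\tx", "ID_REF\tGSM1", "miR-1\t5"), p_bad)
  expect_error(read_expression_matrix(p_bad, dialect = "geo_series_matrix"),
               class = "reopairs_format_error")
})

test_that("malformed expression tables are rejected with located errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "mA\t1\t2", "mA\t3\t4"), p)
  expect_error(read_expression_matrix(p), class = "reopairs_format_error")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "mA\t1\toops", "mB\t3\t4"), p2)
  err <- expect_error(read_expression_matrix(p2),
                      class = "reopairs_parse_error")
  expect_match(conditionMessage(err), "mA")
  expect_match(conditionMessage(err), "s2")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "mA\t1\tNA", "mB\t3\t4"), p3)
  expect_error(read_expression_matrix(p3), class = "reopairs_parse_error")
})

test_that("parsing is independent of line endings and trailing blank lines", {
  m <- rand_expr(4, 3, seed = 3)
  p_unix <- withr::local_tempfile(fileext = ".tsv")
  write_plain_tsv(m, p_unix)
  p_crlf <- withr::local_tempfile(fileext = ".tsv")
  writeBin(charToRaw(paste0(paste(readLines(p_unix), collapse = "\r\n"),
                            "\r\n\r\n")), p_crlf)
  a <- read_expression_matrix(p_unix)
  b <- read_expression_matrix(p_crlf)
  expect_equal(expr_values(a), expr_values(b))
})

test_that("label files parse, normalise tokens, and enforce uniqueness", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s2\tcontrol"), p)
  lab <- read_labels(p)
  expect_equal(nrow(lab), 2L)
  expect_identical(lab$label, c("case", "control"))

  p_dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s1\tcontrol"), p_dup)
  expect_error(read_labels(p_dup), class = "reopairs_format_error")

  p_tok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s2\tmaybe"), p_tok)
  err <- expect_error(read_labels(p_tok), class = "reopairs_format_error")
  expect_match(conditionMessage(err), "control")
})

test_that("a training-scale label file yields the expected class counts", {
  # emulates the 200-case / 2,000-control training split
  p <- withr::local_tempfile(fileext = ".tsv")
  ids <- sprintf("s%04d", 1:2200)
  writeLines(paste(ids, rep(c("case", "control"), c(200, 2000)), sep = "\t"),
             p)
  lab <- read_labels(p)
  expect_equal(unname(table(lab$label)["case"]), 200)
  expect_equal(unname(table(lab$label)["control"]), 2000)
})

test_that("bundled panels load with the published sizes and leading pairs", {
  p13 <- bundled_classifier("13-miRPairs")
  expect_equal(nrow(p13), 13L)
  expect_identical(p13$a[1], "miR-6893-5p")
  expect_identical(p13$b[1], "miR-1290")
  expect_equal(glance(p13)$n_mirnas, 20L)

  p17 <- bundled_classifier("17-miRPairs")
  expect_equal(nrow(p17), 17L)
  expect_identical(p17$a[1], "miR-6746-5p")
  expect_identical(p17$b[1], "miR-6887-5p")
})

test_that("classifier JSON round-trips and invariants are enforced", {
  cl <- ssc_classifier(tibble::tibble(a = c("x", "y", "z"),
                                      b = c("u", "v", "w")),
                       name = "toy")
  p <- withr::local_tempfile(fileext = ".json")
  write_classifier(cl, p)
  back <- read_classifier(p)
  expect_identical(as.data.frame(back), as.data.frame(cl))
  expect_identical(attr(back, "name"), "toy")
  expect_identical(attr(back, "vote_rule"), "majority_reversed")

  expect_warning(ssc_classifier(tibble::tibble(a = c("x", "y"),
                                               b = c("u", "v"))),
                 "even")
  expect_error(ssc_classifier(tibble::tibble(a = c("x", "u"),
                                             b = c("u", "x"))),
               "duplicate")
})
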