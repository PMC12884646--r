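test_that("bundled DSM-5 corpus matches the published statement set", {
  expect_s3_class(dsm5, "symptom_corpus")
  expect_equal(nrow(dsm5), 18L)
  expect_equal(sum(dsm5$domain == "inattention"), 9L)
  expect_equal(sum(dsm5$domain == "hyperactivity_impulsivity"), 9L)
  expect_identical(
    dsm5_inatt$text[2],
    "Often has difficulty in sustaining attention in tasks or play activities")
  # curly-quoted idioms preserved verbatim
  expect_match(dsm5_hyper$text[5], "“driven by a motor”", fixed = TRUE)
})

test_that("bundled score tables carry 36 well-formed pairs per domain", {
  for (tab in list(tbl5, tbl6)) {
    expect_equal(tab$m, 36L)
    expect_equal(tab$n, 3L)
    # every unordered pair of 1..9 exactly once, stored as (low, high)
    expect_setequal(tab$labels,
                    apply(t(combn(9, 2)), 1,
                          function(p) sprintf("(%d,%d)", p[1], p[2])))
    expect_true(all(tab$x > 0 & tab$x < 1))
    expect_true(all(tab$combined > 0 & tab$combined < 1))
  }
  r25 <- which(tbl5$labels == "(2,5)")
  expect_equal(unname(tbl5$x[r25, ]), c(0.619, 0.541, 0.651628))
})

test_that("corpora round-trip losslessly through every format", {
  for (seed in 1:3) {
    co <- rand_corpus(7, seed)
    for (fmt in c("csv", "json")) {
      path <- tempfile(fileext = paste0(".", fmt))
      write_corpus(co, path, fmt)
      back <- read_corpus(path, fmt)
      expect_equal(as.data.frame(back), as.data.frame(co))
      unlink(path)
    }
    path <- tempfile(fileext = ".txt")
    write_corpus(co, path, "txt_lines")
    expect_identical(read_corpus(path, "txt_lines")$text, co$text)
    unlink(path)
  }
  # unicode punctuation survives the csv round-trip
  path <- tempfile(fileext = ".csv")
  write_corpus(dsm5, path, "csv")
  expect_identical(read_corpus(path)$text, dsm5$text)
  unlink(path)
})

test_that("degenerate corpus inputs are rejected with informative errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("id,text,domain,source", empty)
  expect_error(read_corpus(empty), "EmptyCorpus")
  unlink(empty)
  blank <- tempfile(fileext = ".csv")
  writeLines(c("id,text", "a,hello", "b,   "), blank)
  expect_error(read_corpus(blank), "row")
  unlink(blank)
  expect_error(write_corpus(dsm5[0, ], tempfile()), "empty")
  expect_error(load_bundled("nope"), "dsm5_adhd")
  expect_error(symptom_corpus(c("a", "b"), id = c("x", "x")), "duplicate")
})

test_that("txt_lines reads assign zero-padded ordinal ids", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("one sentence", "two sentence", "three sentence"), path)
  co <- read_corpus(path, "txt_lines")
  expect_identical(co$id, c("000", "001", "002"))
  unlink(path)
})
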