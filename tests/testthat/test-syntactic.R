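test_that("triple extraction recovers the published representative triples", {
  t1 <- extract_triples(dsm5_inatt$text[1])
  has <- function(df, h, r, d) {
    any(df$head == h & df$relation == r & df$dependent == d)
  }
  expect_true(has(t1, "fail", "advmod", "often"))
  expect_true(has(t1, "make", "dobj", "mistake"))
  expect_true(has(t1, "give", "aux", "to"))
  expect_true(has(t1, "attention", "amod", "close"))
  expect_true(has(t1, "fail", "xcomp", "give"))
  t4 <- extract_triples(dsm5_inatt$text[4])
  expect_true(has(t4, "follow", "neg", "not"))
  expect_true(has(t4, "follow", "aux", "do"))
  expect_true(has(t4, "on", "pobj", "instruction"))
  # retained-relation filter: no determiner or punctuation relations, ever
  for (txt in dsm5$text) {
    tr <- extract_triples(txt)
    expect_true(all(tr$relation %in% symsim:::RETAINED_RELATIONS))
    expect_false(any(tr$relation %in% c("det", "punct")))
  }
  expect_equal(nrow(extract_triples("stop")), 0L)
})

test_that("triple similarity averages direct and cross vertex alignments", {
  # same head, orthogonal head/dependent: direct = 1, cross = 0 -> 0.5
  t_ab <- list(head = "qq", dependent = "zz")
  expect_equal(word_similarity("qq", "zz"), 0)
  expect_equal(triple_similarity(t_ab, t_ab), 0.5)
  # four-call oracle on concrete and random triples
  four_call <- function(a, b) {
    direct <- (word_similarity(a$head, b$head) +
                 word_similarity(a$dependent, b$dependent)) / 2
    cross <- (word_similarity(a$head, b$dependent) +
                word_similarity(a$dependent, b$head)) / 2
    (direct + cross) / 2
  }
  ta <- list(head = "fail", dependent = "often")
  tb <- list(head = "follow", dependent = "often")
  expect_equal(triple_similarity(ta, tb), four_call(ta, tb))
  set.seed(5)
  for (k in 1:15) {
    a <- list(head = sample(word_pool, 1), dependent = sample(word_pool, 1))
    b <- list(head = sample(word_pool, 1), dependent = sample(word_pool, 1))
    expect_equal(triple_similarity(a, b), four_call(a, b))
    expect_equal(triple_similarity(a, b), triple_similarity(b, a))
    # invariance under simultaneous head/dependent swap of both triples
    a_sw <- list(head = a$dependent, dependent = a$head)
    b_sw <- list(head = b$dependent, dependent = b$head)
    expect_equal(triple_similarity(a, b), triple_similarity(a_sw, b_sw))
  }
  # identical triple generally scores below 1 (cross terms differ)
  t_run <- list(head = "run", dependent = "often")
  expect_equal(triple_similarity(t_run, t_run),
               (1 + word_similarity("run", "often")) / 2)
})

test_that("syntactic sentence similarity is symmetric and bounded", {
  set.seed(3)
  idx <- cbind(sample(18, 6), sample(18, 6))
  for (k in seq_len(nrow(idx))) {
    a <- dsm5$text[idx[k, 1]]; b <- dsm5$text[idx[k, 2]]
    sab <- suppressWarnings(syntactic_similarity(a, b))
    expect_equal(sab, suppressWarnings(syntactic_similarity(b, a)))
    expect_gte(sab, 0); expect_lte(sab, 1)
  }
  # zero-triple sentence scores 0 with a warning
  expect_warning(z <- syntactic_similarity("stop", dsm5$text[1]),
                 "no dependency triples")
  expect_equal(z, 0)
  # self-similarity equals greedy self-alignment (at most 1)
  s_self <- syntactic_similarity(dsm5$text[2], dsm5$text[2])
  expect_lte(s_self, 1)
  expect_gt(s_self, 0.5)
})
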