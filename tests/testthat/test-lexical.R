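test_that("preprocessing lemmatises with POS guidance", {
  ts <- lexical_preprocess(
    "Often leaves seat in situations when remaining seated is expected")
  expect_true("leave" %in% ts$lemma[ts$coarse_pos == "verb"])
  expect_false("leaf" %in% ts$lemma)
  # hand-tagged oracle for the three inflections of "run"
  ts2 <- lexical_preprocess("Running!! runs, ran.")
  expect_identical(ts2$surface, c("running", "runs", "ran"))
  expect_identical(ts2$coarse_pos, rep("verb", 3))
  expect_identical(ts2$lemma, rep("run", 3))
  # all-stopword and empty input reduce to the empty token sequence
  expect_equal(nrow(lexical_preprocess("the of and")), 0L)
  expect_equal(nrow(lexical_preprocess("")), 0L)
  # invariants: lemmas lowercase alphabetic, no stopwords
  ts3 <- lexical_preprocess(dsm5$text[4])
  expect_true(all(grepl("^[a-z]+$", ts3$lemma)))
  expect_false(any(ts3$surface %in% symsim:::STOPWORDS))
})

test_that("hybrid word similarity follows the path/edit-distance rule", {
  expect_equal(word_similarity("task", "task"), 1.0)
  # out-of-vocabulary fallback: edit distance 1 over max length 10
  expect_equal(word_similarity("attention", "attendtion"), 0.9)
  # max-over-senses path similarity agrees with exhaustive oracle
  for (pair in list(c("organize", "lose"), c("task", "play"),
                    c("run", "climb"), c("seat", "hand"),
                    c("attention", "effort"))) {
    got <- word_similarity(pair[1], pair[2])
    want <- oracle_path_sim(pair[1], pair[2])
    if (!is.na(want) && want >= 0.1) expect_equal(got, want)
  }
  # symmetry over random lemma pairs
  set.seed(42)
  for (k in 1:20) {
    a <- sample(word_pool, 1); b <- sample(word_pool, 1)
    expect_equal(word_similarity(a, b), word_similarity(b, a))
  }
})

test_that("greedy alignment is the greedy rule, not the optimal assignment", {
  expect_equal(greedy_align(diag(4)), 1.0)
  # hand trace: picks 0.9 then is forced into 0.1
  expect_equal(greedy_align(matrix(c(0.9, 0.85, 0.8, 0.1), 2, 2)), 0.5)
  expect_equal(greedy_align(matrix(c(0.2, 0.7, 0.4), 1, 3)), 0.7)
  expect_error(greedy_align(matrix(numeric(), 0, 0)), "empty")
  # equivalence with the sort-and-delete oracle on random matrices
  set.seed(7)
  for (k in 1:40) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    S <- matrix(runif(nr * nc), nr, nc)
    expect_equal(greedy_align(S), oracle_greedy(S))
  }
})

test_that("lexical similarity is symmetric, bounded and length-penalised", {
  expect_equal(lexical_similarity(dsm5$text[3], dsm5$text[3])$final, 1.0)
  set.seed(11)
  for (k in 1:10) {
    a <- rand_sentence(sample(3:7, 1)); b <- rand_sentence(sample(3:7, 1))
    sa <- lexical_similarity(a, b); sb <- lexical_similarity(b, a)
    expect_equal(sa$final, sb$final)
    expect_gte(sa$final, 0); expect_lte(sa$final, sa$word_sim)
    expect_lte(sa$word_sim, 1)
    expect_equal(sa$penalty,
                 abs(sa$len_a - sa$len_b) * sa$word_sim /
                   max(sa$len_a, sa$len_b))
    if (sa$len_a == sa$len_b) expect_equal(sa$penalty, 0)
  }
  # lengths 4 vs 2 halve the aligned score
  s <- lexical_similarity("child teacher seat motor", "task play")
  expect_equal(s$len_a, 4L); expect_equal(s$len_b, 2L)
  expect_equal(s$final, s$word_sim / 2)
  # empty side yields 0 with a warning
  expect_warning(z <- lexical_similarity("the of and", "task play"),
                 "zero content")
  expect_equal(z$final, 0)
  expect_true(z$empty)
})

test_that("inattention pair (2,5) scores near the published lexical value", {
  s <- lexical_similarity(dsm5_inatt$text[2], dsm5_inatt$text[5])
  expect_equal(s$final, 0.619, tolerance = 0.05)
})
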