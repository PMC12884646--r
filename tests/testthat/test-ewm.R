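test_that("entropy weights reproduce the published layer weights", {
  w5 <- entropy_weights(tbl5)
  expect_equal(unname(round(w5$w, 2)), c(0.35, 0.16, 0.49))
  w6 <- entropy_weights(tbl6)
  expect_equal(unname(round(w6$w, 2)), c(0.21, 0.04, 0.75))
  expect_equal(sum(w5$w), 1, tolerance = 1e-9)
  expect_true(all(w5$H >= 0 & w5$H <= 1 + 1e-9))
})

test_that("combined scores reproduce the published redundant-pair values", {
  c5 <- combined_scores(tbl5, entropy_weights(tbl5))
  expect_equal(round(unname(c5["(2,5)"]), 2), 0.62)
  expect_equal(round(unname(c5["(5,7)"]), 2), 0.58)
  c6 <- combined_scores(tbl6, entropy_weights(tbl6))
  expect_equal(round(unname(c6["(1,2)"]), 2), 0.49)
  # recomputed combined column matches the published one throughout
  expect_equal(unname(c5), tbl5$combined, tolerance = 2e-6)
  expect_equal(unname(c6), tbl6$combined, tolerance = 2e-6)
})

test_that("degenerate weighting behaves as forced by the formulas", {
  # uniform column carries no information: H = 1, weight 0
  x <- cbind(rep(0.5, 10), seq(0.05, 0.95, .1))
  tab <- layer_score_table(cbind(1:10, 2:11), x)
  w <- entropy_weights(tab)
  expect_equal(unname(w$H[1]), 1, tolerance = 1e-12)
  expect_equal(unname(w$w[1]), 0, tolerance = 1e-12)
  # unit weight on one layer reproduces that column exactly
  expect_equal(unname(combined_scores(tbl5, c(1, 0, 0))),
               unname(tbl5$x[, "lexical"]))
  # hand arithmetic on a toy row
  toy <- layer_score_table(matrix(c(1, 2, 2, 3), 2),
                           rbind(c(0.2, 0.4, 0.6), c(0.1, 0.1, 0.1)))
  expect_equal(unname(combined_scores(toy, rep(1 / 3, 3))[1]), 0.4)
  expect_error(entropy_weights(layer_score_table(matrix(c(1, 2), 1),
                                                 rbind(c(.1, .2, .3)))),
               "m >= 2")
})

test_that("EWM matches a high-precision independent oracle on random tables", {
  set.seed(99)
  for (k in 1:10) {
    m <- sample(5:40, 1)
    X <- matrix(runif(m * 3, 0.01, 0.99), m, 3)
    tab <- layer_score_table(cbind(seq_len(m), seq_len(m) + m), X)
    got <- entropy_weights(tab)
    want <- oracle_ewm(X)
    expect_equal(unname(got$H), want$H, tolerance = 1e-12)
    expect_equal(unname(got$w), want$w, tolerance = 1e-12)
    # convex-combination bounds on combined scores
    comb <- combined_scores(tab, got)
    expect_true(all(comb >= apply(X, 1, min) - 1e-12))
    expect_true(all(comb <= apply(X, 1, max) + 1e-12))
    # scaling one column leaves its normalised distribution, hence the
    # weights, unchanged
    X2 <- X; X2[, 2] <- X2[, 2] * 7
    tab2 <- layer_score_table(tab$pairs, X2)
    expect_equal(entropy_weights(tab2)$w, got$w, tolerance = 1e-12)
  }
})

test_that("percentile cutoffs reproduce the published thresholds", {
  c5 <- combined_scores(tbl5, entropy_weights(tbl5))
  thr <- percentile_cutoff(c5, 99, 0.03)
  expect_equal(round(thr$cutoff, 2), 0.61)
  expect_setequal(thr$selected, c("(2,5)", "(5,7)"))
  sem5 <- setNames(tbl5$x[, "semantic"], tbl5$labels)
  thr_sem <- percentile_cutoff(sem5, 99, 0.03)
  expect_equal(round(thr_sem$cutoff, 2), 0.65)
  expect_setequal(thr_sem$selected, c("(2,5)", "(4,5)", "(1,4)", "(5,7)"))
  sem6 <- setNames(tbl6$x[, "semantic"], tbl6$labels)
  expect_equal(round(percentile_cutoff(sem6, 99, 0.03)$cutoff, 2), 0.47)
  c6 <- combined_scores(tbl6, entropy_weights(tbl6))
  thr6 <- percentile_cutoff(c6, 99, 0.03)
  # the hyperactivity combined-column percentile lands at 0.46 (the
  # published 0.47 matches the semantic column); selection is unaffected
  expect_equal(round(thr6$cutoff, 2), 0.46)
  expect_identical(thr6$selected, "(1,2)")
})

test_that("threshold selection handles edge cases", {
  const <- rep(0.4, 8)
  thr <- percentile_cutoff(const, 99, 0.03)
  expect_equal(thr$cutoff, 0.4)
  expect_length(thr$selected, 8)
  expect_error(percentile_cutoff(c(1, 2), 0), "percentile")
  expect_error(percentile_cutoff(c(1, 2), 100), "percentile")
  expect_error(percentile_cutoff(0.5), "two scores")
})

test_that("redundancy() wraps weights, fusion and thresholding coherently", {
  r <- redundancy(tbl5)
  expect_s3_class(r, "redundancy")
  expect_equal(coef(r), entropy_weights(tbl5)$w)
  expect_setequal(r$threshold$selected, c("(2,5)", "(5,7)"))
  s <- summary(r)
  expect_equal(s$pair[1], "(2,5)") # ranked by combined score
  expect_true(all(s$selected[1:2]))
})
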