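test_that("Wilcoxon signed-rank reproduces the published layer comparisons", {
  w <- wilcoxon_paired(tbl5$x[, "semantic"], tbl5$x[, "lexical"])
  expect_equal(w$statistic, 141.0)
  expect_lt(w$p_value, 0.01)
  expect_equal(wilcoxon_paired(tbl5$x[, "semantic"],
                               tbl5$x[, "syntactic"])$statistic, 79.0)
  expect_equal(wilcoxon_paired(tbl6$x[, "semantic"],
                               tbl6$x[, "lexical"])$statistic, 88.0)
  expect_equal(wilcoxon_paired(tbl6$x[, "semantic"],
                               tbl6$x[, "syntactic"])$statistic, 86.0)
})

test_that("Wilcoxon handles degenerate and small samples exactly", {
  x <- runif(10)
  expect_error(wilcoxon_paired(x, x), "degenerate")
  expect_error(wilcoxon_paired(1:3, 3:1), "at least 5")
  # n = 6 toy: negative ranks 2 + 4 = 6
  d <- c(1, -2, 3, -4, 5, 6)
  w <- wilcoxon_paired(d + 10, rep(10, 6))
  expect_equal(w$statistic, 6)
  orc <- oracle_signrank(d)
  expect_equal(w$statistic, orc$statistic)
  expect_equal(w$p_value, orc$p)
  # agreement with full enumeration for random tie-free samples, n <= 8
  set.seed(31)
  for (k in 1:10) {
    n <- sample(5:8, 1)
    d <- round(runif(n, 0.1, 2), 6) * sample(c(-1, 1), n, TRUE)
    if (anyDuplicated(abs(d))) next
    w <- wilcoxon_paired(d, rep(0, n))
    orc <- oracle_signrank(d)
    expect_equal(w$statistic, orc$statistic)
    expect_equal(w$p_value, orc$p)
  }
})

test_that("mutual information is near zero under independence, grows with dependence", {
  set.seed(17)
  x <- runif(200); y <- runif(200)
  expect_lte(mutual_info(x, y, seed = 1), 0.05)
  # self-dependence on the 36 published semantic scores
  s <- tbl5$x[, "semantic"]
  expect_gt(mutual_info(s, s, seed = 1), 0.5)
  # monotone under increasing linear dependence
  noise <- rnorm(200)
  mi_weak <- mutual_info(x, 0.3 * x + noise, seed = 2)
  mi_strong <- mutual_info(x, 3 * x + 0.1 * noise, seed = 2)
  expect_gt(mi_strong, mi_weak)
  expect_equal(mutual_info(rep(1, 50), runif(50)), 0)
  expect_gte(mutual_info(x, y, seed = 3), 0)
})

test_that("layer validation mirrors the published qualitative pattern", {
  rep6 <- validate_layers(tbl6, seed = 1)
  # syntactic vs semantic dependence is (near) zero in hyperactivity
  expect_lte(rep6$mutual_info[rep6$comparison == "semantic vs syntactic"],
             0.1)
  expect_true(all(rep6$p_value < 0.05))
})

test_that("chi-square imbalance check matches its closed form", {
  cs <- chi_square_balance(18, 32)
  expect_equal(cs$statistic, 3.920)
  expect_equal(cs$p, 0.048, tolerance = 0.01)
  expect_equal(chi_square_balance(25, 25)$statistic, 0)
  expect_equal(chi_square_balance(25, 25)$p, 1)
  expect_equal(chi_square_balance(10, 30)$statistic, 10.0)
  expect_error(chi_square_balance(0, 0), "zero")
  # (a - b)^2 / (a + b) equals the general goodness-of-fit form, and both
  # agree with the stock implementation
  set.seed(4)
  for (k in 1:10) {
    a <- sample(1:100, 1); b <- sample(1:100, 1)
    got <- chi_square_balance(a, b)
    expect_equal(got$statistic, (a - b)^2 / (a + b))
    ref <- suppressWarnings(chisq.test(c(a, b), p = c(0.5, 0.5)))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
})
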