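backend <- stub_backend(7)

test_that("overlap exclusion flags near-duplicates and is monotone", {
  train <- symptom_corpus(c("often loses things necessary for tasks",
                            "often talks excessively in class"),
                          id = c("tr1", "tr2"))
  test <- symptom_corpus(c("often loses things necessary for tasks",
                           "completely unrelated gardening sentence"),
                         id = c("te1", "te2"))
  rep <- overlap_exclude(train, test, backend, 0.90)
  expect_identical(rep$excluded_ids, "te1")
  expect_identical(rep$retained$id, "te2")
  expect_true(all(rep$flagged_pairs$cosine >= 0.90))
  expect_error(overlap_exclude(train, test, backend, 1.5), "cutoff")
  # constructed fixture: exactly 3 of 10 items are verbatim copies
  base <- rand_corpus(10, 77)
  test10 <- base
  test10$text[4:10] <- paste("novel wording number", 4:10, "with zz vocab")
  rep2 <- overlap_exclude(base, test10, backend, 0.90)
  expect_setequal(rep2$excluded_ids, base$id[1:3])
  # lowering the cutoff never retains more items
  retained_at <- function(cut) nrow(overlap_exclude(base, test10, backend,
                                                    cut)$retained)
  cuts <- c(0.95, 0.8, 0.6, 0.4)
  expect_true(all(diff(vapply(cuts, retained_at, 0)) <= 0))
})

test_that("bootstrap accuracies are deterministic and degenerate at 1 for a perfect model", {
  co <- rand_corpus(20, 9)
  co$domain <- sample(c("inattention", "hyperactivity_impulsivity"), 20, TRUE)
  truth <- as.integer(co$domain == "hyperactivity_impulsivity")
  perfect <- function(corpus) as.integer(corpus$domain ==
                                           "hyperactivity_impulsivity")
  acc <- bootstrap_accuracy(perfect, co, B = 30, seed = 5)
  expect_length(acc, 30)
  expect_true(all(acc == 1))
  noisy <- function(corpus) rep(0L, nrow(corpus))
  a1 <- bootstrap_accuracy(noisy, co, B = 30, seed = 5)
  a2 <- bootstrap_accuracy(noisy, co, B = 30, seed = 5)
  expect_identical(a1, a2)
  expect_error(bootstrap_accuracy(perfect, co, B = 1), "B >= 2")
  un <- co; un$domain <- "unknown"
  expect_error(bootstrap_accuracy(perfect, un), "unlabelled")
})

test_that("paired t comparison matches closed-form arithmetic", {
  a <- c(0.9, 0.85, 0.95, 0.8, 0.9)
  b <- c(0.85, 0.8, 0.9, 0.85, 0.8)
  cmp <- paired_t_compare(a, b)
  d <- a - b
  se <- sd(d) / sqrt(5)
  expect_equal(cmp$mean_diff, mean(d))
  expect_equal(cmp$t, mean(d) / se)
  expect_equal(cmp$ci95,
               mean(d) + c(-1, 1) * qt(0.975, 4) * se)
  expect_equal(cmp$p, 2 * pt(-abs(mean(d) / se), 4))
  # elementwise-identical distributions are flagged degenerate
  dg <- paired_t_compare(a, a)
  expect_true(dg$degenerate)
  expect_equal(dg$mean_diff, 0)
  expect_equal(dg$ci95, c(0, 0))
  # permuting iterations identically in both conditions leaves t unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(paired_t_compare(a[perm], b[perm])$t, cmp$t)
})

test_that("bootstrap intervals cover a simulated true accuracy", {
  p_true <- 0.8; n <- 50; B <- 30
  cover <- 0
  for (r in 1:200) {
    set.seed(3000 + r)
    correct <- rbinom(n, 1, p_true)
    co <- symptom_corpus(sprintf("item %d run %d", 1:n, r),
                         domain = "inattention")
    truth <- rep(0L, n)
    # bootstrap over items: realised prediction correctness is resampled
    acc <- bootstrap_accuracy(function(cp) ifelse(correct == 1, 0L, 1L),
                              co, truth = truth, B = B, seed = r)
    ci <- mean(acc) + c(-1, 1) * qt(0.975, B - 1) * sd(acc)
    if (p_true >= ci[1] && p_true <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.85)
})
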