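backend <- stub_backend(7)

test_that("the synthetic questionnaire generator is deterministic and labelled", {
  sp <- synthetic_spec(5, 10, seed = 7)
  q1 <- generate_questionnaire(sp, dsm5)
  q2 <- generate_questionnaire(sp, dsm5)
  expect_identical(q1, q2)
  expect_equal(nrow(q1), 20L)
  expect_equal(sum(q1$domain == "non_adhd"), 10L)
  expect_equal(sum(q1$domain == "inattention"), 5L)
  # paraphrases inherit the source item's domain label
  para <- q1[!is.na(q1$source_item), ]
  src_dom <- dsm5$domain[match(para$source_item, dsm5$id)]
  expect_identical(para$domain, src_dom)
  expect_error(synthetic_spec(0, 0), "zero items")
})

test_that("verbatim copies are caught by the leakage screen", {
  sp <- synthetic_spec(4, 0, ops = "verbatim_copy", seed = 3)
  q <- generate_questionnaire(sp, dsm5)
  rep <- overlap_exclude(dsm5, q, backend, 0.90)
  expect_equal(nrow(rep$retained), 0L)
  expect_true(all(rep$flagged_pairs$cosine >= 1 - 1e-12))
})

test_that("the full pipeline separates mild paraphrases from distractors", {
  # separable-by-construction property: synonym-swap paraphrases stay close
  # to their source statements under the hashed bag-of-tokens backend
  train_non <- generate_questionnaire(synthetic_spec(0, 16, seed = 101), dsm5)
  fit <- screen_fit(dsm5, train_non, backend)
  test <- generate_questionnaire(
    synthetic_spec(6, 10, ops = "synonym_swap", seed = 202), dsm5)
  pr <- predict(fit, test)
  truth_adhd <- as.integer(test$domain != "non_adhd")
  filter_acc <- mean(as.integer(pr$passed) == truth_adhd)
  expect_gte(filter_acc, 0.9)
  keep <- pr$passed & test$domain != "non_adhd"
  subtype_truth <- as.integer(test$domain[keep] == "hyperactivity_impulsivity")
  expect_gte(mean(pr$subtype[keep] == subtype_truth), 0.9)
})
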