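test_that("cosine matrices are symmetric, unit-diagonal and exact", {
  b <- stub_backend(3)
  co <- rand_corpus(8, 21)
  M <- cosine_pairwise(b, co)
  expect_equal(unname(diag(M)), rep(1, 8))
  expect_equal(M, t(M))
  expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  # independent normalised-dot-product oracle
  E <- embed_texts(b, co$text)
  want <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    want[i, j] <- sum(E[i, ] * E[j, ]) /
      sqrt(sum(E[i, ]^2) * sum(E[j, ]^2))
  }
  expect_equal(unclass(M), want, ignore_attr = TRUE, tolerance = 1e-12)
  # duplicate texts embed identically
  co2 <- symptom_corpus(c("same text here", "same text here", "other words"))
  M2 <- cosine_pairwise(b, co2)
  expect_equal(M2[1, 2], 1.0)
})

test_that("stub backend is deterministic and nearly orthogonal on random text", {
  b1 <- stub_backend(9); b2 <- stub_backend(9)
  txts <- c("alpha beta", "gamma delta epsilon")
  expect_identical(embed_texts(b1, txts), embed_texts(b2, txts))
  expect_equal(unname(sqrt(rowSums(embed_texts(b1, txts)^2))), c(1, 1))
  expect_equal(ncol(embed_texts(b1, "x")), 768L)
  set.seed(123)
  rand_txt <- replicate(60, paste(sample(letters, 8, TRUE), collapse = ""))
  E <- embed_texts(b1, rand_txt)
  C <- tcrossprod(E / sqrt(rowSums(E^2)))
  offdiag <- abs(C[upper.tri(C)])
  expect_gte(mean(offdiag < 0.2), 0.95)
})

test_that("backend comparison uses upper-triangle Spearman correlation", {
  b <- stub_backend(1)
  co <- rand_corpus(6, 5)
  M <- cosine_pairwise(b, co)
  self <- compare_backends(M, M)
  expect_equal(self$rho, 1.0)
  # anti-ranked toy matrices over 6 upper-triangle pairs
  mk <- function(vals) {
    M <- diag(4); M[upper.tri(M)] <- vals
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(letters[1:4], letters[1:4])
    structure(M, class = c("similarity_matrix", "matrix"))
  }
  A <- mk(c(.1, .2, .3, .4, .5, .6)); B <- mk(c(.6, .5, .4, .3, .2, .1))
  expect_equal(compare_backends(A, B)$rho, -1.0)
  bad <- M; dimnames(bad) <- list(rev(co$id), rev(co$id))
  expect_error(compare_backends(M, bad), "mismatch")
})

test_that("zero-norm embeddings are rejected by name", {
  zb <- embedding_backend("zero", 4, function(texts) {
    matrix(0, length(texts), 4)
  })
  co <- symptom_corpus("some text", id = "bad_item")
  expect_error(cosine_pairwise(zb, co), "bad_item")
})
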