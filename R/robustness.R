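# Robustness machinery: embedding-overlap leakage exclusion, bootstrap
# accuracy distributions and paired-t comparisons between conditions.

#' Exclude test items that nearly duplicate training language
#'
#' Computes cosine similarity between every training and test item in
#' embedding space and excludes a test item when ANY training item reaches
#' the cutoff (default 0.90, a conservative near-duplicate/paraphrase
#' threshold). The training corpus is never modified.
#'
#' @param train,test corpora.
#' @param backend an \code{embedding_backend}.
#' @param cutoff cosine threshold in (0, 1].
#' @return object of class \code{overlap_report}: list with
#'   \code{flagged_pairs} (train id, test id, cosine), \code{excluded_ids},
#'   \code{retained} (corpus), \code{cutoff}.
#' @export
overlap_exclude <- function(train, test, backend, cutoff = 0.90) {
  if (NROW(train) == 0L || NROW(test) == 0L) {
    stop("empty corpus", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]",
                                      call. = FALSE)
  Et <- embed_texts(backend, train$text)
  Ex <- embed_texts(backend, test$text)
  Et <- Et / sqrt(rowSums(Et^2)); Ex <- Ex / sqrt(rowSums(Ex^2))
  C <- Et %*% t(Ex)
  hits <- which(C >= cutoff, arr.ind = TRUE)
  flagged <- data.frame(train_id = train$id[hits[, 1]],
                        test_id = test$id[hits[, 2]],
                        cosine = C[hits], stringsAsFactors = FALSE)
  excluded <- unique(flagged$test_id)
  retained <- test[!test$id %in% excluded, , drop = FALSE]
  class(retained) <- c("symptom_corpus", "data.frame")
  rownames(retained) <- NULL
  structure(list(flagged_pairs = flagged, excluded_ids = excluded,
                 retained = retained, cutoff = cutoff),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  total <- length(x$excluded_ids) + NROW(x$retained)
  cat(sprintf("Overlap exclusion at cosine >= %.2f: %d of %d test items excluded (%.0f%%)\n",
              x$cutoff, length(x$excluded_ids), total,
              100 * length(x$excluded_ids) / total))
  invisible(x)
}

#' Bootstrap accuracy distribution of a fitted predictor
#'
#' Resamples the labelled test items with replacement (same size) B times
#' and recomputes accuracy on each resample; the model is not refit.
#' Iteration i draws under seed \code{seed + i}, so two conditions
#' evaluated with the same seed share resampling draws and are paired by
#' iteration.
#'
#' @param predict_fun function(corpus) -> integer labels 0/1, already
#'   fitted.
#' @param corpus labelled corpus (domain labels other than
#'   \code{"unknown"}).
#' @param truth integer 0/1 truth per item; derived from the domain column
#'   (1 = hyperactivity_impulsivity) when NULL.
#' @param B number of bootstrap iterations (default 30).
#' @param seed base seed.
#' @return numeric vector of B accuracies.
#' @export
bootstrap_accuracy <- function(predict_fun, corpus, truth = NULL, B = 30L,
                               seed = 1L) {
  if (B < 2L) stop("need B >= 2", call. = FALSE)
  if (is.null(truth)) {
    if (all(corpus$domain == "unknown")) stop("corpus is unlabelled",
                                              call. = FALSE)
    truth <- as.integer(corpus$domain == "hyperactivity_impulsivity")
  }
  pred <- as.integer(predict_fun(corpus))
  n <- NROW(corpus)
  vapply(seq_len(B), function(i) {
    idx <- with_seed(seed + i, sample.int(n, n, replace = TRUE))
    mean(pred[idx] == truth[idx])
  }, 0)
}

#' Paired t comparison of two bootstrap accuracy distributions
#'
#' Two-sided paired t-test on per-iteration accuracy differences, with the
#' 95% confidence interval \code{mean_diff +/- t_{0.975, B-1} * SE}. When
#' the differences have zero variance the t statistic is undefined and
#' reported as NA with the mean difference only.
#'
#' @param acc_a,acc_b equal-length accuracy vectors (paired by iteration).
#' @return object of class \code{bootstrap_comparison}: list with
#'   \code{acc_a}, \code{acc_b}, \code{mean_diff}, \code{ci95}, \code{t},
#'   \code{p}, \code{degenerate}.
#' @export
paired_t_compare <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("unequal lengths", call. = FALSE)
  if (length(acc_a) < 2L) stop("need >= 2 paired iterations", call. = FALSE)
  d <- acc_a - acc_b
  md <- mean(d)
  if (stats::sd(d) == 0) {
    return(structure(list(acc_a = acc_a, acc_b = acc_b, mean_diff = md,
                          ci95 = c(md, md), t = NA_real_, p = NA_real_,
                          degenerate = TRUE),
                     class = "bootstrap_comparison"))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  structure(list(acc_a = acc_a, acc_b = acc_b, mean_diff = md,
                 ci95 = as.vector(tt$conf.int), t = unname(tt$statistic),
                 p = tt$p.value, degenerate = FALSE),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Paired comparison degenerate (zero-variance differences); mean diff %.4f\n",
                x$mean_diff))
  } else {
    cat(sprintf("Paired t: diff %.4f, 95%% CI [%.4f, %.4f], t = %.3f, p = %.3f\n",
                x$mean_diff, x$ci95[1], x$ci95[2], x$t, x$p))
  }
  invisible(x)
}
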