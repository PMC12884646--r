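# Two-stage screening pipeline: an embedding-based filter separating
# ADHD-consistent from non-ADHD symptom language, three-dimensional
# similarity-difference features, and subtype classifiers assigning
# retained items to the inattention (class 0) or hyperactivity/impulsivity
# (class 1) domain.

#' Pipeline configuration
#'
#' Bundles every tunable of the screening pipeline with its reference
#' default: filter iteration cap 1000, 100 forest trees with random state
#' 42, overlap-exclusion cosine cutoff 0.90, 30 bootstrap iterations,
#' 768-dimensional embeddings, hybrid word-similarity fallback threshold
#' 0.1, entropy zero replacement 1e-10, selection percentile 99 with
#' relaxation 0.03.
#'
#' @param ... overrides for individual keys.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(filter_max_iter = 1000L, forest_trees = 100L,
              forest_seed = 42L, overlap_cutoff = 0.90,
              bootstrap_iters = 30L, embed_dim = 768L, min_path_sim = 0.1,
              zero_eps = 1e-10, percentile = 99, relaxation = 0.03,
              adasyn_k = 5L, global_seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Similarity-difference feature vector for one sentence
#'
#' For each similarity layer L (lexical, syntactic, semantic) the feature is
#' the mean similarity of the item to all inattention exemplars minus its
#' mean similarity to all hyperactivity/impulsivity exemplars, giving a
#' three-dimensional vector whose sign leans positive for
#' inattention-like items. If the item text occurs verbatim among the
#' exemplars that self-pair is excluded from the mean.
#'
#' @param item a sentence.
#' @param inatt,hyper exemplar corpora for the two domains (non-empty).
#' @param backend an \code{embedding_backend}.
#' @param min_path_sim hybrid word-similarity fallback threshold.
#' @return named numeric vector \code{c(d_lex, d_syn, d_sem)}.
#' @export
extract_features <- function(item, inatt, hyper, backend,
                             min_path_sim = 0.1) {
  if (NROW(inatt) == 0L || NROW(hyper) == 0L) {
    stop("exemplar corpus empty", call. = FALSE)
  }
  layer_means <- function(exemplars) {
    keep <- exemplars$text != item
    if (!any(keep)) keep <- rep(TRUE, length(keep)) # item IS the whole corpus
    texts <- exemplars$text[keep]
    lex <- vapply(texts, function(t)
      suppressWarnings(lexical_similarity(item, t,
                                          min_path_sim = min_path_sim)$final),
      0)
    syn <- vapply(texts, function(t)
      suppressWarnings(syntactic_similarity(item, t,
                                            min_path_sim = min_path_sim)), 0)
    ei <- embed_texts(backend, item)
    ee <- embed_texts(backend, texts)
    sem <- as.vector((ee %*% t(ei)) /
                       (sqrt(rowSums(ee^2)) * sqrt(sum(ei^2))))
    c(lex = mean(lex), syn = mean(syn), sem = mean(sem))
  }
  mi <- layer_means(inatt); mh <- layer_means(hyper)
  stats::setNames(mi - mh, c("d_lex", "d_syn", "d_sem"))
}

feature_matrix <- function(corpus, inatt, hyper, backend,
                           min_path_sim = 0.1) {
  t(vapply(corpus$text, extract_features, numeric(3),
           inatt = inatt, hyper = hyper, backend = backend,
           min_path_sim = min_path_sim, USE.NAMES = FALSE))
}

# Adaptive synthetic oversampling (ADASYN): synthesises minority-class
# points by interpolating towards minority neighbours, with per-point
# budgets proportional to the share of majority points among each minority
# point's k nearest neighbours (the "difficulty" of its region).
adasyn_balance <- function(X, y, k = 5L, seed = 1L) {
  stopifnot(length(unique(y)) == 2L)
  tab <- table(y)
  if (min(tab) < 2L) stop("oversampling needs >= 2 items per class",
                          call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  g <- max(tab) - min(tab)
  if (g == 0L) return(list(X = X, y = y))
  idx_min <- which(y == minority)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  k_eff <- min(k, nrow(X) - 1L)
  r <- vapply(idx_min, function(i) {
    nn <- order(D[i, ])[seq_len(k_eff)]
    mean(y[nn] != minority)
  }, 0)
  r <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  counts <- floor(r * g)
  # distribute the remainder to the most difficult regions
  rem <- g - sum(counts)
  if (rem > 0) {
    ord <- order(r, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  with_seed(seed, {
    synth <- list()
    for (ii in seq_along(idx_min)) {
      i <- idx_min[ii]
      if (counts[ii] == 0L) next
      nn_min <- idx_min[idx_min != i]
      nn_min <- nn_min[order(D[i, nn_min])][seq_len(min(k_eff, length(nn_min)))]
      for (s in seq_len(counts[ii])) {
        z <- nn_min[sample.int(length(nn_min), 1L)]
        lambda <- stats::runif(1)
        synth[[length(synth) + 1L]] <- X[i, ] + lambda * (X[z, ] - X[i, ])
      }
    }
    Xs <- do.call(rbind, synth)
    list(X = rbind(X, Xs), y = c(y, rep(minority, nrow(Xs))))
  })
}

ridge_logistic <- function(X, y01, maxit = 1000L) {
  # L2-regularised logistic fit (single small lambda), the convention of
  # default-regularised linear log-odds classifiers
  glmnet::glmnet(X, factor(y01), family = "binomial", alpha = 0,
                 lambda = 1 / length(y01), standardize = FALSE,
                 maxit = maxit)
}

#' Train the ADHD/non-ADHD filtering layer
#'
#' Embeds all training statements, balances the classes with adaptive
#' synthetic oversampling (ADASYN, k nearest neighbours in embedding
#' space, seeded), and fits an L2-regularised linear log-odds classifier
#' with the configured iteration cap. The ADHD class is positive.
#'
#' @param adhd corpus of ADHD symptom statements (positive class).
#' @param non_adhd corpus of non-ADHD diagnostic statements (negative
#'   class).
#' @param backend an \code{embedding_backend}.
#' @param cfg a [pipeline_config()].
#' @return object of class \code{filter_model}.
#' @export
train_filter <- function(adhd, non_adhd, backend, cfg = pipeline_config()) {
  if (NROW(adhd) < 2L || NROW(non_adhd) < 2L) {
    stop("each class needs >= 2 items (oversampling undefined)",
         call. = FALSE)
  }
  X <- rbind(embed_texts(backend, adhd$text),
             embed_texts(backend, non_adhd$text))
  y <- c(rep("adhd", NROW(adhd)), rep("non_adhd", NROW(non_adhd)))
  bal <- adasyn_balance(X, y, k = cfg$adasyn_k, seed = cfg$global_seed)
  y01 <- as.integer(bal$y == "adhd")
  fit <- ridge_logistic(bal$X, y01, maxit = cfg$filter_max_iter)
  structure(list(fit = fit, backend_name = backend$name,
                 resampled_counts = table(bal$y), cfg = cfg),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat("ADHD filter (ridge logistic on", ncol(x$fit$beta), "dims)\n")
  cat("Post-resampling class counts:",
      paste(names(x$resampled_counts), x$resampled_counts, collapse = ", "),
      "\n")
  invisible(x)
}

filter_prob <- function(model, backend, corpus) {
  E <- embed_texts(backend, corpus$text)
  as.vector(stats::predict(model$fit, E, type = "response"))
}

#' Apply the filtering layer to a corpus
#'
#' Partitions the corpus (order-preserving) into items classified as
#' ADHD-consistent and items rejected as non-ADHD language. When the
#' corpus carries informative domain labels (anything but
#' \code{"unknown"}) a [evaluate()] report against those labels is
#' attached.
#'
#' @param model a \code{filter_model}.
#' @param backend the \code{embedding_backend} the model was trained with.
#' @param corpus corpus to screen.
#' @return list with \code{passed}, \code{rejected} (both corpora),
#'   \code{prob} and \code{report} (NULL without labels).
#' @export
apply_filter <- function(model, backend, corpus) {
  if (!identical(model$backend_name, backend$name)) {
    stop("filter was trained with backend '", model$backend_name,
         "', got '", backend$name, "'", call. = FALSE)
  }
  if (NROW(corpus) == 0L) {
    return(list(passed = corpus, rejected = corpus, prob = numeric(),
                report = NULL))
  }
  p <- filter_prob(model, backend, corpus)
  pass <- p >= 0.5
  keep_class <- function(df) {
    class(df) <- c("symptom_corpus", "data.frame"); rownames(df) <- NULL; df
  }
  report <- NULL
  if (any(corpus$domain != "unknown")) {
    truth <- as.integer(corpus$domain %in%
                          c("inattention", "hyperactivity_impulsivity"))
    report <- evaluate(as.integer(pass), p, truth)
  }
  list(passed = keep_class(corpus[pass, , drop = FALSE]),
       rejected = keep_class(corpus[!pass, , drop = FALSE]),
       prob = p, report = report)
}

#' Train a subtype classifier on similarity-difference features
#'
#' Labels are 0 = inattention, 1 = hyperactivity/impulsivity. Available
#' kinds: \code{"forest"} (100 trees, random state 42),
#' \code{"rbf_margin"} (radial-basis-kernel maximum-margin classifier with
#' probability outputs) and \code{"linear_logodds"} (default-configured
#' L2 linear log-odds). No hyper-parameter search is performed.
#'
#' @param kind classifier kind.
#' @param X feature matrix (columns d_lex, d_syn, d_sem).
#' @param y integer labels 0/1, both classes present.
#' @param cfg a [pipeline_config()].
#' @return object of class \code{subtype_model}.
#' @export
train_subtype <- function(kind = c("forest", "rbf_margin", "linear_logodds"),
                          X, y, cfg = pipeline_config()) {
  kind <- match.arg(kind)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class labels", call. = FALSE)
  if (min(table(y)) < 2L) stop("need >= 2 items per class", call. = FALSE)
  X <- as.matrix(X)
  fit <- switch(kind,
    forest = with_seed(cfg$forest_seed,
      randomForest::randomForest(x = X, y = factor(y, levels = 0:1),
                                 ntree = cfg$forest_trees)),
    rbf_margin = with_seed(cfg$global_seed,
      e1071::svm(x = X, y = factor(y, levels = 0:1), kernel = "radial",
                 probability = TRUE)),
    linear_logodds = ridge_logistic(X, y, maxit = cfg$filter_max_iter))
  structure(list(kind = kind, fit = fit, cfg = cfg), class = "subtype_model")
}

#' Predict subtype labels and class-1 probabilities
#'
#' @param object a \code{subtype_model}.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return data frame with \code{pred} (0/1) and \code{prob} (probability
#'   of class 1, hyperactivity/impulsivity).
#' @export
predict.subtype_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  prob <- switch(object$kind,
    forest = stats::predict(object$fit, X, type = "prob")[, "1"],
    rbf_margin = {
      pr <- stats::predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    linear_logodds = as.vector(stats::predict(object$fit, X,
                                              type = "response")))
  data.frame(pred = as.integer(prob >= 0.5), prob = unname(prob))
}

#' Classification metrics with class 1 positive
#'
#' Computes the 2x2 confusion matrix and accuracy, precision, recall, F1,
#' specificity, the rank-statistic AUC over the supplied scores, and a
#' per-class precision/recall/F1 table. AUC is reported as \code{NA} when
#' the truth contains a single class.
#'
#' @param pred predicted labels 0/1.
#' @param prob scores for class 1 (used for AUC; may be NULL).
#' @param truth true labels 0/1.
#' @return object of class \code{classification_report}.
#' @export
evaluate <- function(pred, prob, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(tp, tp + fp); recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  auc <- NA_real_
  if (!is.null(prob) && length(unique(truth)) == 2L) {
    r <- rank(prob)
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  per_class <- data.frame(
    class = c(0L, 1L),
    precision = c(div(tn, tn + fn), precision),
    recall = c(div(tn, tn + fp), recall),
    f1 = c({p0 <- div(tn, tn + fn); r0 <- div(tn, tn + fp)
            if (is.na(p0) || is.na(r0) || p0 + r0 == 0) NA_real_
            else 2 * p0 * r0 / (p0 + r0)}, f1))
  structure(list(accuracy = (tp + tn) / length(truth), precision = precision,
                 recall = recall, f1 = f1,
                 specificity = div(tn, tn + fp), auc = auc,
                 confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                                    dimnames = list(pred = c("0", "1"),
                                                    truth = c("0", "1"))),
                 per_class = per_class),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | spec %.3f | AUC %s\n",
    x$accuracy, x$precision, x$recall, x$f1, x$specificity,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(x$confusion)
  invisible(x)
}

#' Fit the complete two-stage screening pipeline
#'
#' Trains the ADHD/non-ADHD filter on the two training corpora and a
#' subtype classifier on the similarity-difference features of the ADHD
#' exemplars (their own domain labels supply the 0/1 targets). The fitted
#' object predicts on new corpora by filtering first and classifying the
#' retained items.
#'
#' @param train_adhd ADHD exemplar corpus with domain labels
#'   \code{inattention} / \code{hyperactivity_impulsivity}.
#' @param train_non_adhd non-ADHD statement corpus.
#' @param backend an \code{embedding_backend}.
#' @param subtype subtype classifier kind (see [train_subtype()]).
#' @param cfg a [pipeline_config()].
#' @return object of class \code{screen_fit}.
#' @export
screen_fit <- function(train_adhd, train_non_adhd, backend,
                       subtype = c("forest", "rbf_margin", "linear_logodds"),
                       cfg = pipeline_config()) {
  subtype <- match.arg(subtype)
  inatt <- corpus_domain(train_adhd, "inattention")
  hyper <- corpus_domain(train_adhd, "hyperactivity_impulsivity")
  filter <- train_filter(train_adhd, train_non_adhd, backend, cfg)
  X <- feature_matrix(train_adhd, inatt, hyper, backend,
                      min_path_sim = cfg$min_path_sim)
  y <- as.integer(train_adhd$domain == "hyperactivity_impulsivity")
  sub <- train_subtype(subtype, X, y, cfg)
  structure(list(filter = filter, subtype = sub, inatt = inatt,
                 hyper = hyper, backend = backend, cfg = cfg),
            class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat("Two-stage screening pipeline\n")
  cat("  backend:", x$backend$name, "\n")
  cat("  subtype classifier:", x$subtype$kind, "\n")
  cat("  exemplars:", NROW(x$inatt), "inattention /", NROW(x$hyper),
      "hyperactivity-impulsivity\n")
  invisible(x)
}

#' Run a fitted screening pipeline on a corpus
#'
#' @param object a \code{screen_fit}.
#' @param newdata a \code{symptom_corpus}.
#' @param ... unused.
#' @return data frame with one row per input item: filter probability and
#'   decision, and for retained items the predicted subtype (0 =
#'   inattention, 1 = hyperactivity/impulsivity) and its probability.
#' @export
predict.screen_fit <- function(object, newdata, ...) {
  flt <- apply_filter(object$filter, object$backend, newdata)
  out <- data.frame(id = newdata$id, text = newdata$text,
                    filter_prob = flt$prob,
                    passed = flt$prob >= 0.5,
                    subtype = NA_integer_, subtype_prob = NA_real_,
                    stringsAsFactors = FALSE)
  if (NROW(flt$passed) > 0L) {
    X <- feature_matrix(flt$passed, object$inatt, object$hyper,
                        object$backend,
                        min_path_sim = object$cfg$min_path_sim)
    sp <- predict(object$subtype, X)
    out$subtype[out$passed] <- sp$pred
    out$subtype_prob[out$passed] <- sp$prob
  }
  out
}
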