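# Entropy Weight Method (EWM) fusion of the three similarity layers and
# percentile-based redundancy thresholding.

#' Entropy weights for the similarity layers
#'
#' Objective layer weights by the Entropy Weight Method: each layer column
#' is normalised to a probability distribution (p_ij = x_ij / sum_i x_ij,
#' zeros replaced by a small positive constant), its Shannon entropy is
#' scaled by k = 1/ln(m) so H_j lies in [0, 1], the divergence d_j = 1 -
#' H_j measures the layer's information content, and weights are the
#' divergences normalised to sum to one. Layers with more dispersed score
#' distributions therefore receive more weight; a perfectly uniform column
#' has H = 1 and weight 0.
#'
#' @param table a \code{layer_score_table} (all scores >= 0, m >= 2 rows,
#'   no all-zero column).
#' @param zero_eps replacement for zero probabilities (default 1e-10).
#' @return object of class \code{entropy_weights}: list with \code{k},
#'   \code{H}, \code{d}, \code{w} (named per layer).
#' @export
entropy_weights <- function(table, zero_eps = 1e-10) {
  x <- table$x
  m <- nrow(x)
  if (m < 2L) stop("entropy weights need m >= 2 rows", call. = FALSE)
  if (any(x < 0)) stop("scores must be non-negative", call. = FALSE)
  cs <- colSums(x)
  if (any(cs == 0)) stop("all-zero layer column", call. = FALSE)
  p <- sweep(x, 2, cs, "/")
  p[p == 0] <- zero_eps
  k <- 1 / log(m)
  H <- -k * colSums(p * log(p))
  d <- 1 - H
  w <- d / sum(d)
  structure(list(k = k, H = H, d = d, w = w), class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("Entropy weights (k =", format(x$k, digits = 4), ")\n")
  print(round(rbind(entropy = x$H, divergence = x$d, weight = x$w), 4))
  invisible(x)
}

#' Combined similarity scores
#'
#' Weighted sum of each pair's original (not column-normalised) layer
#' scores: \code{combined_i = sum_j w_j x_ij}. Because the weights are a
#' convex combination, every combined score lies between the pair's
#' smallest and largest layer score.
#'
#' @param table a \code{layer_score_table}.
#' @param w an \code{entropy_weights} object (or bare weight vector).
#' @return numeric vector of combined scores, named by pair label.
#' @export
combined_scores <- function(table, w) {
  wv <- if (inherits(w, "entropy_weights")) w$w else w
  if (length(wv) != ncol(table$x)) stop("weight/layer mismatch", call. = FALSE)
  out <- as.vector(table$x %*% wv)
  names(out) <- table$labels
  out
}

#' Percentile cutoff and redundant-pair selection
#'
#' The cutoff is the linear-interpolation percentile of the scores (rank
#' position p/100 * (n - 1) on the ascending sort, the standard type-7
#' quantile); items scoring at least \code{cutoff - relaxation} are
#' selected, so the relaxation (default 0.03 on the 0-1 similarity scale,
#' the "top 1st percentile +/- 3" rule) is applied on the lower side only.
#'
#' @param scores numeric vector (>= 2 values), optionally named.
#' @param percentile percentile in (0, 100); default 99 ("top 1st
#'   percentile").
#' @param relaxation subtracted from the cutoff before selection.
#' @return object of class \code{threshold_result}: list with
#'   \code{percentile}, \code{cutoff}, \code{relaxation}, \code{selected}
#'   (labels) and \code{scores}.
#' @export
percentile_cutoff <- function(scores, percentile = 99, relaxation = 0.03) {
  if (length(scores) < 2L) stop("need at least two scores", call. = FALSE)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(scores, percentile / 100, type = 7))
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  sel <- names(scores)[scores >= cutoff - relaxation]
  structure(list(percentile = percentile, cutoff = cutoff,
                 relaxation = relaxation, selected = sel, scores = scores),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Cutoff at percentile %g: %.4f (relaxation %.3g)\n",
              x$percentile, x$cutoff, x$relaxation))
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Redundancy analysis of a layer score table
#'
#' The central fit: derives entropy weights from the three layer columns,
#' fuses them into combined per-pair scores, and flags redundant pairs by
#' the percentile cutoff with relaxation. Returns a classed object with
#' \code{print}, \code{summary}, \code{coef} (the layer weights) and
#' \code{plot} (score distribution with cutoff) methods.
#'
#' @param table a \code{layer_score_table}, e.g. from [layer_scores()] or
#'   [load_bundled()].
#' @param percentile selection percentile (default 99).
#' @param relaxation cutoff relaxation (default 0.03).
#' @param zero_eps zero replacement in the entropy step.
#' @return object of class \code{redundancy}.
#' @export
redundancy <- function(table, percentile = 99, relaxation = 0.03,
                       zero_eps = 1e-10) {
  stopifnot(inherits(table, "layer_score_table"))
  w <- entropy_weights(table, zero_eps = zero_eps)
  comb <- combined_scores(table, w)
  thr <- percentile_cutoff(comb, percentile, relaxation)
  structure(list(table = table, weights = w, combined = comb,
                 threshold = thr, resources = attr(table, "resources")),
            class = "redundancy")
}

#' @export
print.redundancy <- function(x, ...) {
  cat("Redundancy analysis of", x$table$m, "symptom pairs\n")
  cat("Layer weights:",
      paste(sprintf("%s %.2f", names(x$weights$w), x$weights$w),
            collapse = ", "), "\n")
  cat(sprintf("Cutoff (p%g) %.4f - relaxation %.3g\n",
              x$threshold$percentile, x$threshold$cutoff,
              x$threshold$relaxation))
  cat("Redundant pairs:", paste(x$threshold$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.redundancy <- function(object, ...) {
  df <- data.frame(pair = object$table$labels, object$table$x,
                   combined = unname(object$combined),
                   selected = object$table$labels %in% object$threshold$selected,
                   check.names = FALSE)
  df[order(-df$combined), ]
}

#' @export
coef.redundancy <- function(object, ...) object$weights$w

#' @export
plot.redundancy <- function(x, ...) {
  graphics::hist(x$combined, breaks = 12, col = "grey85",
                 main = "Combined similarity scores",
                 xlab = "entropy-weighted combined similarity")
  graphics::abline(v = x$threshold$cutoff, col = "darkgreen", lty = 2)
  graphics::abline(v = x$threshold$cutoff - x$threshold$relaxation,
                   col = "darkgreen", lty = 3)
  invisible(x)
}
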