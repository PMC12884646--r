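# Statistical validation that the similarity layers carry non-redundant
# information: Wilcoxon signed-rank paired comparison, k-nearest-neighbour
# mutual information, and the class-imbalance chi-square check.

#' Wilcoxon signed-rank test on paired score lists
#'
#' Two-sided test on the paired differences. Zero differences are dropped
#' before ranking (Wilcoxon's original treatment); the reported statistic
#' is the smaller of the positive- and negative-difference rank sums. The
#' p-value uses the exact signed-rank distribution when n <= 25 and there
#' are no ties in |differences|, and the normal approximation otherwise.
#'
#' @param x,y equal-length numeric vectors (n >= 5 after pairing).
#' @return object of class \code{paired_test}: list with \code{statistic}
#'   (min rank sum), \code{p_value}, \code{n} (non-zero differences) and
#'   \code{method}.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop("degenerate sample: all paired differences are zero", call. = FALSE)
  }
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  stat <- min(w_pos, w_neg)
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25L && !ties) {
    p <- min(1, 2 * stats::psignrank(stat, n))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tie_tab^3 - tie_tab) / 48)
    z <- (stat - mu) / sigma
    p <- min(1, 2 * stats::pnorm(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  structure(list(statistic = stat, p_value = p, n = n, method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.1f, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' k-nearest-neighbour mutual information between two score lists
#'
#' Nonparametric Kraskov-style estimate of the mutual information (in nats)
#' between two continuous variables, with k = 3 neighbours under the
#' Chebyshev metric. A tiny seeded jitter breaks ties so the estimate is
#' reproducible; negative estimates are clipped to zero, and zero indicates
#' (estimated) independence. Constant inputs return 0.
#'
#' @param x,y equal-length numeric vectors (n >= 10).
#' @param k neighbour count (default 3).
#' @param seed integer seed for the tie-breaking jitter.
#' @return non-negative mutual information estimate.
#' @export
mutual_info <- function(x, y, k = 3L, seed = 1L) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 10L) stop("need at least 10 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  x <- x + stats::rnorm(n, sd = 1e-10 * max(stats::sd(x), 1e-12))
  y <- y + stats::rnorm(n, sd = 1e-10 * max(stats::sd(y), 1e-12))
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  psi <- digamma
  s <- 0
  for (i in seq_len(n)) {
    eps <- sort(dz[i, ])[k]
    nx <- sum(dx[i, -i] < eps)
    ny <- sum(dy[i, -i] < eps)
    s <- s + psi(nx + 1) + psi(ny + 1)
  }
  mi <- psi(k) + psi(n) - s / n
  max(0, mi)
}

#' Chi-square goodness-of-fit check for class imbalance
#'
#' One-degree-of-freedom test of two class counts against equal expected
#' counts: chi^2 = sum (obs - exp)^2 / exp with exp = (n_pos + n_neg)/2,
#' algebraically (a - b)^2 / (a + b).
#'
#' @param n_pos,n_neg non-negative class counts, not both zero.
#' @return list with \code{statistic} and \code{p}.
#' @export
chi_square_balance <- function(n_pos, n_neg) {
  if (n_pos + n_neg < 1) stop("both counts zero", call. = FALSE)
  e <- (n_pos + n_neg) / 2
  stat <- (n_pos - e)^2 / e + (n_neg - e)^2 / e
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Layer-validation report for a score table
#'
#' Runs the Wilcoxon signed-rank comparison and the mutual-information
#' estimate of the semantic layer against the lexical and syntactic layers,
#' mirroring the published validation layout.
#'
#' @param table a \code{layer_score_table} with lexical/syntactic/semantic
#'   columns.
#' @param seed seed for the mutual-information jitter.
#' @return data frame with one row per comparison: statistic, p-value and
#'   mutual information.
#' @export
validate_layers <- function(table, seed = 1L) {
  x <- table$x
  cmp <- list(c("semantic", "lexical"), c("semantic", "syntactic"))
  out <- do.call(rbind, lapply(cmp, function(cc) {
    wt <- wilcoxon_paired(x[, cc[1]], x[, cc[2]])
    mi <- mutual_info(x[, cc[2]], x[, cc[1]], seed = seed)
    data.frame(comparison = paste(cc[1], "vs", cc[2]),
               statistic = wt$statistic, p_value = wt$p_value,
               mutual_info = mi, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
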