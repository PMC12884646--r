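#' Hybrid word-to-word similarity
#'
#' Taxonomy path similarity (maximum over all sense pairs) with a
#' normalised-Levenshtein fallback: when no sense pair is connected in the
#' hypernym forest, or the best path similarity falls below
#' \code{min_path_sim}, the score is \code{1 - editdistance(a, b) /
#' max(nchar(a), nchar(b))}. Symmetric in its arguments and always in
#' [0, 1].
#'
#' @param a,b lowercase lemmas.
#' @param pos_a,pos_b optional coarse POS restricting the taxonomy senses.
#' @param min_path_sim threshold below which the path score is discarded in
#'   favour of the edit-distance fallback (default 0.1).
#' @return similarity in [0, 1].
#' @export
word_similarity <- function(a, b, pos_a = NULL, pos_b = NULL,
                            min_path_sim = 0.1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty lemma", call. = FALSE)
  ps <- path_similarity(a, b, pos_a, pos_b)
  if (!is.na(ps) && ps >= min_path_sim) return(ps)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Greedy alignment of a similarity matrix
#'
#' Repeatedly selects the largest remaining entry, accumulates it and
#' deletes its row and column, until rows or columns are exhausted
#' (\code{min(nrow, ncol)} iterations); returns the accumulated total
#' divided by the number of iterations. Ties are broken by the smallest
#' (row, column) index lexicographically, so the result is deterministic.
#' This is the aggregation rule shared by the lexical and syntactic layers;
#' it is greedy, not an optimal assignment.
#'
#' @param S numeric matrix of pairwise similarities in [0, 1].
#' @return mean similarity of the greedily aligned pairs.
#' @export
greedy_align <- function(S) {
  S <- as.matrix(S)
  if (length(S) == 0L || nrow(S) == 0L || ncol(S) == 0L) {
    stop("empty alignment matrix", call. = FALSE)
  }
  iters <- min(nrow(S), ncol(S))
  rows <- seq_len(nrow(S)); cols <- seq_len(ncol(S))
  total <- 0
  for (k in seq_len(iters)) {
    sub <- S[rows, cols, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    # lexicographic (row, col) tie-break
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    total <- total + sub[best[1], best[2]]
    rows <- rows[-best[1]]; cols <- cols[-best[2]]
  }
  total / iters
}

#' Lexical similarity between two sentences
#'
#' Both sentences are preprocessed (see [lexical_preprocess()]), a token
#' similarity matrix is built with [word_similarity()], aggregated by
#' [greedy_align()], and a length penalty
#' \code{|len_a - len_b| * word_sim / max(len_a, len_b)} is subtracted to
#' obtain the final score. Symmetric; equal-length sentences incur no
#' penalty.
#'
#' @param a,b sentences.
#' @param min_path_sim fallback threshold passed to [word_similarity()].
#' @return an object of class \code{lexical_score} with fields
#'   \code{word_sim}, \code{len_a}, \code{len_b}, \code{penalty},
#'   \code{final} and \code{empty} (TRUE when either side preprocesses to
#'   nothing, in which case the score is 0 and a warning is issued).
#' @export
lexical_similarity <- function(a, b, min_path_sim = 0.1) {
  ta <- lexical_preprocess(a); tb <- lexical_preprocess(b)
  if (nrow(ta) == 0L || nrow(tb) == 0L) {
    warning("sentence reduced to zero content tokens; lexical score 0",
            call. = FALSE)
    return(structure(list(word_sim = 0, len_a = nrow(ta), len_b = nrow(tb),
                          penalty = 0, final = 0, empty = TRUE),
                     class = "lexical_score"))
  }
  S <- matrix(0, nrow(ta), nrow(tb))
  for (i in seq_len(nrow(ta))) {
    for (j in seq_len(nrow(tb))) {
      S[i, j] <- word_similarity(ta$lemma[i], tb$lemma[j],
                                 ta$coarse_pos[i], tb$coarse_pos[j],
                                 min_path_sim = min_path_sim)
    }
  }
  ws <- greedy_align(S)
  la <- nrow(ta); lb <- nrow(tb)
  penalty <- abs(la - lb) * ws / max(la, lb)
  structure(list(word_sim = ws, len_a = la, len_b = lb, penalty = penalty,
                 final = ws - penalty, empty = FALSE),
            class = "lexical_score")
}

#' @export
print.lexical_score <- function(x, ...) {
  cat(sprintf(
    "Lexical similarity: %.4f (word_sim %.4f, penalty %.4f, lengths %d/%d)\n",
    x$final, x$word_sim, x$penalty, x$len_a, x$len_b))
  invisible(x)
}
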