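#' Compute the three-layer similarity score table for a domain corpus
#'
#' For every unordered pair of items (i < j, 1-based positions matching the
#' corpus order) computes lexical, syntactic and semantic similarity and
#' assembles them into a [layer_score_table()]. A nine-item domain yields
#' the canonical 36-pair table.
#'
#' @param corpus a \code{symptom_corpus} (typically one symptom domain).
#' @param backend an \code{embedding_backend} for the semantic layer.
#' @param min_path_sim hybrid word-similarity fallback threshold.
#' @return a \code{layer_score_table}; the attribute \code{resources}
#'   records the taxonomy, parser and backend versions used.
#' @export
layer_scores <- function(corpus, backend, min_path_sim = 0.1) {
  n <- NROW(corpus)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  sem <- cosine_pairwise(backend, corpus)
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  x <- matrix(NA_real_, m, 3,
              dimnames = list(NULL, c("lexical", "syntactic", "semantic")))
  for (k in seq_len(m)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    x[k, 1] <- lexical_similarity(corpus$text[i], corpus$text[j],
                                  min_path_sim = min_path_sim)$final
    x[k, 2] <- syntactic_similarity(corpus$text[i], corpus$text[j],
                                    min_path_sim = min_path_sim)
    x[k, 3] <- sem[i, j]
  }
  out <- layer_score_table(pairs, x)
  attr(out, "resources") <- c(taxonomy = taxonomy_version(),
                              parser = parser_version(),
                              backend = backend$name)
  out
}

#' Export a layer score table as a data frame / CSV
#'
#' @param table a \code{layer_score_table}.
#' @param path optional CSV path; when given the table is written there.
#' @return data frame mirroring the published table layout (invisibly when
#'   writing).
#' @export
as.data.frame.layer_score_table <- function(x, ...) {
  df <- data.frame(pair = x$labels, x$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$combined)) df$combined <- x$combined
  df
}
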