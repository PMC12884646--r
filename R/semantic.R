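# Semantic layer: sentence embeddings behind a pluggable backend contract,
# pairwise cosine similarity, and rank-correlation comparison of backends.
# The reference configuration uses 768-dimensional sentence-transformer
# embeddings ("pritamdeka/S-Biomed-Roberta-snli-multinli-stsb" as the
# clinical model, "all-mpnet-base-v2" as the general-purpose alternate);
# those model weights are external, so any function mapping texts to
# vectors can be wrapped as a backend. The bundled stub backend is a
# deterministic hashed bag-of-tokens random projection that needs no
# external resources.

#' Construct an embedding backend
#'
#' A backend is a named, fixed-dimension, deterministic mapping from texts
#' to real vectors. \code{embed_fn} must return one \code{dim}-length finite
#' vector per input text, identically for identical text.
#'
#' @param name identifier string (recorded in outputs).
#' @param dim embedding dimension (768 for the reference backends).
#' @param embed_fn function(character vector) -> numeric matrix with one row
#'   per text and \code{dim} columns.
#' @return an object of class \code{embedding_backend}.
#' @export
embedding_backend <- function(name, dim, embed_fn) {
  stopifnot(is.character(name), length(name) == 1L, dim >= 1,
            is.function(embed_fn))
  structure(list(name = name, dim = as.integer(dim), embed = embed_fn,
                 cache = new.env(parent = emptyenv())),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("Embedding backend '%s' (dim %d)\n", x$name, x$dim))
  invisible(x)
}

# deterministic 31-bit polynomial string hash (exact in double arithmetic)
str_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

token_seed <- function(token, seed) {
  (str_hash(token) + 1103515245 * (seed %% 1024)) %% 2147483647
}

#' Deterministic stub embedding backend
#'
#' Embeds a sentence as the unit-normalised sum of per-token pseudo-random
#' Gaussian vectors, each token's vector derived from a seeded hash of the
#' token string (a hashed random-indexing scheme). Tokens are first folded
#' through the package's curated synonym groups so that synonyms share a
#' vector, mimicking the synonym robustness of a learned semantic encoder.
#' Identical texts always map to identical vectors; texts sharing no tokens
#' are nearly orthogonal in high dimension; texts sharing most tokens
#' (paraphrases, copies) have high cosine. Purely offline and reproducible.
#'
#' @param seed integer seed folded into every token hash.
#' @param dim embedding dimension (default 768).
#' @return an \code{embedding_backend}.
#' @export
stub_backend <- function(seed = 1L, dim = 768L) {
  token_cache <- new.env(parent = emptyenv())
  token_vec <- function(tok) {
    if (!is.null(token_cache[[tok]])) return(token_cache[[tok]])
    v <- withr_seed_rnorm(token_seed(tok, seed), dim)
    token_cache[[tok]] <- v
    v
  }
  embed_fn <- function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      toks <- tokenize(texts[i])
      if (length(toks) == 0L) toks <- "empty"
      mapped <- SYNONYM_SWAPS[toks]
      toks <- ifelse(is.na(mapped), toks, mapped)
      v <- rowSums(vapply(toks, token_vec, numeric(dim)))
      nv <- sqrt(sum(v^2))
      if (nv == 0) nv <- 1
      out[i, ] <- v / nv
    }
    out
  }
  embedding_backend(sprintf("stub-hash-%d", seed), dim, embed_fn)
}

# draw dim normals under a local RNG state without touching the caller's
withr_seed_rnorm <- function(seed, dim) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  stats::rnorm(dim)
}

#' Embed the texts of a corpus (with caching)
#'
#' Vectors are cached inside the backend keyed by text, so repeated
#' pipeline stages reuse embeddings.
#'
#' @param backend an \code{embedding_backend}.
#' @param texts character vector.
#' @return numeric matrix, one row per text.
#' @export
embed_texts <- function(backend, texts) {
  stopifnot(inherits(backend, "embedding_backend"))
  out <- matrix(NA_real_, length(texts), backend$dim)
  miss <- vapply(texts, function(t) is.null(backend$cache[[t]]), TRUE)
  if (any(miss)) {
    fresh <- backend$embed(unique(texts[miss]))
    if (!is.matrix(fresh) || ncol(fresh) != backend$dim ||
        !all(is.finite(fresh))) {
      stop("backend '", backend$name, "' returned malformed embeddings",
           call. = FALSE)
    }
    uniq <- unique(texts[miss])
    for (k in seq_along(uniq)) backend$cache[[uniq[k]]] <- fresh[k, ]
  }
  for (i in seq_along(texts)) out[i, ] <- backend$cache[[texts[i]]]
  out
}

#' Pairwise cosine similarity matrix over a corpus
#'
#' @param backend an \code{embedding_backend}.
#' @param corpus a \code{symptom_corpus}.
#' @return an object of class \code{similarity_matrix}: a symmetric matrix
#'   with unit diagonal, dimnames = item ids, and attributes recording the
#'   backend name.
#' @export
cosine_pairwise <- function(backend, corpus) {
  if (NROW(corpus) == 0L) stop("empty corpus", call. = FALSE)
  E <- embed_texts(backend, corpus$text)
  norms <- sqrt(rowSums(E^2))
  zero <- norms < 1e-12
  if (any(zero)) {
    stop("zero-norm embedding for item(s): ",
         paste(corpus$id[zero], collapse = ", "), call. = FALSE)
  }
  En <- E / norms
  M <- tcrossprod(En)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(corpus$id, corpus$id)
  structure(M, backend = backend$name, class = c("similarity_matrix", "matrix"))
}

#' Rank agreement between two similarity matrices
#'
#' Spearman rank correlation over the upper-triangle (i < j) entries of two
#' cosine-similarity matrices computed over the same items, with a
#' two-sided p-value.
#'
#' @param simA,simB \code{similarity_matrix} objects with identical labels
#'   in identical order.
#' @return list with \code{rho} and \code{p}.
#' @export
compare_backends <- function(simA, simB) {
  if (!identical(dimnames(simA)[[1]], dimnames(simB)[[1]])) {
    stop("similarity matrices have mismatched labels", call. = FALSE)
  }
  ut <- upper.tri(simA)
  ct <- suppressWarnings(
    stats::cor.test(simA[ut], simB[ut], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
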