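#' Symptom corpora
#'
#' A symptom corpus is an ordered collection of short text items, each with a
#' unique id, a domain label (\code{"inattention"},
#' \code{"hyperactivity_impulsivity"}, \code{"non_adhd"} or \code{"unknown"})
#' and a source (the instrument or manual the item comes from). Corpora are
#' stored as data frames of class \code{symptom_corpus} with columns
#' \code{id}, \code{text}, \code{domain}, \code{source}.
#'
#' @param id character vector of unique ids; autogenerated zero-padded
#'   ordinals when \code{NULL}.
#' @param text character vector of non-empty sentences.
#' @param domain domain label per item, recycled; unrecognised values are an
#'   error.
#' @param source instrument name per item, recycled.
#' @return a \code{symptom_corpus} data frame.
#' @export
symptom_corpus <- function(text, id = NULL, domain = "unknown", source = "") {
  text <- as.character(text)
  if (length(text) == 0L) stop("EmptyCorpus: no items", call. = FALSE)
  blank <- !nzchar(trimws(text))
  if (any(blank)) {
    stop("blank text at row(s): ", paste(which(blank), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(id)) {
    id <- sprintf(paste0("%0", max(3L, nchar(length(text))), "d"),
                  seq_along(text) - 1L)
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate ids in corpus", call. = FALSE)
  domain <- rep_len(as.character(domain), length(text))
  ok <- c("inattention", "hyperactivity_impulsivity", "non_adhd", "unknown")
  bad <- setdiff(unique(domain), ok)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = id, text = text, domain = domain,
                    source = rep_len(as.character(source), length(text)),
                    stringsAsFactors = FALSE)
  class(out) <- c("symptom_corpus", "data.frame")
  out
}

#' @export
print.symptom_corpus <- function(x, ...) {
  cat("Symptom corpus:", nrow(x), "items\n")
  tab <- table(x$domain)
  cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  [%s] %s\n", x$id[i],
                if (nchar(x$text[i]) > 64) paste0(substr(x$text[i], 1, 61), "...")
                else x$text[i]))
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

as_symptom_corpus <- function(df) {
  if (!"text" %in% names(df)) stop("corpus input lacks a 'text' field", call. = FALSE)
  symptom_corpus(text = df$text,
                 id = if ("id" %in% names(df)) as.character(df$id) else NULL,
                 domain = if ("domain" %in% names(df)) df$domain else "unknown",
                 source = if ("source" %in% names(df)) df$source else "")
}

#' Read a symptom corpus from disk
#'
#' Supported formats: \code{csv} (comma-delimited, UTF-8, header row with at
#' least a \code{text} column), \code{json} (array of objects with the same
#' keys), and \code{txt_lines} (one item per line). Missing ids are
#' autogenerated as zero-padded ordinals; missing domains become
#' \code{"unknown"}.
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"json"}, \code{"txt_lines"};
#'   guessed from the file extension when missing.
#' @return a \code{symptom_corpus}.
#' @export
read_corpus <- function(path, format = c("csv", "json", "txt_lines")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json", "txt_lines")
  }
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
    if (nrow(df) == 0L) stop("EmptyCorpus: ", path, call. = FALSE)
    as_symptom_corpus(df)
  } else if (format == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (NROW(df) == 0L) stop("EmptyCorpus: ", path, call. = FALSE)
    as_symptom_corpus(as.data.frame(df, stringsAsFactors = FALSE))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("EmptyCorpus: ", path, call. = FALSE)
    symptom_corpus(text = lines)
  }
}

#' Write a symptom corpus to disk
#'
#' Round-trips losslessly with [read_corpus()] for every supported format
#' (for \code{txt_lines} only the text column survives).
#'
#' @param corpus a \code{symptom_corpus}.
#' @inheritParams read_corpus
#' @export
write_corpus <- function(corpus, path, format = c("csv", "json", "txt_lines")) {
  if (NROW(corpus) == 0L) stop("refusing to write an empty corpus", call. = FALSE)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json", "txt_lines")
  }
  format <- match.arg(format)
  df <- as.data.frame(corpus)[, c("id", "text", "domain", "source")]
  if (format == "csv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = FALSE, dataframe = "rows")
  } else {
    writeLines(df$text, path, useBytes = TRUE)
  }
  invisible(NULL)
}

#' Per-pair layer score tables
#'
#' A layer score table holds, for every unordered pair of items in a
#' nine-symptom domain, the lexical, syntactic and semantic similarity
#' scores (36 rows, 3 score columns). The bundled reference tables also
#' carry the published combined column for comparison.
#'
#' @param pairs character labels \code{"(i,j)"} or a 2-column integer matrix
#'   of 1-based index pairs with i < j.
#' @param x numeric matrix, rows = pairs, columns = layers (lexical,
#'   syntactic, semantic).
#' @param combined optional reference combined-score column.
#' @return an object of class \code{layer_score_table} with elements
#'   \code{pairs} (2-column integer matrix), \code{labels}, \code{x}
#'   (m x n score matrix) and optionally \code{combined}.
#' @export
layer_score_table <- function(pairs, x, combined = NULL) {
  if (is.character(pairs)) pairs <- parse_pair_labels(pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  x <- as.matrix(x)
  if (nrow(x) != nrow(pairs)) stop("pair/score row mismatch", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite layer scores", call. = FALSE)
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j", call. = FALSE)
  labels <- sprintf("(%d,%d)", pairs[, 1], pairs[, 2])
  if (anyDuplicated(labels)) stop("duplicate pairs", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- c("lexical", "syntactic", "semantic")[seq_len(ncol(x))]
  structure(list(pairs = pairs, labels = labels, x = x, combined = combined,
                 m = nrow(x), n = ncol(x)),
            class = "layer_score_table")
}

parse_pair_labels <- function(labels) {
  m <- regmatches(labels, gregexpr("[0-9]+", labels))
  bad <- vapply(m, length, 1L) != 2L
  if (any(bad)) stop("unparseable pair label(s): ",
                     paste(labels[bad], collapse = ", "), call. = FALSE)
  t(vapply(m, function(v) as.integer(v), integer(2)))
}

#' @export
print.layer_score_table <- function(x, ...) {
  cat("Layer score table:", x$m, "pairs x", x$n, "layers\n")
  df <- data.frame(pair = x$labels, x$x, check.names = FALSE)
  if (!is.null(x$combined)) df$combined <- x$combined
  print(utils::head(df, 8), row.names = FALSE)
  if (x$m > 8) cat("  ...\n")
  invisible(x)
}

#' Load bundled reference data
#'
#' \code{"dsm5_adhd"} returns the 18 core DSM-5 ADHD symptom statements
#' (9 inattention + 9 hyperactivity/impulsivity) exactly as transcribed;
#' \code{"table5_inattention"} and \code{"table6_hyperactivity"} return the
#' published 36-pair layer score tables for each domain, with the published
#' combined column retained as reference data.
#'
#' @param name one of \code{"dsm5_adhd"}, \code{"table5_inattention"},
#'   \code{"table6_hyperactivity"}.
#' @return a \code{symptom_corpus} or a \code{layer_score_table}.
#' @export
load_bundled <- function(name) {
  valid <- c("dsm5_adhd", "table5_inattention", "table6_hyperactivity")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown bundled dataset; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "symsim",
                      mustWork = TRUE)
  if (name == "dsm5_adhd") return(read_corpus(path, "csv"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  layer_score_table(df$pair, as.matrix(df[, c("lexical", "syntactic", "semantic")]),
                    combined = df$combined)
}

#' Subset a corpus by domain
#'
#' @param corpus a \code{symptom_corpus}.
#' @param domain a domain label.
#' @return the \code{symptom_corpus} restricted to that domain.
#' @export
corpus_domain <- function(corpus, domain) {
  out <- corpus[corpus$domain == domain, , drop = FALSE]
  if (nrow(out) == 0L) stop("no items with domain ", domain, call. = FALSE)
  class(out) <- c("symptom_corpus", "data.frame")
  rownames(out) <- NULL
  out
}
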