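# Syntactic layer: RDF-style dependency triples (head, relation, dependent)
# extracted by a deterministic rule-based shallow parser over the POS-tagged
# token sequence, then sentence similarity by greedy alignment of
# triple-pair similarities. Only a curated subset of dependency relations is
# retained; determiners and punctuation never yield triples.

RETAINED_RELATIONS <- c("nsubj", "nsubjpass", "dobj", "iobj", "dative",
                        "advmod", "prep", "pobj", "aux", "auxpass", "amod",
                        "xcomp", "ccomp", "conj", "neg", "acomp")

#' Parser version string
#'
#' Identifies the built-in rule-based dependency-triple extractor (recorded
#' in outputs; triple inventories are parser-version sensitive).
#' @return a single string.
#' @export
parser_version <- function() "symsim-ruleparser/1.0"

is_verb_tag <- function(tag) startsWith(tag, "V")
is_noun_tag <- function(tag) startsWith(tag, "N")

# head of the noun phrase starting at or after position i: the last token of
# the first maximal noun run encountered before a verb/prep/conj boundary
np_head_after <- function(tags, i, n) {
  j <- i
  while (j <= n && !is_noun_tag(tags[j])) {
    if (is_verb_tag(tags[j]) || tags[j] %in% c("IN", "TO", "CC")) return(NA_integer_)
    j <- j + 1
  }
  if (j > n) return(NA_integer_)
  while (j + 1 <= n && is_noun_tag(tags[j + 1])) j <- j + 1
  j
}

#' Extract filtered dependency triples from a sentence
#'
#' The sentence is stripped of punctuation, lowercased, POS-tagged and
#' lemmatised, and grammatical relations are read off with deterministic
#' attachment rules (adverb to nearest verb, auxiliary/negation/infinitival
#' marker to the following main verb, adjectival modifier to the following
#' noun, direct object and prepositional complements from the verb's right
#' context, verb/noun coordination, infinitival complements). Only triples
#' whose relation is in the retained set (subjects, objects, adverbial,
#' prepositional, auxiliary, adjectival, clausal-complement, coordination,
#' negation relations) are returned; \code{det} and \code{punct} are never
#' produced.
#'
#' @param text a sentence.
#' @return a data frame with columns \code{head}, \code{relation},
#'   \code{dependent} (lemmas, lowercase), ordered by head token position;
#'   zero rows if the sentence yields no retained relation.
#' @export
extract_triples <- function(text) {
  empty <- data.frame(head = character(), relation = character(),
                      dependent = character(), stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(empty)
  toks <- tokenize(text)
  n <- length(toks)
  if (n < 2L) return(empty)
  tags <- tag_pos(toks)
  cp <- coarse_pos(tags)
  lem <- mapply(lemmatize, toks, cp, USE.NAMES = FALSE)

  verb_idx <- which(vapply(tags, is_verb_tag, TRUE))
  # auxiliaries: be/have/do/modals followed (through adverbs/negation/TO)
  # by another verb; that verb is the main verb they attach to
  aux_of <- rep(NA_integer_, n)
  for (v in verb_idx) {
    if (lem[v] %in% c("be", "have", "do") || tags[v] == "MD") {
      j <- v + 1
      while (j <= n && (tags[j] %in% c("RB", "RP", "TO"))) j <- j + 1
      if (j <= n && is_verb_tag(tags[j])) aux_of[v] <- j
    }
  }
  main_verbs <- setdiff(verb_idx, which(!is.na(aux_of)))

  rows <- list()
  add <- function(h, rel, d, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      head = h, relation = rel, dependent = d, .pos = pos,
      stringsAsFactors = FALSE)
  }

  nearest_main_verb <- function(i, prefer = c("after", "before")) {
    prefer <- match.arg(prefer)
    aft <- main_verbs[main_verbs > i]
    bef <- main_verbs[main_verbs < i]
    if (prefer == "after") {
      if (length(aft)) return(aft[1])
      if (length(bef)) return(bef[length(bef)])
    } else {
      if (length(bef)) return(bef[length(bef)])
      if (length(aft)) return(aft[1])
    }
    NA_integer_
  }

  # aux / auxpass / neg
  for (v in which(!is.na(aux_of))) {
    m <- aux_of[v]
    rel <- if (lem[v] == "be" && tags[m] %in% c("VBD", "VBN")) "auxpass" else "aux"
    add(lem[m], rel, lem[v], m)
  }
  for (i in which(toks == "not")) {
    aft <- main_verbs[main_verbs > i]
    if (length(aft)) add(lem[aft[1]], "neg", "not", aft[1])
  }
  # infinitival "to" as aux; nominal "to" handled with prepositions below
  to_idx <- which(tags == "TO")
  for (i in to_idx) {
    j <- i + 1
    while (j <= n && tags[j] == "RB") j <- j + 1
    if (j <= n && is_verb_tag(tags[j])) {
      add(lem[j], "aux", "to", j)
      # xcomp: governing verb or adjective to the left of "to"
      k <- i - 1
      while (k >= 1 && tags[k] %in% c("RB", "RP")) k <- k - 1
      if (k >= 1 && is_verb_tag(tags[k]) && k %in% main_verbs) {
        add(lem[k], "xcomp", lem[j], k)
      } else if (k >= 1 && tags[k] == "JJ") {
        add(lem[k], "xcomp", lem[j], k)
      }
    }
  }
  # advmod: adverbs (not negation) attach to the nearest main verb,
  # preferring a following verb for sentence-initial adverbs
  for (i in which(tags == "RB" & toks != "not")) {
    pref <- if (any(main_verbs > i)) "after" else "before"
    v <- nearest_main_verb(i, pref)
    if (!is.na(v)) add(lem[v], "advmod", lem[i], v)
  }
  # amod: adjective before the noun it modifies
  for (i in which(tags == "JJ")) {
    j <- i + 1
    while (j <= n && tags[j] == "JJ") j <- j + 1
    if (j <= n && is_noun_tag(tags[j])) {
      while (j + 1 <= n && is_noun_tag(tags[j + 1])) j <- j + 1
      add(lem[j], "amod", lem[i], i)
    }
  }
  # nsubj: noun-phrase head directly before the first main verb
  if (length(main_verbs)) {
    v1 <- main_verbs[1]
    k <- v1 - 1
    while (k >= 1 && tags[k] %in% c("RB", "DT", "JJ")) k <- k - 1
    if (k >= 1 && is_noun_tag(tags[k])) add(lem[v1], "nsubj", lem[k], v1)
  }
  # dobj: first noun-phrase head in the verb's right context
  for (v in main_verbs) {
    if (lem[v] == "be") next
    h <- np_head_after(tags, v + 1, n)
    if (!is.na(h)) add(lem[v], "dobj", lem[h], v)
  }
  # prep + pobj: prepositions (incl. nominal "to") head their object;
  # the preposition attaches to the nearest preceding main verb
  prep_idx <- c(which(tags == "IN"),
                to_idx[vapply(to_idx, function(i) {
                  j <- i + 1
                  while (j <= n && tags[j] == "RB") j <- j + 1
                  !(j <= n && is_verb_tag(tags[j]))
                }, TRUE)])
  for (p in sort(prep_idx)) {
    h <- np_head_after(tags, p + 1, n)
    if (is.na(h)) next
    add(lem[p], "pobj", lem[h], p)
    v <- nearest_main_verb(p, "before")
    if (!is.na(v) && v < p) add(lem[v], "prep", lem[p], v)
  }
  # conj: coordination of main verbs and of nouns across a conjunction
  for (cc in which(tags == "CC")) {
    vb <- main_verbs[main_verbs < cc]; va <- main_verbs[main_verbs > cc]
    if (length(vb) && length(va)) add(lem[vb[length(vb)]], "conj",
                                      lem[va[1]], vb[length(vb)])
    if (cc > 1 && cc < n && is_noun_tag(tags[cc - 1])) {
      h <- np_head_after(tags, cc + 1, n)
      if (!is.na(h)) add(lem[cc - 1], "conj", lem[h], cc - 1)
    }
  }
  # acomp: predicative adjective after a copula
  for (v in main_verbs[lem[main_verbs] == "be"]) {
    j <- v + 1
    while (j <= n && tags[j] == "RB") j <- j + 1
    if (j <= n && tags[j] == "JJ") add("be", "acomp", lem[j], v)
  }

  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$.pos), c("head", "relation", "dependent")]
  out <- unique(out)
  rownames(out) <- NULL
  stopifnot(all(out$relation %in% RETAINED_RELATIONS))
  out
}

#' Similarity between two dependency triples
#'
#' Average of a direct alignment (head with head, dependent with dependent)
#' and a cross alignment (head with dependent and vice versa), each itself
#' the mean of two [word_similarity()] calls. Relation labels do not enter
#' the score. Symmetric, and invariant to swapping head and dependent in
#' both triples simultaneously.
#'
#' @param t1,t2 single-row triple data frames or lists with \code{head} and
#'   \code{dependent}.
#' @param min_path_sim fallback threshold for [word_similarity()].
#' @return similarity in [0, 1].
#' @export
triple_similarity <- function(t1, t2, min_path_sim = 0.1) {
  direct <- mean(c(word_similarity(t1$head, t2$head, min_path_sim = min_path_sim),
                   word_similarity(t1$dependent, t2$dependent,
                                   min_path_sim = min_path_sim)))
  cross <- mean(c(word_similarity(t1$head, t2$dependent,
                                  min_path_sim = min_path_sim),
                  word_similarity(t1$dependent, t2$head,
                                  min_path_sim = min_path_sim)))
  mean(c(direct, cross))
}

#' Syntactic similarity between two sentences
#'
#' Extracts dependency triples from both sentences, builds the triple-pair
#' similarity matrix with [triple_similarity()] and aggregates it with the
#' same greedy alignment as the lexical layer. No length penalty is applied
#' by default (\code{length_penalty = TRUE} switches the lexical-layer
#' penalty on). If either sentence yields no triples the score is 0 with a
#' warning.
#'
#' @param a,b sentences.
#' @param length_penalty apply the lexical-layer length penalty to the
#'   triple counts (default \code{FALSE}).
#' @param min_path_sim fallback threshold for [word_similarity()].
#' @return similarity in [0, 1].
#' @export
syntactic_similarity <- function(a, b, length_penalty = FALSE,
                                 min_path_sim = 0.1) {
  ta <- extract_triples(a); tb <- extract_triples(b)
  if (nrow(ta) == 0L || nrow(tb) == 0L) {
    warning("sentence yields no dependency triples; syntactic score 0",
            call. = FALSE)
    return(0)
  }
  S <- matrix(0, nrow(ta), nrow(tb))
  for (i in seq_len(nrow(ta))) {
    for (j in seq_len(nrow(tb))) {
      S[i, j] <- triple_similarity(ta[i, ], tb[j, ],
                                   min_path_sim = min_path_sim)
    }
  }
  score <- greedy_align(S)
  if (length_penalty) {
    score <- score - abs(nrow(ta) - nrow(tb)) * score / max(nrow(ta), nrow(tb))
  }
  score
}
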