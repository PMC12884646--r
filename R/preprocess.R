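# Text preprocessing for the lexical and syntactic layers: tokenisation,
# stopword removal, rule-based Penn Treebank POS tagging and POS-aware
# lemmatisation. The tagger and lemmatiser are compact rule/lexicon systems
# tuned for short English behavioural-symptom sentences; lexicons live in
# this file so the whole pipeline runs offline and deterministically.

# Standard English stopword list (classic 170-word list used by most NLP
# toolkits). "often" and other content adverbs are deliberately not in it.
STOPWORDS <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why",
  "how", "all", "any", "both", "each", "few", "more", "most", "other",
  "some", "such", "no", "nor", "not", "only", "own", "same", "so", "than",
  "too", "very", "s", "t", "can", "will", "just", "don", "should", "now")

DETERMINERS <- c("the", "a", "an", "this", "that", "these", "those", "each",
                 "every", "some", "any", "no")
PREPOSITIONS <- c("in", "on", "at", "by", "for", "with", "of", "from",
                  "about", "as", "before", "after", "during", "between",
                  "through", "into", "over", "under", "within", "without",
                  "when", "while", "if", "because", "until")
MODALS <- c("can", "could", "may", "might", "must", "shall", "should",
            "will", "would")
CONJUNCTIONS <- c("and", "or", "but", "nor")
PRONOUNS <- c("i", "you", "he", "she", "it", "we", "they", "them", "him",
              "her", "us", "me")
POSS_PRONOUNS <- c("my", "your", "his", "her", "its", "our", "their")

ADVERBS <- c("often", "never", "always", "sometimes", "frequently",
             "usually", "rarely", "seldom", "easily", "directly", "quietly",
             "quickly", "slowly", "excessively", "constantly", "repeatedly",
             "loudly", "carefully", "carelessly", "readily", "again",
             "also", "away", "back", "well", "soon")
ADJ_LY_EXCEPTIONS <- c("daily", "early", "only", "lonely", "friendly",
                       "silly", "ugly", "lovely")
PARTICLES <- c("out", "up", "off")

ADJECTIVES <- c("close", "careless", "careful", "necessary", "essential",
                "extraneous", "forgetful", "mental", "cognitive",
                "inappropriate", "improper", "unable", "incapable",
                "reluctant", "unwilling", "seated", "leisure", "quiet",
                "calm", "easy", "excessive", "daily", "early", "sad",
                "angry", "tired", "irritable", "happy", "fearful", "whole",
                "busy", "restless", "sustained", "hard", "difficult",
                "other", "late", "new", "loud", "hungry", "messy", "upset")

# Base-form verb lexicon; also drives -s/-ing/-ed restoration.
VERBS <- c("fail", "give", "make", "have", "do", "be", "sustain", "listen",
           "speak", "follow", "finish", "organize", "organise", "avoid",
           "engage", "require", "lose", "distract", "fidget", "tap",
           "squirm", "leave", "remain", "expect", "run", "climb", "play",
           "act", "drive", "talk", "blurt", "complete", "wait", "interrupt",
           "intrude", "seem", "go", "forget", "remember", "attend", "focus",
           "concentrate", "start", "stop", "keep", "get", "say", "see",
           "need", "want", "try", "help", "cry", "sleep", "eat", "fight",
           "argue", "refuse", "annoy", "blame", "steal", "destroy", "worry",
           "feel", "appear", "plan", "arrange", "misplace", "take", "hear",
           "watch", "notice", "stay", "continue", "end", "participate",
           "anticipate", "disturb", "bother", "obey", "ask", "tell",
           "answer", "jump", "walk", "wiggle", "maintain", "come", "sit",
           "stand", "throw", "hit", "shout", "scream", "whine", "sulk",
           "defy", "ignore", "tidy", "share", "read", "write", "draw",
           "build", "wash", "brush", "dress", "wake", "nap")

NOUNS <- c("attention", "detail", "mistake", "difficulty", "trouble",
           "task", "chore", "activity", "instruction", "thing", "stimulus",
           "seat", "situation", "hand", "foot", "motor", "answer",
           "question", "turn", "effort", "play", "game", "work",
           "assignment", "leisure", "child", "parent", "teacher", "adult",
           "toy", "bedtime", "homework", "appetite", "mood", "temper",
           "rule", "conversation", "classroom", "school", "home", "meal",
           "sleep", "night", "day", "morning", "friend", "sibling", "item",
           "belonging", "object", "material", "tool", "memory", "behavior",
           "symptom", "energy", "interest", "worry", "sadness", "anger",
           "fear", "tantrum", "chair", "table", "book", "story", "picture",
           "food", "clothes", "tooth", "hair", "face", "room", "house")

IRREGULAR_VERB_PAST <- c(
  ran = "run", made = "make", lost = "lose", left = "leave", spoke = "speak",
  spoken = "speak", drove = "drive", driven = "drive", went = "go",
  gone = "go", got = "get", kept = "keep", began = "begin", felt = "feel",
  said = "say", saw = "see", seen = "see", took = "take", taken = "take",
  gave = "give", given = "give", came = "come", sat = "sit", stood = "stand",
  ate = "eat", slept = "sleep", fought = "fight", threw = "throw",
  thrown = "throw", hit = "hit", heard = "hear", told = "tell",
  woke = "wake", forgot = "forget", forgotten = "forget", did = "do",
  done = "do", had = "have", was = "be", were = "be", been = "be")

IRREGULAR_NOUN_PLURAL <- c(
  feet = "foot", children = "child", stimuli = "stimulus", teeth = "tooth",
  mice = "mouse", people = "person", men = "man", women = "woman",
  criteria = "criterion", clothes = "clothes")

#' Tokenise a sentence into lowercase word tokens
#'
#' Lowercases, splits on non-alphanumeric boundaries and keeps purely
#' alphabetic tokens only (punctuation and digits are dropped).
#'
#' @param text a sentence.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  text <- tolower(text)
  # normalise curly quotes/dashes so quoted idioms survive tokenisation
  text <- gsub("[‘’“”]", " ", text)
  text <- gsub("[–—-]", " ", text)
  toks <- unlist(strsplit(text, "[^a-z']+"))
  toks <- gsub("'", "", toks)
  toks[nzchar(toks) & grepl("^[a-z]+$", toks)]
}

strip_s <- function(w) {
  if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
  if (grepl("(ch|sh|ss|x|z)es$", w)) return(sub("es$", "", w))
  if (grepl("[^s]s$", w)) return(sub("s$", "", w))
  w
}

# Penn Treebank POS tagging by lexicon lookup, suffix rules and a
# left-context pass. Coverage targets short behavioural sentences.
tag_pos <- function(tokens) {
  n <- length(tokens)
  tags <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    w <- tokens[i]
    base_s <- strip_s(w)
    base_v <- restore_base(base_s, VERBS) # recover e-final verb stems
    tag <-
      if (w == "to") "TO"
      else if (w == "not") "RB"
      else if (w %in% MODALS) "MD"
      else if (w %in% DETERMINERS) "DT"
      else if (w %in% c("is", "are", "am")) "VBZ"
      else if (w %in% c("was", "were")) "VBD"
      else if (w %in% c("be")) "VB"
      else if (w %in% c("been")) "VBN"
      else if (w %in% c("being", "having", "doing")) "VBG"
      else if (w == "has") "VBZ"
      else if (w %in% c("have", "do")) "VBP"
      else if (w %in% c("had", "did")) "VBD"
      else if (w == "does") "VBZ"
      else if (w %in% PRONOUNS) "PRP"
      else if (w %in% POSS_PRONOUNS) "PRP$"
      else if (w %in% CONJUNCTIONS) "CC"
      else if (w %in% PARTICLES) "RP"
      else if (w %in% PREPOSITIONS) "IN"
      else if (w %in% ADVERBS) "RB"
      else if (grepl("ly$", w) && !w %in% ADJ_LY_EXCEPTIONS) "RB"
      else if (w %in% names(IRREGULAR_VERB_PAST)) "VBD"
      else if (prev %in% c("TO", "MD") && !w %in% NOUNS &&
               !base_s %in% NOUNS) "VB"
      else if (w %in% ADJECTIVES) "JJ"
      else if (w %in% VERBS) if (prev %in% c("TO", "MD")) "VB" else "VBP"
      else if (grepl("ing$", w) && nchar(w) > 4) "VBG"
      else if (grepl("ed$", w) && nchar(w) > 3) "VBD"
      else if (grepl("s$", w) && base_v %in% VERBS && !base_s %in% NOUNS) "VBZ"
      else if (grepl("s$", w) && base_v %in% VERBS && base_s %in% NOUNS &&
               !prev %in% c("DT", "JJ", "IN", "PRP$", "CD")) "VBZ"
      else if (grepl("s$", w) && !grepl("ss$|us$|is$", w)) "NNS"
      else if (grepl("(ous|ful|less|ive|able|ible|al)$", w) &&
               !w %in% NOUNS) "JJ"
      else "NN"
    tags[i] <- tag
    prev <- tag
  }
  tags
}

# Penn tag -> coarse category; unmappable tags default to noun.
coarse_pos <- function(penn) {
  ifelse(grepl("^V", penn), "verb",
  ifelse(grepl("^J", penn), "adjective",
  ifelse(grepl("^RB", penn) | penn == "RB", "adverb", "noun")))
}

restore_base <- function(stem, lexicon) {
  if (stem %in% lexicon) return(stem)
  withe <- paste0(stem, "e")
  if (withe %in% lexicon) return(withe)
  if (nchar(stem) > 2 &&
      substr(stem, nchar(stem), nchar(stem)) ==
      substr(stem, nchar(stem) - 1, nchar(stem) - 1)) {
    undoubled <- substr(stem, 1, nchar(stem) - 1)
    if (undoubled %in% lexicon) return(undoubled)
  }
  stem
}

#' Lemmatise a token given its coarse part of speech
#'
#' Irregular forms are resolved from built-in tables; regular inflections by
#' suffix rules with e-restoration and consonant-undoubling validated
#' against the verb lexicon (so "organizing" maps to "organize" and
#' "running" to "run"). Nouns and verbs use separate irregular tables, so a
#' verb-tagged "leaves" becomes "leave" while a noun-tagged "leaves" would
#' become "leaf".
#'
#' @param word lowercase token.
#' @param pos one of \code{"noun"}, \code{"verb"}, \code{"adjective"},
#'   \code{"adverb"}.
#' @return the lemma (lowercase).
#' @export
lemmatize <- function(word, pos = "noun") {
  w <- tolower(word)
  if (pos == "verb") {
    if (w == "leaves") return("leave")
    if (w %in% names(IRREGULAR_VERB_PAST)) return(unname(IRREGULAR_VERB_PAST[w]))
    if (w %in% c("is", "are", "am", "be", "been", "being")) return("be")
    if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
    if (grepl("ing$", w) && nchar(w) > 4) {
      return(restore_base(sub("ing$", "", w), VERBS))
    }
    if (grepl("ied$", w)) return(sub("ied$", "y", w))
    if (grepl("ed$", w) && nchar(w) > 3) {
      return(restore_base(sub("ed$", "", w), VERBS))
    }
    if (grepl("(ch|sh|ss|x|z|o)es$", w)) {
      return(restore_base(sub("es$", "", w), VERBS))
    }
    if (grepl("[^s]s$", w)) return(sub("s$", "", w))
    return(w)
  }
  if (pos == "noun") {
    if (w == "leaves") return("leaf")
    if (w %in% names(IRREGULAR_NOUN_PLURAL)) return(unname(IRREGULAR_NOUN_PLURAL[w]))
    return(strip_s(w))
  }
  w
}

#' Preprocess a sentence for the lexical similarity layer
#'
#' Pipeline: lowercase, tokenise, drop stopwords, keep alphabetic tokens,
#' Penn POS-tag, map tags to coarse categories (noun/verb/adjective/adverb,
#' unmappable tags default to noun), then lemmatise with the coarse POS.
#' POS tagging happens on the full token sequence (before stopword removal)
#' so left-context rules see function words.
#'
#' @param text a sentence.
#' @return a data frame of class \code{token_seq} with columns
#'   \code{surface}, \code{penn_pos}, \code{coarse_pos}, \code{lemma}; zero
#'   rows if nothing survives preprocessing (callers must handle this).
#' @export
lexical_preprocess <- function(text) {
  if (!nzchar(trimws(text))) {
    out <- data.frame(surface = character(), penn_pos = character(),
                      coarse_pos = character(), lemma = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("token_seq", "data.frame")
    return(out)
  }
  toks <- tokenize(text)
  tags <- tag_pos(toks)
  keep <- !(toks %in% STOPWORDS)
  toks <- toks[keep]; tags <- tags[keep]
  cp <- coarse_pos(tags)
  lem <- mapply(lemmatize, toks, cp, USE.NAMES = FALSE)
  out <- data.frame(surface = toks, penn_pos = tags, coarse_pos = cp,
                    lemma = lem, stringsAsFactors = FALSE)
  class(out) <- c("token_seq", "data.frame")
  out
}
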