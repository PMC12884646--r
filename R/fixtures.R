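# Deterministic synthetic questionnaire generator: paraphrases of a base
# symptom corpus (inheriting its domain labels) plus templated non-ADHD
# distractor items, so every pipeline stage is exercisable offline with
# known ground truth. Fixtures exercise code paths; they do not claim
# clinical realism.

# hand-curated surface synonym table over the base-corpus vocabulary; the
# replacements share taxonomy senses with the originals so paraphrases stay
# lexically close
SYNONYM_SWAPS <- c(
  "tasks" = "chores", "task" = "chore", "mistakes" = "errors",
  "difficulty" = "trouble", "often" = "frequently",
  "easily" = "readily", "necessary" = "essential",
  "unable" = "incapable", "reluctant" = "unwilling",
  "inappropriate" = "improper", "loses" = "misplaces",
  "organizing" = "arranging", "intrudes" = "interrupts",
  "finish" = "complete", "required" = "needed"
)

FILLERS <- c("at home", "in the classroom", "during the day",
             "according to parents", "at school")

DISTRACTOR_TEMPLATES <- c(
  "Often appears sad or tearful for most of the day",
  "Frequently argues with adults and refuses to comply with rules",
  "Often loses temper and blames others for own misbehavior",
  "Shows little interest in food and eats very small meals",
  "Often deliberately annoys siblings and defies household rules",
  "Has trouble falling asleep and wakes during the night",
  "Often destroys toys or property belonging to others",
  "Appears tired and low in energy most mornings",
  "Often whines or sulks when asked to tidy the bedroom",
  "Frequently starts physical fights with other children",
  "Expresses worry and fear about being away from parents",
  "Often steals small items from classmates or shops",
  "Shows sudden temper tantrums with screaming and crying",
  "Often refuses to share and deliberately breaks rules of games",
  "Complains of feeling worthless and cries without clear reason",
  "Often lies to obtain favors or to avoid obligations",
  "Shows markedly reduced pleasure in nearly all usual hobbies",
  "Often shouts angrily at caregivers when routines change"
)

#' Specification for a synthetic questionnaire
#'
#' @param n_adhd_paraphrases paraphrase items generated per domain.
#' @param n_distractors non-ADHD distractor items.
#' @param ops perturbation operations drawn from \code{"synonym_swap"},
#'   \code{"clause_reorder"}, \code{"filler_insert"},
#'   \code{"verbatim_copy"}.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_adhd_paraphrases = 5L, n_distractors = 10L,
                           ops = c("synonym_swap", "clause_reorder",
                                   "filler_insert", "verbatim_copy"),
                           seed = 1L) {
  ops <- match.arg(ops, several.ok = TRUE)
  if (n_adhd_paraphrases + n_distractors <= 0) {
    stop("spec generates zero items", call. = FALSE)
  }
  structure(list(n_adhd_paraphrases = as.integer(n_adhd_paraphrases),
                 n_distractors = as.integer(n_distractors),
                 ops = ops, seed = as.integer(seed)),
            class = "synthetic_spec")
}

swap_synonyms <- function(text) {
  out <- tolower(text)
  for (w in names(SYNONYM_SWAPS)) {
    out <- gsub(paste0("\\b", w, "\\b"), SYNONYM_SWAPS[[w]], out)
  }
  out
}

reorder_clause <- function(text) {
  t0 <- tolower(text)
  if (grepl("^often ", t0)) return(paste0(sub("^often ", "", t0), " often"))
  if (grepl("^is often ", t0)) {
    return(paste0(sub("^is often ", "is ", t0), " often"))
  }
  paste("often", t0)
}

perturb <- function(text, op) {
  switch(op,
         synonym_swap = swap_synonyms(text),
         clause_reorder = reorder_clause(text),
         filler_insert = paste(tolower(text),
                               FILLERS[sample.int(length(FILLERS), 1L)]),
         verbatim_copy = text)
}

#' Generate a synthetic questionnaire corpus
#'
#' Draws \code{n_adhd_paraphrases} source items per labelled domain of the
#' base corpus, applies one randomly chosen perturbation operation to each
#' (paraphrases inherit the source item's domain label and record the
#' source id in the \code{source_item} column), and appends
#' \code{n_distractors} templated non-ADHD behavioural items labelled
#' \code{non_adhd}. Byte-identical output for identical spec and base.
#'
#' @param spec a [synthetic_spec()].
#' @param base labelled base corpus (typically
#'   \code{load_bundled("dsm5_adhd")}).
#' @return a \code{symptom_corpus} with an extra \code{source_item} column.
#' @export
generate_questionnaire <- function(spec, base) {
  stopifnot(inherits(spec, "synthetic_spec"))
  domains <- intersect(c("inattention", "hyperactivity_impulsivity"),
                       unique(base$domain))
  with_seed(spec$seed, {
    rows <- list()
    for (dom in domains) {
      pool <- base[base$domain == dom, , drop = FALSE]
      for (k in seq_len(spec$n_adhd_paraphrases)) {
        src <- pool[sample.int(nrow(pool), 1L), ]
        op <- spec$ops[sample.int(length(spec$ops), 1L)]
        rows[[length(rows) + 1L]] <- data.frame(
          text = perturb(src$text, op), domain = dom,
          source = "synthetic-questionnaire", source_item = src$id,
          stringsAsFactors = FALSE)
      }
    }
    if (spec$n_distractors > 0L) {
      idx <- rep_len(sample.int(length(DISTRACTOR_TEMPLATES)),
                     spec$n_distractors)
      dup <- duplicated(idx)
      texts <- DISTRACTOR_TEMPLATES[idx]
      # recycled templates get a filler so texts stay distinct
      texts[dup] <- paste(texts[dup],
                          FILLERS[sample.int(length(FILLERS),
                                             sum(dup), replace = TRUE)])
      for (i in seq_along(texts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          text = texts[i], domain = "non_adhd",
          source = "synthetic-questionnaire", source_item = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    out <- symptom_corpus(df$text,
                          id = sprintf("syn_%03d", seq_len(nrow(df)) - 1L),
                          domain = df$domain, source = df$source)
    out$source_item <- df$source_item
    out
  })
}
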