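#' Closed part-of-speech tag set
#'
#' The nine grammatical categories a token may receive. Every tagger backend
#' must emit tags from this set only; `OTHER` covers anything the backend
#' cannot place (interjections, numerals, residue).
#'
#' @format Character vector of nine tag names.
#' @export
POS_TAGS <- c(
  "NOUN", "VERB", "ADJECTIVE", "ADVERB", "PRONOUN",
  "PREPOSITION", "CONJUNCTION", "ARTICLE", "OTHER"
)

# WordNet lexicographer files: 26 noun categories, 15 verb categories.
.noun_supersenses <- paste0("noun.", c(
  "tops", "act", "animal", "artifact", "attribute", "body", "cognition",
  "communication", "event", "feeling", "food", "group", "location",
  "motive", "object", "person", "phenomenon", "plant", "possession",
  "process", "quantity", "relation", "shape", "state", "substance", "time"
))

.verb_supersenses <- paste0("verb.", c(
  "body", "change", "cognition", "communication", "competition",
  "consumption", "contact", "creation", "emotion", "motion", "perception",
  "possession", "social", "stative", "weather"
))

#' Supersense tag set
#'
#' The 41 WordNet lexicographer categories (26 noun, 15 verb) plus
#' `adj.all` for adjectives, used as shallow semantic types when pruning
#' frame-slot candidates. The set is fixed at load time; [is_supersense()]
#' checks membership.
#'
#' @format Character vector of 42 tag names.
#' @export
SUPERSENSE_TAGS <- c(.noun_supersenses, .verb_supersenses, "adj.all")

#' Test membership in the closed tag sets
#'
#' @param x character vector of candidate tags.
#' @return Logical vector, `TRUE` where `x` is a legal tag.
#' @export
is_supersense <- function(x) x %in% SUPERSENSE_TAGS

#' @rdname is_supersense
#' @export
is_pos_tag <- function(x) x %in% POS_TAGS
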