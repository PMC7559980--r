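#' Frame field names
#'
#' The six slots of the violence frame, in canonical order. The order
#' doubles as the tie-break when a token is equally close to two fields.
#'
#' @export
FRAME_FIELDS <- c("AGENT", "MODE_INSTRUMENT", "TIME", "LOCATION",
                  "BODY_PART", "LESION_TYPE")

#' Construct a frame field specification
#'
#' A field spec fixes which tokens may fill a slot: the allowed
#' part-of-speech tags, the allowed supersense tags, and the seed terms
#' whose mean embedding serves as the field's prototype vector.
#'
#' @param name field name, one of [FRAME_FIELDS].
#' @param allowed_pos character vector of PoS tags from [POS_TAGS].
#' @param allowed_sst character vector of supersense tags from
#'   [SUPERSENSE_TAGS].
#' @param seed_terms character vector of prototype seed tokens.
#' @return A `vf_field_spec`.
#' @export
field_spec <- function(name, allowed_pos, allowed_sst, seed_terms) {
  stopifnot(length(allowed_pos) > 0L, length(allowed_sst) > 0L)
  if (!all(is_pos_tag(allowed_pos))) stop("illegal PoS in allowed_pos for ", name)
  if (!all(is_supersense(allowed_sst))) stop("illegal supersense in allowed_sst for ", name)
  structure(list(name = name, allowed_pos = allowed_pos,
                 allowed_sst = allowed_sst, seed_terms = as.character(seed_terms)),
            class = "vf_field_spec")
}

#' The default violence-frame schema
#'
#' Six fields with their allowed PoS and supersense sets - nouns tagged
#' noun.person for the agent; nouns of object/artifact/state/substance/
#' feeling/act type for the mode or instrument; noun.time, noun.location
#' and noun.body for time, location and body part; and nouns or adjectives
#' of state/phenomenon/adjectival type for the lesion - plus per-field seed
#' terms (typical fillers such as "husband", "punch", "evening", "home",
#' "arm", "fracture") and the similarity threshold of 0.5 below which no
#' candidate is reported.
#'
#' @param similarity_threshold minimum cosine similarity for a filler
#'   (default 0.5).
#' @return A `vf_frame_schema`: list with `fields` (named list of
#'   [field_spec()]s in canonical order) and `similarity_threshold`.
#' @export
default_frame_schema <- function(similarity_threshold = 0.5) {
  fields <- list(
    field_spec("AGENT", "NOUN", "noun.person",
               c("husband", "known_person")),
    field_spec("MODE_INSTRUMENT", "NOUN",
               c("noun.object", "noun.artifact", "noun.state",
                 "noun.substance", "noun.feeling", "noun.act"),
               c("punch", "knife")),
    field_spec("TIME", "NOUN", "noun.time",
               c("evening", "night")),
    field_spec("LOCATION", "NOUN", "noun.location",
               c("home", "workplace")),
    field_spec("BODY_PART", "NOUN", "noun.body",
               c("arm", "head")),
    field_spec("LESION_TYPE", c("NOUN", "ADJECTIVE"),
               c("noun.state", "adj.all", "noun.phenomenon"),
               c("fracture", "contusion", "trauma"))
  )
  frame_schema(fields, similarity_threshold)
}

#' Construct a frame schema
#'
#' @param fields list of [field_spec()]s with unique names.
#' @param similarity_threshold real in `(0, 1]`.
#' @return A `vf_frame_schema`.
#' @export
frame_schema <- function(fields, similarity_threshold = 0.5) {
  nms <- vapply(fields, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate field names in schema")
  if (!(similarity_threshold > 0 && similarity_threshold <= 1)) {
    stop("similarity_threshold must lie in (0, 1]")
  }
  names(fields) <- nms
  structure(list(fields = fields, similarity_threshold = similarity_threshold),
            class = "vf_frame_schema")
}

#' Read a frame schema from YAML or JSON
#'
#' Expected structure: a `similarity_threshold` scalar and a `fields` map
#' whose entries carry `allowed_pos`, `allowed_sst` and `seed_terms` lists.
#' See `system.file("extdata", "frame_schema.yaml", package = "violframe")`
#' for the shipped default.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `vf_frame_schema`.
#' @export
read_frame_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fields <- lapply(names(raw$fields), function(nm) {
    f <- raw$fields[[nm]]
    field_spec(nm, unlist(f$allowed_pos), unlist(f$allowed_sst), unlist(f$seed_terms))
  })
  thr <- if (is.null(raw$similarity_threshold)) 0.5 else raw$similarity_threshold
  frame_schema(fields, thr)
}

#' Candidate generation: all distinct tokens of the record
#'
#' Candidates are types, not token positions: repeated words contribute a
#' single candidate, and the same candidate set seeds every field.
#'
#' @param seq a `vf_tokens` sequence with extended tokens marked.
#' @return Character vector of distinct tokens (order of first occurrence),
#'   with an `extended` attribute.
#' @export
generate_candidates <- function(seq) {
  toks <- as.character(seq)
  ext <- attr(seq, "extended")
  if (is.null(ext)) ext <- grepl("_", toks, fixed = TRUE)
  keep <- !duplicated(toks)
  token_sequence(toks[keep], ext[keep])
}

#' Prune candidates by PoS and supersense compatibility
#'
#' A candidate is retained for a field iff its PoS tag is among the field's
#' allowed PoS AND at least one supersense of its most frequent sense is
#' among the field's allowed supersenses. Extended tokens (multiword
#' locutions) bypass both checks and are always retained. Out-of-lexicon
#' tokens have an empty supersense set and are therefore pruned unless
#' extended.
#'
#' @param candidates a `vf_tokens` candidate set from
#'   [generate_candidates()].
#' @param field a `vf_field_spec`.
#' @param lex a `vf_lexicon` supplying tags.
#' @return A `vf_tokens` subset of `candidates`.
#' @export
prune_candidates <- function(candidates, field, lex) {
  toks <- as.character(candidates)
  ext <- attr(candidates, "extended")
  if (length(toks) == 0L) return(candidates)
  pos <- pos_tag(candidates, lex)
  keep <- vapply(seq_along(toks), function(i) {
    if (ext[i]) return(TRUE)
    if (!(pos[i] %in% field$allowed_pos)) return(FALSE)
    sst <- most_frequent_supersenses(toks[i], lex)
    length(intersect(sst, field$allowed_sst)) > 0L
  }, logical(1))
  token_sequence(toks[keep], ext[keep])
}

#' Rank candidates by cosine similarity to the field prototype
#'
#' Tokens without an embedding vector cannot be scored and are dropped
#' (mirroring what happens to an unexpanded abbreviation that never made it
#' into the training vocabulary). Sorting is by descending score with
#' lexicographic tie-break.
#'
#' @param candidates a `vf_tokens` candidate set (typically pruned).
#' @param prototype a `vf_prototype` from [build_prototype()].
#' @param model a `vf_embeddings`.
#' @return A `vf_ranking`: data frame with columns `token`, `score`, sorted
#'   descending, plus attributes `field` and `dropped` (unrankable tokens).
#' @export
rank_candidates <- function(candidates, prototype, model) {
  toks <- as.character(candidates)
  have <- vapply(toks, function(t) in_vocabulary(model, t), logical(1))
  scored <- toks[have]
  score <- vapply(scored, function(t) {
    cosine_similarity(embedding_vector(model, t), prototype$vector)
  }, numeric(1))
  ord <- order(-score, scored)
  out <- data.frame(token = scored[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  structure(out, field = prototype$field, dropped = toks[!have],
            class = c("vf_ranking", "data.frame"))
}

#' Resolve per-field rankings into a filled frame
#'
#' Two rules, applied in order: (1) every entry scoring below the
#' similarity threshold is discarded; (2) a token that survives for more
#' than one field is kept only in the field where its score is highest (the
#' "closest" field), cross-field ties broken by schema field order. All
#' survivors of a field are reported as its fillers - a slot may end up
#' with zero or several.
#'
#' @param rankings named list of `vf_ranking`s, one per schema field.
#' @param threshold minimum similarity score.
#' @return A `vf_frame`: named list (schema order) of data frames with
#'   columns `token`, `score`.
#' @export
resolve_assignments <- function(rankings, threshold) {
  field_names <- names(rankings)
  kept <- lapply(rankings, function(r) r[r$score >= threshold, , drop = FALSE])
  # best field per token: highest score, then earliest field in schema order
  all_tok <- unique(unlist(lapply(kept, function(r) r$token)))
  best_field <- vapply(all_tok, function(tk) {
    sc <- vapply(field_names, function(f) {
      i <- match(tk, kept[[f]]$token)
      if (is.na(i)) -Inf else kept[[f]]$score[i]
    }, numeric(1))
    field_names[which.max(sc)]   # which.max keeps the earliest on ties
  }, character(1))
  out <- lapply(field_names, function(f) {
    r <- kept[[f]]
    r <- r[best_field[r$token] == f, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  names(out) <- field_names
  structure(out, class = "vf_frame")
}

#' @export
print.vf_frame <- function(x, ...) {
  for (f in names(x)) {
    fills <- if (nrow(x[[f]]) == 0L) "-" else {
      paste(sprintf("%s (%.2f)", x[[f]]$token, x[[f]]$score), collapse = ", ")
    }
    cat(sprintf("%-16s %s\n", f, fills))
  }
  invisible(x)
}

#' Extract the violence frame from a cleaned record
#'
#' Orchestrates the explanation pipeline on one narrative: tokenize, mark
#' extended tokens, generate the candidate set, prune by PoS/supersense
#' compatibility (skipped when `use_filters = FALSE`, giving the
#' similarity-only baseline), rank against each field's prototype, then
#' threshold and resolve cross-field competition. Deterministic given its
#' inputs. Normally invoked only on records the classifier labeled V.
#'
#' @param text one cleaned narrative string (after [clean_text()]).
#' @param schema a `vf_frame_schema`.
#' @param model a `vf_embeddings`.
#' @param lex a `vf_lexicon`.
#' @param mwe_list multiword expressions to merge before extraction.
#' @param use_filters if `FALSE`, PoS/supersense pruning is skipped and
#'   ranking alone decides (the evaluation baseline).
#' @param prototypes optional precomputed named list of `vf_prototype`s
#'   (one per schema field), to avoid rebuilding them per record.
#' @return A `vf_frame` with attribute `rankings`: the per-field
#'   `vf_ranking`s before thresholding, used by ranked-retrieval metrics.
#' @export
extract_frame <- function(text, schema, model, lex,
                          mwe_list = character(0), use_filters = TRUE,
                          prototypes = NULL) {
  if (is.null(prototypes)) {
    prototypes <- lapply(schema$fields, build_prototype, model = model)
  }
  seq <- mark_extended_tokens(tokenize(text), mwe_list)
  cand <- generate_candidates(seq)
  rankings <- lapply(schema$fields, function(f) {
    cc <- if (use_filters) prune_candidates(cand, f, lex) else cand
    rank_candidates(cc, prototypes[[f$name]], model)
  })
  frame <- resolve_assignments(rankings, schema$similarity_threshold)
  attr(frame, "rankings") <- rankings
  frame
}
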