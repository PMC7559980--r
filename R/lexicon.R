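#' Read a tagger lexicon from TSV
#'
#' The lexicon is the deterministic tagging backend used for PoS and
#' supersense lookup: columns `lemma`, `pos`, `supersenses`. The
#' `supersenses` column lists sense groups in decreasing frequency order,
#' groups separated by `;`, ties within a group separated by `,`
#' (e.g. `noun.act;noun.artifact` ranks noun.act first, while
#' `noun.act,noun.artifact` is a tie of the top sense). `#` starts a
#' comment.
#'
#' @param path TSV path; defaults to the fixture lexicon shipped with the
#'   package.
#' @return A `vf_lexicon` object.
#' @export
read_lexicon <- function(path = system.file("extdata", "lexicon.tsv",
                                            package = "violframe")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("malformed lexicon line(s): ", paste(which(lengths(parts) < 3L), collapse = ", "))
  }
  lemma <- tolower(trimws(vapply(parts, `[[`, "", 1L)))
  pos <- toupper(trimws(vapply(parts, `[[`, "", 2L)))
  sst <- trimws(vapply(parts, `[[`, "", 3L))
  if (length(lemma) > 0 && lemma[1] == "lemma") {
    lemma <- lemma[-1L]; pos <- pos[-1L]; sst <- sst[-1L]
  }
  lexicon(lemma, pos, sst)
}

#' Construct a lexicon from vectors
#'
#' @param lemma character vector of lowercase lemmas.
#' @param pos character vector of PoS tags from [POS_TAGS].
#' @param supersenses character vector: per lemma, sense groups separated by
#'   `;` (frequency-ranked), ties within a group by `,`.
#' @return A `vf_lexicon`: a list with `entries` (data frame) and `index`
#'   (named lookup).
#' @export
lexicon <- function(lemma, pos, supersenses) {
  stopifnot(length(lemma) == length(pos), length(pos) == length(supersenses))
  if (!all(is_pos_tag(pos))) {
    stop("unknown PoS tag(s): ", paste(unique(pos[!is_pos_tag(pos)]), collapse = ", "))
  }
  groups <- lapply(strsplit(supersenses, ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    lapply(strsplit(g[nzchar(g)], ",", fixed = TRUE), function(s) tolower(trimws(s)))
  })
  all_sst <- unlist(groups)
  if (length(all_sst) > 0 && !all(is_supersense(all_sst))) {
    stop("unknown supersense tag(s): ",
         paste(unique(all_sst[!is_supersense(all_sst)]), collapse = ", "))
  }
  if (any(lengths(groups) == 0L)) stop("every lexicon entry needs at least one supersense")
  if (anyDuplicated(lemma)) {
    stop("duplicate lemma(s): ", paste(unique(lemma[duplicated(lemma)]), collapse = ", "))
  }
  idx <- seq_along(lemma)
  names(idx) <- lemma
  obj <- list(
    entries = data.frame(lemma = lemma, pos = pos, stringsAsFactors = FALSE),
    groups = groups,
    index = idx
  )
  class(obj) <- "vf_lexicon"
  obj
}

#' @export
print.vf_lexicon <- function(x, ...) {
  cat("<vf_lexicon> ", nrow(x$entries), " lemmas\n", sep = "")
  invisible(x)
}

#' Part-of-speech tag a token sequence
#'
#' Deterministic lexicon lookup with the clinical-text fallback rules:
#' out-of-lexicon tokens are tagged `NOUN` (out-of-vocabulary terms in ER
#' narratives are overwhelmingly nouns - unexpanded abbreviations, drug
#' names, anatomy), and extended tokens (multiword locutions) are always
#' `NOUN`.
#'
#' @param seq a `vf_tokens` sequence (lowercased).
#' @param lex a `vf_lexicon`.
#' @return Character vector of PoS tags, one per token, named by token.
#' @export
pos_tag <- function(seq, lex) {
  toks <- as.character(seq)
  ext <- attr(seq, "extended")
  if (is.null(ext)) ext <- grepl("_", toks, fixed = TRUE)
  hit <- lex$index[toks]
  tags <- ifelse(is.na(hit), "NOUN", lex$entries$pos[hit])
  tags[ext] <- "NOUN"
  names(tags) <- toks
  tags
}

#' Supersenses of a token's most frequent sense
#'
#' Implements the most-frequent-sense heuristic: returns the supersense(s)
#' of the top-ranked sense group of the token (ties among equally frequent
#' senses give the union of their supersenses). Out-of-lexicon tokens
#' return the empty set and thus cannot pass supersense filtering unless
#' they are extended tokens, which bypass filtering altogether.
#'
#' @param token a single token string.
#' @param lex a `vf_lexicon`.
#' @return Character vector of supersense tags (possibly empty).
#' @examples
#' lex <- lexicon("husband", "NOUN", "noun.person")
#' most_frequent_supersenses("husband", lex)
#' @export
most_frequent_supersenses <- function(token, lex) {
  stopifnot(is.character(token), length(token) == 1L)
  i <- unname(lex$index[token])
  if (is.na(i)) return(character(0))
  lex$groups[[i]][[1L]]
}
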