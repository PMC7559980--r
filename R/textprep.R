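#' Normalize punctuation and whitespace in a raw narrative
#'
#' Lowercases the text, collapses runs of whitespace to a single space,
#' inserts a missing space after sentence punctuation (`. , ; : ! ?`) when it
#' is directly followed by a letter, and strips leading/trailing whitespace.
#' This is the first cleaning stage for emergency-room narratives, which are
#' typically typed in a hurry ("trauma,head", doubled spaces, stray
#' newlines). Unmatched brackets are left untouched; punctuation is removed
#' later, at tokenization.
#'
#' The function is total (any string, including `""`) and a projection:
#' applying it twice gives the same result as applying it once.
#'
#' @param text character vector of raw narratives.
#' @return Character vector of normalized, lowercased narratives.
#' @examples
#' normalize_punctuation("Trauma,head  and   neck")
#' @export
normalize_punctuation <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  out <- gsub("[[:space:]]+", " ", out)
  # "trauma,head" -> "trauma, head"; digit contexts (3.5) left alone
  out <- gsub("([.,;:!?])(?=[[:alpha:]])", "\\1 ", out, perl = TRUE)
  trimws(out)
}

#' Read a rewrite dictionary from TSV
#'
#' The dictionary drives abbreviation/acronym/typo expansion during
#' cleaning. The TSV has columns `surface`, `expansion`, `kind`
#' (one of `abbreviation`, `acronym`, `typo`); `#` starts a comment line.
#' Surfaces and expansions are lowercased on load.
#'
#' @param path path to a UTF-8 TSV file; defaults to the fixture dictionary
#'   shipped with the package.
#' @return A `vf_dictionary` object (data frame with columns `surface`,
#'   `expansion`, `kind`), validated by [validate_dictionary()].
#' @seealso [apply_rewrites()]
#' @export
read_rewrite_dictionary <- function(path = system.file("extdata", "rewrite_dictionary.tsv",
                                                       package = "violframe")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("malformed dictionary line(s): ", paste(which(bad), collapse = ", "))
  }
  d <- data.frame(
    surface   = tolower(trimws(vapply(parts, `[[`, "", 1L))),
    expansion = tolower(trimws(vapply(parts, `[[`, "", 2L))),
    kind      = vapply(parts, function(p) if (length(p) >= 3L) trimws(p[[3L]]) else "abbreviation", ""),
    stringsAsFactors = FALSE
  )
  if (nrow(d) > 0 && d$surface[1] == "surface") d <- d[-1L, , drop = FALSE]  # header row
  rownames(d) <- NULL
  rewrite_dictionary(d$surface, d$expansion, d$kind)
}

#' Construct a rewrite dictionary from vectors
#'
#' @param surface,expansion,kind character vectors of equal length; `kind`
#'   entries must be `abbreviation`, `acronym` or `typo`.
#' @return A validated `vf_dictionary`.
#' @export
rewrite_dictionary <- function(surface, expansion, kind = rep("abbreviation", length(surface))) {
  d <- data.frame(
    surface = tolower(as.character(surface)),
    expansion = tolower(as.character(expansion)),
    kind = as.character(kind),
    stringsAsFactors = FALSE
  )
  class(d) <- c("vf_dictionary", "data.frame")
  validate_dictionary(d)
  d
}

#' Validate a rewrite dictionary
#'
#' Enforces the invariants that make single-pass rewriting idempotent:
#' surfaces contain no whitespace, are unique and non-empty, `kind` is one
#' of the three recognized labels, and no whole token of any expansion
#' equals any surface form (this rules out self-maps like
#' `tr -> tr cranico` as well as chains like `a -> b`, `b -> c`, either of
#' which would make a second rewriting pass differ from the first).
#'
#' @param dict a `vf_dictionary`.
#' @return `dict`, invisibly, if valid; otherwise signals a configuration
#'   error.
#' @export
validate_dictionary <- function(dict) {
  stopifnot(is.data.frame(dict))
  if (!all(c("surface", "expansion", "kind") %in% names(dict))) {
    stop("dictionary must have columns surface, expansion, kind")
  }
  if (nrow(dict) == 0L) return(invisible(dict))
  if (any(!nzchar(dict$surface))) stop("empty surface form in dictionary")
  if (any(grepl("[[:space:]]", dict$surface))) {
    stop("surface forms must not contain whitespace")
  }
  if (anyDuplicated(dict$surface)) {
    stop("duplicate surface forms: ",
         paste(unique(dict$surface[duplicated(dict$surface)]), collapse = ", "))
  }
  if (!all(dict$kind %in% c("abbreviation", "acronym", "typo"))) {
    stop("kind must be abbreviation, acronym or typo")
  }
  exp_tokens <- unique(unlist(strsplit(dict$expansion, "[[:space:]]+")))
  clash <- intersect(exp_tokens, dict$surface)
  if (length(clash) > 0L) {
    stop("expansion token(s) equal to a surface form (breaks idempotence): ",
         paste(clash, collapse = ", "))
  }
  invisible(dict)
}

#' Expand abbreviations, acronyms and typos in a normalized narrative
#'
#' Replaces every whole-token occurrence of a dictionary surface form with
#' its expansion; tokens absent from the dictionary are left verbatim
#' (e.g. an unlisted abbreviation like "aass" stays as it is, and will later
#' fail embedding lookup rather than corrupt the text). Matching is
#' case-insensitive and on word boundaries only, never substrings, so "dx"
#' is expanded but a word merely containing "dx" is not.
#'
#' Applying the operation twice equals applying it once; this idempotence is
#' guaranteed by the dictionary invariants (see [validate_dictionary()]).
#'
#' @param text character vector, already passed through
#'   [normalize_punctuation()].
#' @param dict a `vf_dictionary`.
#' @return A list with `text` (rewritten character vector) and
#'   `n_substitutions` (total replaced occurrences across the vector).
#' @examples
#' d <- rewrite_dictionary("tr", "trauma")
#' apply_rewrites("tr cranico", d)
#' @export
apply_rewrites <- function(text, dict) {
  stopifnot(is.character(text))
  validate_dictionary(dict)
  n_sub <- 0L
  if (nrow(dict) > 0L) {
    for (i in seq_len(nrow(dict))) {
      pat <- paste0("\\b", .regex_escape(dict$surface[i]), "\\b")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)
      n_sub <- n_sub + sum(vapply(m, function(x) sum(x > 0L), 0L))
      text <- gsub(pat, dict$expansion[i], text, perl = TRUE, ignore.case = TRUE)
    }
  }
  list(text = text, n_substitutions = n_sub)
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Tokenize a cleaned narrative
#'
#' Removes punctuation (everything except letters, digits and underscore)
#' and splits on whitespace. Empty tokens never occur in the output.
#'
#' @param text a single character string.
#' @return A `vf_tokens` object: character vector of surfaces with a logical
#'   `extended` attribute (all `FALSE` here; see [mark_extended_tokens()]).
#' @examples
#' tokenize("blunt trauma (fist)")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("[^[:alnum:]_]+", " ", text)
  toks <- strsplit(trimws(stripped), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  token_sequence(toks, rep(FALSE, length(toks)))
}

#' Build a token sequence
#'
#' @param tokens character vector of non-empty surfaces.
#' @param extended logical vector marking multiword extended tokens.
#' @return A `vf_tokens` object.
#' @export
token_sequence <- function(tokens, extended = grepl("_", tokens, fixed = TRUE)) {
  tokens <- as.character(tokens)
  stopifnot(all(nzchar(tokens)), length(extended) == length(tokens))
  structure(tokens, extended = as.logical(extended), class = "vf_tokens")
}

#' @export
print.vf_tokens <- function(x, ...) {
  marks <- ifelse(attr(x, "extended"), "*", "")
  cat(paste0(unclass(x), marks, collapse = " "), "\n")
  invisible(x)
}

#' Merge known multiword locutions into extended tokens
#'
#' Scans the sequence left to right and merges the longest listed multiword
#' expression starting at each position into a single token whose words are
#' joined by underscore (e.g. "known person" becomes `known_person`), marked
#' as extended. Extended tokens later bypass PoS/supersense pruning during
#' frame filling. The concatenation of surfaces is preserved modulo the
#' joining character.
#'
#' @param seq a `vf_tokens` sequence.
#' @param mwe_list character vector of multiword expressions, each at least
#'   two whitespace-separated words.
#' @return A `vf_tokens` sequence with locutions merged.
#' @examples
#' mark_extended_tokens(tokenize("hit by known person"), "known person")
#' @export
mark_extended_tokens <- function(seq, mwe_list) {
  toks <- as.character(seq)
  ext <- attr(seq, "extended")
  if (is.null(ext)) ext <- rep(FALSE, length(toks))
  mwe_list <- tolower(trimws(mwe_list))
  mwe_list <- mwe_list[nzchar(mwe_list)]
  if (length(mwe_list) == 0L || length(toks) == 0L) {
    return(token_sequence(toks, ext))
  }
  mwe_words <- strsplit(mwe_list, "[[:space:]]+")
  if (any(lengths(mwe_words) < 2L)) {
    stop("every multiword expression must have at least two words")
  }
  mwe_words <- mwe_words[order(-lengths(mwe_words))]  # longest match wins
  out_tok <- character(0)
  out_ext <- logical(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    matched <- 0L
    for (w in mwe_words) {
      k <- length(w)
      if (i + k - 1L <= n && identical(toks[i:(i + k - 1L)], w)) {
        matched <- k
        break
      }
    }
    if (matched > 0L) {
      out_tok <- c(out_tok, paste(toks[i:(i + matched - 1L)], collapse = "_"))
      out_ext <- c(out_ext, TRUE)
      i <- i + matched
    } else {
      out_tok <- c(out_tok, toks[i])
      out_ext <- c(out_ext, ext[i])
      i <- i + 1L
    }
  }
  token_sequence(out_tok, out_ext)
}

#' Read the default multiword-expression list
#'
#' One expression per line; `#` comments allowed.
#'
#' @param path path to the list; defaults to the shipped fixture.
#' @return Character vector of multiword expressions.
#' @export
read_mwe_list <- function(path = system.file("extdata", "mwe_list.txt",
                                             package = "violframe")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines[nzchar(lines)]
}

#' Full cleaning stage: normalize, rewrite, report
#'
#' Convenience wrapper running [normalize_punctuation()] then
#' [apply_rewrites()] over a vector of narratives.
#'
#' @param text character vector of raw narratives.
#' @param dict a `vf_dictionary`.
#' @return List with `text` (cleaned narratives) and `n_substitutions`.
#' @export
clean_text <- function(text, dict = read_rewrite_dictionary()) {
  apply_rewrites(normalize_punctuation(text), dict)
}
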