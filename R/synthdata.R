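#' Default per-field gold fill probabilities
#'
#' Probability that a violence record mentions each frame slot, matching
#' the per-slot annotation frequencies observed in real emergency-room
#' violence reports (agent mentioned in 60% of records, mode/instrument in
#' 97%, time in 23.5%, location in 8%, body part in 89.5%, lesion type in
#' 86.5%).
#'
#' @export
DEFAULT_FILL_RATES <- c(
  AGENT = 0.60, MODE_INSTRUMENT = 0.97, TIME = 0.235,
  LOCATION = 0.08, BODY_PART = 0.895, LESION_TYPE = 0.865
)

#' Default filler inventories
#'
#' Per-field token lists used to instantiate templates; every token exists
#' in the fixture lexicon with a PoS/supersense compatible with its field
#' (the extended token `known_person` bypasses tagging by design).
#'
#' @export
DEFAULT_INVENTORIES <- list(
  AGENT = c("husband", "wife", "neighbor", "stranger", "brother",
            "colleague", "known_person"),
  MODE_INSTRUMENT = c("punch", "kick", "knife", "stick", "bottle",
                      "belt", "aggression"),
  TIME = c("evening", "night", "morning", "afternoon", "yesterday", "today"),
  LOCATION = c("home", "workplace", "street", "school", "park", "bar"),
  BODY_PART = c("arm", "head", "shoulder", "leg", "face", "wrist", "chest"),
  LESION_TYPE = c("fracture", "contusion", "trauma", "wound", "bruise",
                  "laceration")
)

# Templates are segment vectors; a segment containing "@FIELD" is emitted
# only when that slot is filled, with the placeholder replaced by the
# sampled filler. Violence templates carry assault vocabulary absent from
# the non-violence ones, which describe accidental injuries.
DEFAULT_V_TEMPLATES <- list(
  c("@TIME", "the patient was assaulted", "by her @AGENT", "with a @MODE_INSTRUMENT",
    "at the @LOCATION", "causing @LESION_TYPE", "of the @BODY_PART"),
  c("patient states she was attacked", "by a @AGENT", "@TIME",
    "at the @LOCATION", "suffered @LESION_TYPE", "to the @BODY_PART",
    "with a @MODE_INSTRUMENT"),
  c("beaten", "by her @AGENT", "with a @MODE_INSTRUMENT", "@TIME",
    "at the @LOCATION", "reports @LESION_TYPE", "on the @BODY_PART"),
  c("victim of assault", "by a @AGENT", "@TIME", "at the @LOCATION",
    "presents @LESION_TYPE", "of the @BODY_PART", "after a @MODE_INSTRUMENT")
)

DEFAULT_NV_TEMPLATES <- list(
  c("@TIME", "the patient fell from a ladder", "at the @LOCATION",
    "causing @LESION_TYPE", "of the @BODY_PART"),
  c("patient slipped on the stairs", "@TIME", "at the @LOCATION",
    "reports @LESION_TYPE", "to the @BODY_PART"),
  c("accidental injury while cooking", "@TIME", "suffered @LESION_TYPE",
    "of the @BODY_PART"),
  c("sports accident during training", "@TIME", "at the @LOCATION",
    "presents @LESION_TYPE", "on the @BODY_PART")
)

#' Synthetic-corpus generator configuration
#'
#' Fixes the study conditions under which the pipeline is exercised: corpus
#' size, the 3.36% violence prevalence of real ER surveillance data (class
#' counts are allocated by exact quota, not per-record coin flips, so the
#' count is deterministic), per-field gold fill probabilities, filler
#' inventories consistent with the fixture lexicon, and the noise channel
#' (abbreviation injection through the rewrite dictionary used in reverse
#' with a steep Zipfian preference for its most frequent entries, plus
#' character-level typos and whitespace/punctuation jitter).
#'
#' @param n_records corpus size.
#' @param violence_prevalence fraction of V records (default 0.0336).
#' @param abbrev_rate probability scale of replacing a dictionary expansion
#'   with its abbreviation (default 0.5; the effective probability of entry
#'   ranked r is `abbrev_rate / r`).
#' @param typo_rate per-token probability of one character-level typo
#'   (default 0.02).
#' @param space_noise_rate per-record probability of duplicated whitespace
#'   (default 0.1).
#' @param dictionary a `vf_dictionary` used in reverse by the noise
#'   injector.
#' @param fill_rates named per-field fill probabilities
#'   (default [DEFAULT_FILL_RATES]).
#' @param inventories named per-field filler lists
#'   (default [DEFAULT_INVENTORIES]).
#' @param v_templates,nv_templates template sets (see package source for
#'   the segment format).
#' @param lexicon_check optional `vf_lexicon`; when supplied, every
#'   non-extended inventory token must be present in it (configuration
#'   error otherwise).
#' @param seed integer seed.
#' @return A `vf_generator_config`.
#' @export
generator_config <- function(n_records, violence_prevalence = 0.0336,
                             abbrev_rate = 0.5, typo_rate = 0.02,
                             space_noise_rate = 0.1,
                             dictionary = read_rewrite_dictionary(),
                             fill_rates = DEFAULT_FILL_RATES,
                             inventories = DEFAULT_INVENTORIES,
                             v_templates = DEFAULT_V_TEMPLATES,
                             nv_templates = DEFAULT_NV_TEMPLATES,
                             lexicon_check = NULL, seed = 1L) {
  stopifnot(n_records >= 1,
            violence_prevalence > 0, violence_prevalence < 1,
            abbrev_rate >= 0, abbrev_rate <= 1,
            typo_rate >= 0, typo_rate <= 1)
  if (!setequal(names(fill_rates), FRAME_FIELDS)) {
    stop("fill_rates must name exactly the six frame fields")
  }
  if (!is.null(lexicon_check)) {
    for (f in FRAME_FIELDS) {
      toks <- inventories[[f]]
      plain <- toks[!grepl("_", toks, fixed = TRUE)]
      missing <- plain[!(plain %in% lexicon_check$entries$lemma)]
      if (length(missing) > 0L) {
        stop("inventory token(s) absent from lexicon: ",
             paste(missing, collapse = ", "))
      }
    }
  }
  structure(list(n_records = as.integer(n_records),
                 violence_prevalence = violence_prevalence,
                 abbrev_rate = abbrev_rate, typo_rate = typo_rate,
                 space_noise_rate = space_noise_rate,
                 dictionary = dictionary, fill_rates = fill_rates,
                 inventories = inventories, v_templates = v_templates,
                 nv_templates = nv_templates, seed = as.integer(seed)),
            class = "vf_generator_config")
}

.instantiate <- function(template, fills) {
  out <- character(0)
  for (seg in template) {
    m <- regmatches(seg, regexpr("@[A-Z_]+", seg))
    if (length(m) == 0L) {
      out <- c(out, seg)
    } else {
      f <- sub("^@", "", m)
      if (!is.null(fills[[f]])) {
        surface <- gsub("_", " ", fills[[f]], fixed = TRUE)
        out <- c(out, sub(m, surface, seg, fixed = TRUE))
      }
    }
  }
  paste(out, collapse = " ")
}

#' Inject realistic noise into a clean narrative
#'
#' Emulates the error profile of hurriedly typed ER reports: dictionary
#' expansions are replaced by their abbreviated surface forms (the rewrite
#' dictionary used in reverse; entry ranked r in the dictionary is injected
#' with probability `abbrev_rate / r`, giving the steep Zipfian profile of
#' real out-of-vocabulary terms), whitespace may be duplicated, and tokens
#' may receive one character-level typo (adjacent transposition, deletion
#' or duplication). Abbreviation injection is exactly inverted by
#' [apply_rewrites()]; typo events are returned so tests can condition on
#' them. Deterministic under the caller's RNG state.
#'
#' @param text a clean, lowercase, single-spaced narrative.
#' @param cfg a `vf_generator_config`.
#' @return List with `text` (noisy narrative) and `typo_tokens` (tokens hit
#'   by a typo).
#' @export
inject_noise <- function(text, cfg) {
  d <- cfg$dictionary
  if (cfg$abbrev_rate > 0 && nrow(d) > 0L) {
    for (i in seq_len(nrow(d))) {
      p <- cfg$abbrev_rate / i
      pat <- paste0("\\b", .regex_escape(d$expansion[i]), "\\b")
      m <- gregexpr(pat, text, perl = TRUE)[[1L]]
      if (m[1L] > 0L) {
        hit <- stats::runif(length(m)) < p
        if (any(hit)) {
          # replace selected occurrences right-to-left to keep offsets valid
          lens <- attr(m, "match.length")
          for (j in rev(which(hit))) {
            text <- paste0(substr(text, 1L, m[j] - 1L), d$surface[i],
                           substring(text, m[j] + lens[j]))
          }
        }
      }
    }
  }
  typo_tokens <- character(0)
  if (cfg$typo_rate > 0) {
    toks <- strsplit(text, " ", fixed = TRUE)[[1L]]
    for (i in seq_along(toks)) {
      if (nchar(toks[i]) >= 3L && stats::runif(1) < cfg$typo_rate) {
        typo_tokens <- c(typo_tokens, toks[i])
        toks[i] <- .apply_typo(toks[i])
      }
    }
    text <- paste(toks, collapse = " ")
  }
  if (cfg$space_noise_rate > 0 && stats::runif(1) < cfg$space_noise_rate) {
    sp <- gregexpr(" ", text, fixed = TRUE)[[1L]]
    if (sp[1L] > 0L) {
      j <- sp[sample.int(length(sp), 1L)]
      text <- paste0(substr(text, 1L, j), " ", substring(text, j + 1L))
    }
  }
  list(text = text, typo_tokens = typo_tokens)
}

.apply_typo <- function(tok) {
  n <- nchar(tok)
  kind <- sample.int(3L, 1L)
  i <- sample.int(n - 1L, 1L)
  ch <- strsplit(tok, "")[[1L]]
  if (kind == 1L) {                      # transpose adjacent
    tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
  } else if (kind == 2L) {               # delete
    ch <- ch[-i]
  } else {                               # duplicate
    ch <- append(ch, ch[i], after = i)
  }
  paste(ch, collapse = "")
}

#' Generate a labeled synthetic ER-like corpus with gold frames
#'
#' Violence records instantiate a slot-bearing assault template with one
#' sampled filler per mentioned slot (slot mention follows the per-field
#' fill probabilities); non-violence records use accident templates sharing
#' the time/location/body/lesion vocabulary but none of the assault words.
#' Class counts follow the configured prevalence by exact quota. The gold
#' frame is recorded before noise injection; multiword fillers are stored
#' in underscore form (`known_person`) while the text spells them with a
#' space.
#'
#' @param cfg a [generator_config()].
#' @return A data frame (one row per record) with columns `id`, `text`
#'   (noisy narrative), `clean_text` (pre-noise narrative), `label`
#'   (`"V"`/`"NV"`), and list columns `gold_frame` (named list of gold
#'   filler vectors; `NULL` for NV records) and `typo_tokens`.
#' @export
generate_corpus <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_records
  n_v <- max(1L, round(n * cfg$violence_prevalence))
  labels <- rep("NV", n)
  labels[sample.int(n, n_v)] <- "V"
  ids <- sprintf("rec%05d", seq_len(n))
  clean <- character(n)
  gold <- vector("list", n)
  typos <- vector("list", n)
  noisy <- character(n)
  for (r in seq_len(n)) {
    if (labels[r] == "V") {
      tpl <- cfg$v_templates[[sample.int(length(cfg$v_templates), 1L)]]
      fills <- list()
      for (f in FRAME_FIELDS) {
        if (stats::runif(1) < cfg$fill_rates[[f]]) {
          inv <- cfg$inventories[[f]]
          fills[[f]] <- inv[sample.int(length(inv), 1L)]
        }
      }
      gold[[r]] <- lapply(fills, identity)
    } else {
      tpl <- cfg$nv_templates[[sample.int(length(cfg$nv_templates), 1L)]]
      fills <- list()
      for (f in c("TIME", "LOCATION", "BODY_PART", "LESION_TYPE")) {
        if (stats::runif(1) < cfg$fill_rates[[f]]) {
          inv <- cfg$inventories[[f]]
          fills[[f]] <- inv[sample.int(length(inv), 1L)]
        }
      }
      gold[r] <- list(NULL)
    }
    clean[r] <- .instantiate(tpl, fills)
    nz <- inject_noise(clean[r], cfg)
    noisy[r] <- nz$text
    typos[[r]] <- nz$typo_tokens
  }
  out <- data.frame(id = ids, text = noisy, clean_text = clean,
                    label = labels, stringsAsFactors = FALSE)
  out$gold_frame <- gold
  out$typo_tokens <- typos
  out
}
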