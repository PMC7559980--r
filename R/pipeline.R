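#' Run the full tracking pipeline on a set of records
#'
#' Wires the stages end to end: clean every narrative (punctuation
#' normalization + dictionary rewriting), categorize each record V/NV with
#' the trained classifier, and fill the violence frame for the records
#' labeled V only (the gating rule of the surveillance design; set
#' `explain_all = TRUE` to force explanation of every record). Output
#' preserves input order and is deterministic given the trained components
#' and seeds; run metadata (package version, seeds, schema threshold,
#' per-stage counters) is attached as an attribute and embedded when
#' writing JSONL.
#'
#' @param records data frame with `id` and `text` columns (raw narratives).
#' @param model a trained `vf_classifier`.
#' @param embeddings a `vf_embeddings`.
#' @param schema a `vf_frame_schema`.
#' @param lex a `vf_lexicon`.
#' @param dict a `vf_dictionary` for cleaning.
#' @param mwe_list multiword expressions merged before frame extraction.
#' @param baseline if `TRUE`, frames are extracted without PoS/supersense
#'   filtering (similarity-only baseline).
#' @param explain_all if `TRUE`, extract a frame for every record, not just
#'   the ones predicted V.
#' @return A `vf_pipeline_result`: data frame with columns `id`, `text`,
#'   `clean_text`, `probability`, `label` and list column `frame`
#'   (`NULL` for records without a frame), with attribute `meta`.
#' @export
run_pipeline <- function(records, model, embeddings, schema, lex,
                         dict = read_rewrite_dictionary(),
                         mwe_list = read_mwe_list(),
                         baseline = FALSE, explain_all = FALSE) {
  stopifnot(all(c("id", "text") %in% names(records)))
  cleaned <- clean_text(records$text, dict)
  preds <- predict_label(model, cleaned$text, ids = records$id)
  prototypes <- lapply(schema$fields, build_prototype, model = embeddings)
  frames <- vector("list", nrow(records))
  do_explain <- explain_all | preds$label == "V"
  for (r in which(do_explain)) {
    frames[[r]] <- extract_frame(cleaned$text[r], schema, embeddings, lex,
                                 mwe_list = mwe_list,
                                 use_filters = !baseline,
                                 prototypes = prototypes)
  }
  out <- data.frame(id = records$id, text = records$text,
                    clean_text = cleaned$text,
                    probability = preds$probability, label = preds$label,
                    stringsAsFactors = FALSE)
  out$frame <- frames
  attr(out, "meta") <- list(
    package_version = as.character(utils::packageVersion("violframe")),
    classifier_seed = model$cfg$seed,
    similarity_threshold = schema$similarity_threshold,
    baseline = baseline,
    counters = list(records_in = nrow(records),
                    substitutions_applied = cleaned$n_substitutions,
                    v_predictions = sum(preds$label == "V"),
                    frames_built = sum(!vapply(frames, is.null, logical(1))))
  )
  class(out) <- c("vf_pipeline_result", "data.frame")
  out
}

#' Write pipeline output to JSONL
#'
#' One object per record: `id`, `label`, `probability`, and for explained
#' records a `frame` map from field name to an array of
#' `{token, score}` fillers. The first line is a `meta` object carrying the
#' run metadata.
#'
#' @param result a `vf_pipeline_result` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_result <- function(result, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- attr(result, "meta")
  writeLines(jsonlite::toJSON(list(meta = meta), auto_unbox = TRUE, digits = NA), con)
  for (r in seq_len(nrow(result))) {
    obj <- list(id = result$id[r],
                label = result$label[r],
                probability = result$probability[r])
    fr <- result$frame[[r]]
    if (!is.null(fr)) {
      obj$frame <- lapply(unclass(fr)[names(fr)], function(df) {
        lapply(seq_len(nrow(df)), function(i) {
          list(token = df$token[i], score = df$score[i])
        })
      })
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
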