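#' Write records to JSONL
#'
#' One JSON object per line with fields `id`, `text` and, when present,
#' `label`, `clean_text`, `gold_frame` (field -> array of gold fillers).
#'
#' @param records data frame with at least `id` and `text` columns
#'   (list column `gold_frame` optional), e.g. from [generate_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in seq_len(nrow(records))) {
    obj <- list(id = records$id[r], text = records$text[r])
    for (col in c("clean_text", "label")) {
      if (col %in% names(records) && !is.na(records[[col]][r])) {
        obj[[col]] <- records[[col]][r]
      }
    }
    if ("gold_frame" %in% names(records) && !is.null(records$gold_frame[[r]])) {
      obj$gold_frame <- lapply(records$gold_frame[[r]], function(v) as.list(v))
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read records from JSONL or CSV
#'
#' JSONL: one object per line with `id`, `text`, optional `label`,
#' `clean_text`, `gold_frame`. CSV: columns `id`, `text`, optional `label`.
#' The format is chosen by file extension (`.csv` vs anything else).
#'
#' @param path input path.
#' @return Data frame with columns `id`, `text`, `label` (`NA` when
#'   absent) and list column `gold_frame`.
#' @export
read_records <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "text") %in% names(d))) stop("CSV needs id and text columns: ", path)
    if (!"label" %in% names(d)) d$label <- NA_character_
    d$gold_frame <- vector("list", nrow(d))
    return(d[, c("id", "text", "label", "gold_frame")])
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) stop("malformed JSON at ", path, " line ", i,
                                      ": ", conditionMessage(e)))
  })
  d <- data.frame(
    id = vapply(objs, function(o) as.character(o$id), ""),
    text = vapply(objs, function(o) if (is.null(o$text)) "" else as.character(o$text), ""),
    label = vapply(objs, function(o) if (is.null(o$label)) NA_character_ else as.character(o$label), ""),
    stringsAsFactors = FALSE
  )
  d$clean_text <- vapply(objs, function(o) {
    if (is.null(o$clean_text)) NA_character_ else as.character(o$clean_text)
  }, "")
  d$gold_frame <- lapply(objs, function(o) {
    if (is.null(o$gold_frame)) NULL
    else lapply(o$gold_frame, function(v) unlist(v, use.names = FALSE))
  })
  if (anyDuplicated(d$id)) stop("duplicate record ids in ", path)
  d
}
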