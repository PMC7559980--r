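#' Per-class precision, recall and F1 from aligned predictions
#'
#' Standard confusion-matrix metrics for the binary V/NV categorization.
#' Predictions and gold are joined on `id`; a mismatch in the id sets is a
#' data error.
#'
#' @param predictions data frame with columns `id`, `label`.
#' @param gold data frame with columns `id`, `label`.
#' @return A `vf_class_report`: list with `per_class` (data frame rows V,
#'   NV; columns precision, recall, f1) and `counts`
#'   (`tp`, `fp`, `tn`, `fn` with V as the positive class).
#' @export
classification_metrics <- function(predictions, gold) {
  pid <- as.character(predictions$id); gid <- as.character(gold$id)
  if (!setequal(pid, gid) || length(pid) != length(gid)) {
    stop("prediction and gold id sets differ")
  }
  pl <- predictions$label[match(gid, pid)]
  gl <- gold$label
  tp <- sum(pl == "V" & gl == "V")
  fp <- sum(pl == "V" & gl == "NV")
  tn <- sum(pl == "NV" & gl == "NV")
  fn <- sum(pl == "NV" & gl == "V")
  prf <- function(tp_, fp_, fn_) {
    p <- if (tp_ + fp_ > 0) tp_ / (tp_ + fp_) else 0
    r <- if (tp_ + fn_ > 0) tp_ / (tp_ + fn_) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per_class <- rbind(V = prf(tp, fp, fn), NV = prf(tn, fn, fp))
  structure(list(per_class = as.data.frame(per_class),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "vf_class_report")
}

#' @export
print.vf_class_report <- function(x, ...) {
  print(round(x$per_class, 3))
  cat("counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# gold/ranking pairs with non-empty gold; shared by the retrieval metrics
.eval_cases <- function(rankings, gold) {
  stopifnot(length(rankings) == length(gold))
  keep <- lengths(gold) > 0L
  list(rankings = rankings[keep], gold = gold[keep])
}

#' Mean average precision of ranked filler lists
#'
#' Average precision per case is computed over the returned ranking against
#' the gold filler set (a gold filler absent from the ranking contributes
#' zero), then averaged over the cases with non-empty gold. Matching is
#' exact string match after lowercasing.
#'
#' @param rankings list of character vectors, each a ranked candidate list
#'   (best first) for one (record, field) case.
#' @param gold list of character vectors of gold fillers, aligned with
#'   `rankings`; empty-gold cases are excluded from the denominator.
#' @return MAP in `[0, 1]` (`NaN` when no case has gold).
#' @export
map_score <- function(rankings, gold) {
  ec <- .eval_cases(rankings, gold)
  ap <- mapply(function(r, g) {
    r <- tolower(r); g <- unique(tolower(g))
    hit <- r %in% g
    if (!any(hit)) return(0)
    prec <- cumsum(hit)[hit] / which(hit)
    sum(prec) / length(g)
  }, ec$rankings, ec$gold)
  mean(ap)
}

#' Success at k
#'
#' Fraction of evaluated cases whose top-k ranking contains at least one
#' gold filler (S@1: "the first value was correct"; S@5: a correct value
#' among the first five).
#'
#' @inheritParams map_score
#' @param k cut-off rank (>= 1).
#' @return S@k in `[0, 1]`.
#' @export
success_at_k <- function(rankings, gold, k) {
  stopifnot(k >= 1)
  ec <- .eval_cases(rankings, gold)
  hits <- mapply(function(r, g) {
    any(tolower(utils::head(r, k)) %in% tolower(g))
  }, ec$rankings, ec$gold)
  mean(hits)
}

#' Recall at k
#'
#' Per case, the fraction of gold fillers returned among the first k
#' ranked values, averaged over cases with non-empty gold.
#'
#' @inheritParams map_score
#' @param k cut-off rank (default 5).
#' @return R@k in `[0, 1]`.
#' @export
recall_at_k <- function(rankings, gold, k = 5) {
  stopifnot(k >= 1)
  ec <- .eval_cases(rankings, gold)
  rec <- mapply(function(r, g) {
    g <- unique(tolower(g))
    length(intersect(tolower(utils::head(r, k)), g)) / length(g)
  }, ec$rankings, ec$gold)
  mean(rec)
}

#' Per-field ranked-retrieval report for frame extraction
#'
#' Computes MAP, S@1, S@5 and R@5 for each frame field from per-record
#' rankings and gold frames. Records whose gold set for a field is empty
#' are excluded from that field's denominator, so denominators differ
#' across fields as the per-field fill rates do.
#'
#' @param frames list of `vf_frame`s (with their `rankings` attribute), one
#'   per evaluated record.
#' @param gold_frames list of named lists: per field, a character vector of
#'   gold fillers (empty or absent = unfilled slot).
#' @param fields field names to report (default [FRAME_FIELDS]).
#' @return A `vf_field_report` data frame: one row per field, columns
#'   `field`, `n`, `map`, `s_at_1`, `s_at_5`, `r_at_5`.
#' @export
field_report <- function(frames, gold_frames, fields = FRAME_FIELDS) {
  stopifnot(length(frames) == length(gold_frames))
  rows <- lapply(fields, function(f) {
    rk <- lapply(frames, function(fr) attr(fr, "rankings")[[f]]$token)
    gd <- lapply(gold_frames, function(g) {
      v <- g[[f]]
      if (is.null(v)) character(0) else as.character(v)
    })
    n <- sum(lengths(gd) > 0L)
    data.frame(field = f, n = n,
               map = map_score(rk, gd),
               s_at_1 = success_at_k(rk, gd, 1),
               s_at_5 = success_at_k(rk, gd, 5),
               r_at_5 = recall_at_k(rk, gd, 5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vf_field_report", "data.frame")
  out
}
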