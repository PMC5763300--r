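#' Harmonic-mean F-score
#'
#' `f = 2pr / (p + r)`, defined as 0 when both precision and recall are 0.
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return The F-score as a fraction in \[0, 1\].
#' @examples
#' f_score(0.8222, 0.7255) # ~0.7708
#' @export
f_score <- function(precision, recall) {
  stopifnot(
    all(precision >= 0 & precision <= 1),
    all(recall >= 0 & recall <= 1)
  )
  ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall))
}

#' Score tagger output against a gold standard
#'
#' Matches predicted annotation spans against manually adjudicated gold
#' spans and computes precision, recall and F-score. Gold records labelled
#' `"negative"` mark spans adjudicated as *not* cell mentions (e.g. a
#' gene homonym): predictions landing on them are false positives. Each
#' positive gold span matches at most one prediction, assigned greedily
#' by position; `match_mode = "exact_span"` requires identical offsets,
#' `"overlap"` accepts any overlap.
#'
#' @param predicted An annotation tibble (`doc_id`, `start`, `end`).
#' @param gold A gold tibble (`doc_id`, `start`, `end`, `label` in
#'   positive/negative, optional `class_id`, optional `error_tag`).
#' @param match_mode `"exact_span"` or `"overlap"`.
#' @return A `tagger_eval` object; see [glance.tagger_eval()] for the
#'   metric row and [tidy.tagger_eval()] for the error breakdown.
#' @export
score_annotations <- function(predicted, gold,
                              match_mode = c("exact_span", "overlap")) {
  match_mode <- match.arg(match_mode)
  predicted <- tibble::as_tibble(predicted)
  gold <- tibble::as_tibble(gold)
  if (!"label" %in% names(gold)) gold$label <- "positive"
  if (!"error_tag" %in% names(gold)) gold$error_tag <- NA_character_
  stopifnot(all(gold$label %in% c("positive", "negative")))

  pos <- gold[gold$label == "positive", ]
  pos <- pos[order(pos$doc_id, pos$start, pos$end), ]
  pred <- predicted[order(predicted$doc_id, predicted$start,
    predicted$end), ]

  spans_match <- function(g, p) {
    if (g$doc_id != p$doc_id) return(FALSE)
    if (match_mode == "exact_span") {
      g$start == p$start && g$end == p$end
    } else {
      g$start < p$end && p$start < g$end
    }
  }
  pred_used <- rep(FALSE, nrow(pred))
  gold_hit <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(pred))) {
      if (pred_used[[j]]) next
      if (spans_match(pos[i, ], pred[j, ])) {
        pred_used[[j]] <- TRUE
        gold_hit[[i]] <- TRUE
        break
      }
    }
  }
  tp <- sum(gold_hit)
  fp <- sum(!pred_used)
  fn <- sum(!gold_hit)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)

  # error taxonomy breakdown: tags on missed positives (FN) and on
  # negative golds overlapped by a prediction (FP)
  fn_tags <- pos$error_tag[!gold_hit]
  neg <- gold[gold$label == "negative", ]
  fp_tagged <- character()
  if (nrow(neg) > 0 && any(!pred_used)) {
    leftover <- pred[!pred_used, ]
    for (k in seq_len(nrow(neg))) {
      hit <- any(
        leftover$doc_id == neg$doc_id[[k]] &
          leftover$start < neg$end[[k]] & neg$start[[k]] < leftover$end
      )
      if (hit) fp_tagged <- c(fp_tagged, neg$error_tag[[k]])
    }
  }

  structure(
    list(
      tp = tp, fp = fp, fn = fn,
      precision = precision, recall = recall,
      f_score = f_score(precision, recall),
      match_mode = match_mode,
      fn_tags = fn_tags, fp_tags = fp_tagged
    ),
    class = "tagger_eval"
  )
}

#' @export
print.tagger_eval <- function(x, ...) {
  cat(sprintf(
    "<tagger_eval> tp=%d fp=%d fn=%d | precision %.2f%% recall %.2f%% F %.2f%% (%s)\n",
    x$tp, x$fp, x$fn,
    100 * x$precision, 100 * x$recall, 100 * x$f_score, x$match_mode
  ))
  invisible(x)
}

#' Metric summary of a tagger evaluation
#'
#' @param x A [score_annotations()] result.
#' @param ... Unused.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @method glance tagger_eval
#' @export
glance.tagger_eval <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    precision = x$precision, recall = x$recall, f_score = x$f_score
  )
}

#' Error-taxonomy breakdown of a tagger evaluation
#'
#' Counts false positives and false negatives by the `error_tag`
#' categories attached to gold records (e.g. homonym, missing_synonym,
#' missing_class, boundary).
#'
#' @param x A [score_annotations()] result.
#' @param ... Unused.
#' @return A tibble `error_type` (fp/fn), `error_tag`, `n`.
#' @method tidy tagger_eval
#' @export
tidy.tagger_eval <- function(x, ...) {
  tb <- dplyr::bind_rows(
    tibble::tibble(error_type = "fn",
      error_tag = as.character(x$fn_tags %||% character())),
    tibble::tibble(error_type = "fp",
      error_tag = as.character(x$fp_tags %||% character()))
  )
  if (nrow(tb) == 0) {
    return(tibble::tibble(error_type = character(),
      error_tag = character(), n = integer()))
  }
  tb$error_tag[is.na(tb$error_tag)] <- "untagged"
  dplyr::count(tb, error_type, error_tag, name = "n")
}

#' Read / write gold-standard annotation TSV
#'
#' Columns: doc_id, start, end, class_id (may be empty), label
#' (positive/negative), error_tag (may be empty).
#'
#' @param path File path.
#' @return A gold tibble.
#' @export
read_gold_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
    stringsAsFactors = FALSE, na.strings = "")
  required <- c("doc_id", "start", "end", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("gold table missing column(s): ",
      paste(missing_cols, collapse = ", ")), class = "cellmine_format_error")
  }
  if (!"class_id" %in% names(df)) df$class_id <- NA_character_
  if (!"error_tag" %in% names(df)) df$error_tag <- NA_character_
  tibble::as_tibble(df)
}

#' @rdname read_gold_tsv
#' @param gold A gold tibble.
#' @export
write_gold_tsv <- function(gold, path) {
  na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- c(
    "doc_id\tstart\tend\tclass_id\tlabel\terror_tag",
    sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s",
      gold$doc_id, gold$start, gold$end,
      na_blank(gold$class_id), gold$label,
      na_blank(gold$error_tag %||% rep(NA, nrow(gold)))
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Sample sentences for manual evaluation
#'
#' Reproducibly samples sentences that either contain at least one
#' annotation or contain a keyword (case-insensitive) — the pool a manual
#' evaluation set is drawn from. Sampling is uniform without replacement
#' under the given seed (recorded on the result for provenance).
#'
#' @param corpus A corpus tibble (`doc_id`, `text`).
#' @param annotations An annotation tibble over the corpus.
#' @param keyword Keyword qualifying a sentence even without annotations,
#'   e.g. `"cell line"`.
#' @param n Number of sentences to draw.
#' @param seed Integer seed; the same seed yields the same sample.
#' @return A tibble `doc_id`, `start`, `end`, `text`, `n_annotations`,
#'   with attributes `seed` and `n_qualifying`. If fewer than `n`
#'   sentences qualify, all are returned with a warning.
#' @export
sample_sentences <- function(corpus, annotations, keyword, n, seed = 1L) {
  stopifnot(n >= 1)
  sent <- purrr::map2(corpus$text, corpus$doc_id, function(txt, id) {
    sp <- split_sentences_one(txt)
    if (nrow(sp) == 0) return(NULL)
    sp$doc_id <- id
    sp$text <- span_text(txt, sp$start, sp$end)
    sp
  })
  sent <- dplyr::bind_rows(sent)
  if (nrow(sent) == 0) {
    rlang::warn("no qualifying sentences")
    out <- tibble::tibble(doc_id = character(), start = integer(),
      end = integer(), text = character(), n_annotations = integer())
    attr(out, "seed") <- seed
    attr(out, "n_qualifying") <- 0L
    return(out)
  }
  sent$n_annotations <- purrr::pmap_int(
    sent[c("doc_id", "start", "end")],
    function(doc_id, start, end) {
      sum(annotations$doc_id == doc_id &
          annotations$start < end & start < annotations$end)
    }
  )
  has_kw <- stringi::stri_detect_fixed(
    sent$text, keyword,
    opts_fixed = stringi::stri_opts_fixed(case_insensitive = TRUE)
  )
  pool <- sent[sent$n_annotations > 0 | has_kw, ]
  n_q <- nrow(pool)
  if (n_q == 0) {
    rlang::warn("no qualifying sentences")
    out <- pool[c("doc_id", "start", "end", "text", "n_annotations")]
  } else if (n_q <= n) {
    if (n_q < n) {
      rlang::warn(sprintf("only %d qualifying sentences for n = %d", n_q, n))
    }
    out <- pool[c("doc_id", "start", "end", "text", "n_annotations")]
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    idx <- sample.int(n_q, n)
    out <- pool[sort(idx), c("doc_id", "start", "end", "text",
      "n_annotations")]
  }
  attr(out, "seed") <- seed
  attr(out, "n_qualifying") <- n_q
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
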