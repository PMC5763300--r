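#' Matching policy for the dictionary tagger
#'
#' Makes the recognition policy explicit and configurable. `case_mode`
#' governs how a lexicon surface is compared against text:
#'
#' * `"exact"` — byte-for-byte casing.
#' * `"case_insensitive"` — all surfaces matched ignoring case.
#' * `"smart"` — a surface is matched case-insensitively only when it
#'   contains a lowercase letter *and* is at least 6 characters long;
#'   short symbols ("MCF2", "HeLa") are matched exactly. This favours
#'   precision: it suppresses homonym false positives from casing
#'   variants of short gene-like codes while still letting long
#'   multiword terms ("natural killer cell") match in running text with
#'   natural capitalisation.
#'
#' `boundary` requires that a match is not flanked by letters or digits
#' (so "SMC" does not fire inside "SMCs"). `overlap_mode`
#' `"longest_leftmost"` scans left to right keeping the longest match at
#' each position and resuming after it; `"all"` keeps every match.
#' `match_plural` optionally also accepts surface + "s"/"es" at a
#' boundary (off by default). `expand_hyphens` additionally indexes
#' space<->hyphen variants of each surface ("HEK 293" / "HEK-293"),
#' off by default.
#'
#' @param case_mode One of `"smart"`, `"exact"`, `"case_insensitive"`.
#' @param boundary Require non-alphanumeric flanks?
#' @param overlap_mode One of `"longest_leftmost"`, `"all"`.
#' @param match_plural Also match trivial plural inflections?
#' @param expand_hyphens Index space/hyphen variants?
#' @return A `match_policy` list.
#' @export
match_policy <- function(case_mode = c("smart", "exact", "case_insensitive"),
                         boundary = TRUE,
                         overlap_mode = c("longest_leftmost", "all"),
                         match_plural = FALSE,
                         expand_hyphens = FALSE) {
  structure(
    list(
      case_mode = match.arg(case_mode),
      boundary = isTRUE(boundary),
      overlap_mode = match.arg(overlap_mode),
      match_plural = isTRUE(match_plural),
      expand_hyphens = isTRUE(expand_hyphens)
    ),
    class = "match_policy"
  )
}

# smart-case rule: case-insensitive iff the surface has a lowercase letter
# and is long enough not to be a symbol/code
smart_ci <- function(surface) {
  stringi::stri_detect_regex(surface, "\\p{Ll}") &
    stringi::stri_length(surface) >= 6
}

#' Compile a lexicon into a matcher
#'
#' Builds the pattern table a document is scanned with: one pattern per
#' distinct matchable surface, each carrying the union of class ids it can
#' denote and the per-pattern case sensitivity implied by the policy.
#'
#' @param lex A [refine()]d lexicon (non-empty).
#' @param policy A [match_policy()].
#' @param lexicon_id Tag recorded on every annotation this matcher
#'   produces, conventionally `"cell_type"` or `"cell_line"`.
#' @return A `cell_matcher` object.
#' @export
compile_matcher <- function(lex, policy = match_policy(),
                            lexicon_id = "cell_type") {
  stopifnot(inherits(lex, "lexicon"), inherits(policy, "match_policy"))
  if (nrow(lex$entries) == 0) {
    rlang::abort("cannot compile a matcher from an empty lexicon",
      class = "cellmine_config_error")
  }

  terms <- lex$terms
  terms$.key <- surface_key(terms$surface)
  if (policy$expand_hyphens) {
    sp <- terms
    sp$surface <- stringi::stri_replace_all_fixed(sp$surface, " ", "-")
    hy <- terms
    hy$surface <- stringi::stri_replace_all_fixed(hy$surface, "-", " ")
    extra <- dplyr::bind_rows(sp, hy)
    extra$.key <- surface_key(extra$surface)
    terms <- dplyr::distinct(dplyr::bind_rows(terms, extra))
  }

  ci_of <- function(surface) {
    switch(policy$case_mode,
      exact = rep(FALSE, length(surface)),
      case_insensitive = rep(TRUE, length(surface)),
      smart = smart_ci(surface)
    )
  }
  terms$.ci <- ci_of(terms$surface)

  # case-insensitive surfaces collapse to one pattern per normalized key;
  # case-sensitive ones keep each original casing as its own pattern
  ci_pat <- terms[terms$.ci, ] |>
    dplyr::group_by(.key) |>
    dplyr::summarise(
      pattern = surface[1],
      class_ids = list(sort(unique(class_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci = TRUE) |>
    dplyr::select(pattern, class_ids, ci)
  ex_pat <- terms[!terms$.ci, ] |>
    dplyr::group_by(pattern = surface) |>
    dplyr::summarise(class_ids = list(sort(unique(class_id))),
      .groups = "drop") |>
    dplyr::mutate(ci = FALSE)
  patterns <- dplyr::bind_rows(ci_pat, ex_pat)

  structure(
    list(patterns = patterns, policy = policy, lexicon_id = lexicon_id),
    class = "cell_matcher"
  )
}

#' @export
print.cell_matcher <- function(x, ...) {
  cat(sprintf(
    "<cell_matcher> %d patterns (%d case-insensitive), policy %s/%s, lexicon %s\n",
    nrow(x$patterns), sum(x$patterns$ci),
    x$policy$case_mode, x$policy$overlap_mode, x$lexicon_id
  ))
  invisible(x)
}

# locate every occurrence of one pattern in one text, 0-based half-open
locate_pattern <- function(text, pattern, ci) {
  loc <- stringi::stri_locate_all_fixed(
    text, pattern,
    overlap = TRUE,
    opts_fixed = stringi::stri_opts_fixed(case_insensitive = ci)
  )[[1]]
  if (is.na(loc[1, 1])) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = loc[, 1] - 1L, end = loc[, 2])
}

is_word_char <- function(ch) {
  !is.na(ch) & ch != "" & stringi::stri_detect_regex(ch, "[\\p{L}\\p{Nd}]")
}

#' Annotate one document with a compiled matcher
#'
#' Scans `text` for all lexicon surfaces, applies the boundary rule (a
#' match must not be flanked by letters or digits) and the overlap rule,
#' and returns annotation spans sorted by start offset. Offsets are
#' 0-based half-open into the normalized document text.
#'
#' @param text A single document text.
#' @param matcher A [compile_matcher()] result.
#' @param doc_id Document identifier recorded on each annotation.
#' @return An annotation tibble: `doc_id`, `start`, `end`, `surface`
#'   (matched text as it appears in the document), `class_ids` (list
#'   column), `lexicon_id`.
#' @export
annotate_text <- function(text, matcher, doc_id = "doc") {
  stopifnot(inherits(matcher, "cell_matcher"), length(text) == 1)
  empty <- tibble::tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), class_ids = list(), lexicon_id = character()
  )
  if (is.na(text) || text == "") return(empty)
  pol <- matcher$policy
  pat <- matcher$patterns

  hits <- purrr::pmap(
    list(pat$pattern, pat$class_ids, pat$ci),
    function(pattern, class_ids, ci) {
      loc <- locate_pattern(text, pattern, ci)
      if (nrow(loc) == 0) return(NULL)
      loc$class_ids <- rep(list(class_ids), nrow(loc))
      if (pol$match_plural) {
        for (suf in c("s", "es")) {
          locs <- locate_pattern(text, paste0(pattern, suf), ci)
          if (nrow(locs) > 0) {
            locs$class_ids <- rep(list(class_ids), nrow(locs))
            loc <- dplyr::bind_rows(loc, locs)
          }
        }
      }
      loc
    }
  )
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(empty)

  if (pol$boundary) {
    before <- stringi::stri_sub(text, hits$start, hits$start) # char at start-1 (1-based start)
    after <- stringi::stri_sub(text, hits$end + 1L, hits$end + 1L)
    keep <- !is_word_char(before) & !is_word_char(after)
    hits <- hits[keep, ]
    if (nrow(hits) == 0) return(empty)
  }

  # merge identical spans hit by several patterns (e.g. two casings)
  hits <- hits |>
    dplyr::group_by(start, end) |>
    dplyr::summarise(
      class_ids = list(sort(unique(unlist(class_ids)))),
      .groups = "drop"
    )

  if (pol$overlap_mode == "longest_leftmost") {
    hits <- hits[order(hits$start, -hits$end), ]
    cursor <- -1L
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (hits$start[[i]] >= cursor) {
        keep[[i]] <- TRUE
        cursor <- hits$end[[i]]
      }
    }
    hits <- hits[keep, ]
  } else {
    hits <- hits[order(hits$start, hits$end), ]
  }

  tibble::tibble(
    doc_id = doc_id,
    start = as.integer(hits$start),
    end = as.integer(hits$end),
    surface = span_text(text, hits$start, hits$end),
    class_ids = hits$class_ids,
    lexicon_id = matcher$lexicon_id
  )
}

#' Annotate a whole corpus
#'
#' @param corpus A corpus tibble (`doc_id`, `text`, optionally `year`).
#' @param matcher A [compile_matcher()] result, or a list of matchers
#'   (e.g. a cell-type and a cell-line dictionary) applied in turn.
#' @return An annotation tibble over all documents (see [annotate_text()]).
#' @export
annotate_corpus <- function(corpus, matcher) {
  matchers <- if (inherits(matcher, "cell_matcher")) list(matcher) else matcher
  out <- purrr::map(matchers, function(m) {
    dplyr::bind_rows(purrr::map2(
      corpus$text, corpus$doc_id,
      function(txt, id) annotate_text(txt, m, doc_id = id)
    ))
  })
  dplyr::bind_rows(out)
}

#' Distinct classes covered by a set of annotations
#'
#' The union of candidate class ids across annotations — the "classes
#' referred to in the literature" set that coverage statistics are
#' computed from.
#'
#' @param annotations An annotation tibble with a `class_ids` list column.
#' @return Character vector of distinct class ids.
#' @export
distinct_classes <- function(annotations) {
  ids <- unlist(annotations$class_ids, use.names = FALSE)
  if (is.null(ids)) return(character())
  sort(unique(ids))
}

#' Write annotations as TSV
#'
#' Columns: doc_id, start, end, surface, pipe-delimited class_ids,
#' lexicon_id.
#'
#' @param annotations An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  lines <- c(
    "doc_id\tstart\tend\tsurface\tclass_ids\tlexicon_id",
    sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s",
      annotations$doc_id, annotations$start, annotations$end,
      annotations$surface,
      purrr::map_chr(annotations$class_ids, paste, collapse = "|"),
      annotations$lexicon_id
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
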