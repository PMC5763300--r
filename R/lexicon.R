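#' Extract raw surface forms from an ontology
#'
#' Produces the raw term list a dictionary is compiled from: one row per
#' (label, class) and per (synonym, class) pair over the non-obsolete
#' classes. Surfaces are whitespace-normalized (runs collapsed, ends
#' trimmed) with original case preserved. The same surface may appear for
#' several classes (ambiguity) — e.g. "SMC" as an abbreviation shared
#' across entities — and is kept once per class here.
#'
#' @param onto An [ontology()].
#' @return A tibble with columns `surface`, `class_id`, `provenance`
#'   (`"label"` or `"synonym"`).
#' @export
extract_terms <- function(onto) {
  stopifnot(inherits(onto, "ontology"))
  cls <- onto$classes[!onto$classes$obsolete, ]
  labels <- tibble::tibble(
    surface = cls$label,
    class_id = cls$id,
    provenance = "label"
  )
  syns <- tibble::tibble(
    surface = unlist(cls$synonyms, use.names = FALSE) %||% character(),
    class_id = rep(cls$id, lengths(cls$synonyms)),
    provenance = "synonym"
  )
  out <- dplyr::bind_rows(labels, syns)
  out$surface <- normalize_ws(out$surface)
  out <- out[out$surface != "", ]
  dplyr::distinct(out)
}

#' Refinement configuration for dictionary compilation
#'
#' Controls the filters applied before a dictionary is used for tagging,
#' aiming for precision over recall: very short terms, digit-only terms
#' and generic terms are frequent false-positive sources. Defaults follow
#' the conventional thresholds for cell vocabularies: minimum 3 characters
#' for cell-type dictionaries and 4 for cell-line dictionaries (set
#' `min_length` accordingly).
#'
#' @param min_length Minimum surface length in characters (counting
#'   internal spaces and hyphens); surfaces shorter than this are removed.
#' @param stop_terms Character vector of generic terms to remove;
#'   comparison is case-insensitive on the normalized surface. Defaults to
#'   [default_stop_terms()].
#' @param drop_digit_only Remove surfaces containing no letters (e.g.
#'   "548", "2-2")?
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(min_length = 3,
                              stop_terms = default_stop_terms(),
                              drop_digit_only = TRUE) {
  stopifnot(is.numeric(min_length), min_length >= 1)
  structure(
    list(
      min_length = as.integer(min_length),
      stop_terms = surface_key(stop_terms),
      drop_digit_only = isTRUE(drop_digit_only)
    ),
    class = "refinement_config"
  )
}

#' Default generic-term stop list
#'
#' Generic surfaces that would match throughout the literature without
#' denoting a specific class. The shipped list holds the canonical
#' examples; extend it via a one-term-per-line stop-list file
#' ([read_stop_terms()]) for a given corpus.
#'
#' @return Character vector of stop terms.
#' @export
default_stop_terms <- function() {
  c("P1", "mouse cell", "cell line", "human", "mammalian")
}

#' Read a stop list from a one-term-per-line UTF-8 file
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of terms.
#' @export
read_stop_terms <- function(path) {
  lines <- stringi::stri_trim_both(
    readLines(path, encoding = "UTF-8", warn = FALSE)
  )
  lines[lines != "" & !stringi::stri_detect_regex(lines, "^#")]
}

#' Refine a raw term list into a tagging lexicon
#'
#' Applies the dictionary refinement filters and groups the surviving
#' terms by normalized surface (whitespace-collapsed, case-folded), merging
#' the class ids of ambiguous surfaces into one entry. Every removal is
#' logged with a reason — `digit_only`, `too_short` or `stop_term` (checked
#' in that order; a surface violating several predicates gets the first).
#'
#' @param terms A tibble as returned by [extract_terms()] (columns
#'   `surface`, `class_id`, `provenance`).
#' @param config A [refinement_config()].
#' @return A `lexicon` object: `entries` (one row per retained normalized
#'   surface with merged `class_ids`), `terms` (the retained raw rows,
#'   original casing), `removed` (surface, reason audit), `config`.
#' @export
refine <- function(terms, config = refinement_config()) {
  stopifnot(is.data.frame(terms), inherits(config, "refinement_config"))
  terms <- tibble::as_tibble(terms)
  terms$surface <- normalize_ws(terms$surface)
  terms <- terms[terms$surface != "", ]
  terms$.key <- surface_key(terms$surface)

  keys <- dplyr::distinct(terms[c(".key", "surface")], .key,
    .keep_all = TRUE)
  reason <- rep(NA_character_, nrow(keys))
  if (config$drop_digit_only) {
    reason[is.na(reason) & is_digit_only(keys$.key)] <- "digit_only"
  }
  reason[is.na(reason) &
      stringi::stri_length(keys$.key) < config$min_length] <- "too_short"
  reason[is.na(reason) & keys$.key %in% config$stop_terms] <- "stop_term"

  removed <- tibble::tibble(
    surface = keys$surface[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept_keys <- keys$.key[is.na(reason)]
  kept <- terms[terms$.key %in% kept_keys, ]

  entries <- kept |>
    dplyr::group_by(.key) |>
    dplyr::summarise(
      surface = surface[1],
      class_ids = list(sort(unique(class_id))),
      provenance = list(tibble::tibble(
        surface = surface, class_id = class_id, provenance = provenance
      )),
      .groups = "drop"
    ) |>
    dplyr::rename(key = ".key") |>
    dplyr::arrange(key)

  structure(
    list(
      entries = entries,
      terms = tibble::as_tibble(kept[c("surface", "class_id", "provenance")]),
      removed = removed,
      config = config
    ),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  s <- lexicon_stats(x)
  cat(sprintf(
    "<lexicon> %d surfaces over %d classes (%d surfaces removed by refinement)\n",
    s$term_count, s$distinct_class_count, nrow(x$removed)
  ))
  invisible(x)
}

#' Lexicon size statistics
#'
#' @param lex A [refine()]d lexicon.
#' @return A one-row tibble with `term_count` (distinct normalized
#'   surfaces) and `distinct_class_count` (distinct class ids across all
#'   entries).
#' @export
lexicon_stats <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  tibble::tibble(
    term_count = nrow(lex$entries),
    distinct_class_count = length(
      unique(unlist(lex$entries$class_ids, use.names = FALSE))
    )
  )
}

#' @method glance lexicon
#' @export
glance.lexicon <- function(x, ...) {
  dplyr::bind_cols(
    lexicon_stats(x),
    tibble::tibble(
      n_removed = nrow(x$removed),
      min_length = x$config$min_length
    )
  )
}

#' @method tidy lexicon
#' @export
tidy.lexicon <- function(x, ...) {
  x$entries
}

#' Write / read a lexicon as TSV
#'
#' Serialization: `surface`, pipe-delimited `class_ids`, pipe-delimited
#' `provenance` (aligned with class_ids). The removal audit can be written
#' alongside with [write_removed_tsv()].
#'
#' @param lex A lexicon.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lex, path) {
  prov <- purrr::map_chr(lex$entries$provenance, function(p) {
    paste(p$provenance[match(sort(unique(p$class_id)), p$class_id)],
      collapse = "|")
  })
  lines <- c(
    "surface\tclass_ids\tprovenance",
    sprintf(
      "%s\t%s\t%s",
      lex$entries$surface,
      purrr::map_chr(lex$entries$class_ids, paste, collapse = "|"),
      prov
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
write_removed_tsv <- function(lex, path) {
  lines <- c(
    "surface\treason",
    sprintf("%s\t%s", lex$removed$surface, lex$removed$reason)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Compile a lexicon straight from an ontology
#'
#' Convenience wrapper: [extract_terms()] then [refine()].
#'
#' @inheritParams extract_terms
#' @inheritParams refine
#' @return A lexicon.
#' @export
build_lexicon <- function(onto, config = refinement_config()) {
  refine(extract_terms(onto), config)
}
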