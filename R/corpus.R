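#' Read a JSONL document corpus
#'
#' One JSON object per line with fields `doc_id`, `year` (optional) and
#' `text`. Documents are returned in file order; a missing year is `NA`,
#' never zero.
#'
#' @param source Path to a JSONL file, or a character vector of lines.
#' @return A corpus tibble: `doc_id` (character), `year` (integer, `NA`
#'   when absent), `text` (character).
#' @export
read_corpus <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(stringi::stri_split_lines(source))
  }
  lines <- lines[stringi::stri_trim_both(lines) != ""]
  if (length(lines) == 0) {
    return(tibble::tibble(
      doc_id = character(), year = integer(), text = character()
    ))
  }
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) NULL
    )
    if (is.null(rec) || is.null(rec$doc_id) || is.null(rec$text)) {
      rlang::abort(paste0("malformed corpus record at line ", i),
        class = "cellmine_format_error")
    }
    tibble::tibble(
      doc_id = as.character(rec$doc_id),
      year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
      text = as.character(rec$text)
    )
  })
  out <- dplyr::bind_rows(recs)
  if (anyDuplicated(out$doc_id)) {
    rlang::abort(paste0(
      "duplicate doc_id in corpus: ", out$doc_id[duplicated(out$doc_id)][[1]]
    ), class = "cellmine_format_error")
  }
  out
}

#' Write a corpus tibble as JSONL
#'
#' Round-trips with [read_corpus()]: a `NA` year is omitted from the
#' record rather than written as null.
#'
#' @param corpus A corpus tibble (`doc_id`, `year`, `text`).
#' @param path Output path; if `NULL`, the lines are returned invisibly.
#' @return The lines, invisibly.
#' @export
write_corpus <- function(corpus, path = NULL) {
  lines <- purrr::pmap_chr(
    corpus[c("doc_id", "year", "text")],
    function(doc_id, year, text) {
      rec <- list(doc_id = doc_id)
      if (!is.na(year)) rec$year <- as.integer(year)
      rec$text <- text
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }
  )
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Read a JATS-style full-text article
#'
#' Extracts the plain-text content a tagger runs on from the journal
#' article XML used by full-text archives: `doc_id` from the first
#' `article-id`, `year` as the earliest year over all `pub-date` elements
#' (the earliest publication event), and `text` as title, abstract and
#' body paragraphs joined with single spaces, markup flattened. Reference
#' lists are excluded. Tables and full JATS fidelity are out of scope.
#'
#' @param source Path to an XML file or an XML string.
#' @return A one-row corpus tibble (`doc_id`, `year`, `text`).
#' @export
read_jats_lite <- function(source) {
  doc <- xml2::read_xml(source)
  id_node <- xml2::xml_find_first(doc, ".//article-id")
  if (inherits(id_node, "xml_missing")) {
    rlang::abort("JATS article has no article-id",
      class = "cellmine_format_error")
  }
  doc_id <- xml2::xml_text(id_node)

  years <- xml2::xml_find_all(doc, ".//pub-date/year")
  year <- if (length(years) == 0) {
    NA_integer_
  } else {
    suppressWarnings(min(as.integer(xml2::xml_text(years)), na.rm = TRUE))
  }

  txt_of <- function(xpath) {
    nodes <- xml2::xml_find_all(doc, xpath)
    normalize_ws(xml2::xml_text(nodes))
  }
  pieces <- c(
    txt_of(".//front//article-title"),
    txt_of(".//front//abstract//p"),
    txt_of(".//body//p[not(ancestor::ref-list)]")
  )
  pieces <- pieces[pieces != ""]
  tibble::tibble(
    doc_id = doc_id,
    year = year,
    text = paste(pieces, collapse = " ")
  )
}

# Abbreviations that do not end a sentence even when followed by
# whitespace and an uppercase letter or digit.
sentence_guards <- c(
  "Fig.", "Figs.", "et al.", "e.g.", "i.e.", "cf.", "vs.", "ca.",
  "Dr.", "No.", "approx."
)

#' Split document text into sentence spans
#'
#' Deterministic rule-based splitting: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit, unless the
#' terminator closes a guarded abbreviation ("Fig.", "et al.", "e.g.",
#' ...). Exists to support evaluation sampling; the tagger itself runs on
#' full text. Offsets are 0-based half-open into `text`.
#'
#' @param text A character vector of document texts.
#' @return A list (one element per text) of tibbles with columns `start`,
#'   `end`: non-overlapping spans sorted by `start`.
#' @export
split_sentences <- function(text) {
  purrr::map(text, split_sentences_one)
}

split_sentences_one <- function(text) {
  empty <- tibble::tibble(start = integer(), end = integer())
  if (is.na(text) || stringi::stri_trim_both(text) == "") return(empty)
  n <- stringi::stri_length(text)

  cand <- stringi::stri_locate_all_regex(
    text, "[.!?](?=\\s+[\\p{Lu}\\p{Nd}])"
  )[[1]]
  breaks <- integer()
  if (!is.na(cand[1, 1])) {
    for (pos in cand[, 1]) {
      head_txt <- stringi::stri_sub(text, 1, pos)
      guarded <- any(stringi::stri_endswith_fixed(head_txt, sentence_guards))
      if (!guarded) breaks <- c(breaks, pos) # 1-based index of terminator
    }
  }
  # sentences span (prev break, next break]; trim surrounding whitespace
  bounds <- c(0L, breaks, n)
  spans <- purrr::map(seq_len(length(bounds) - 1), function(i) {
    lo <- bounds[[i]] + 1L  # 1-based start
    hi <- bounds[[i + 1]]
    seg <- stringi::stri_sub(text, lo, hi)
    lead <- stringi::stri_length(
      stringi::stri_match_first_regex(seg, "^\\s*")[1, 1]
    )
    trail <- stringi::stri_length(
      stringi::stri_match_first_regex(seg, "\\s*$")[1, 1]
    )
    s <- lo + lead
    e <- hi - trail
    if (s > e) return(NULL)
    tibble::tibble(start = s - 1L, end = as.integer(e)) # 0-based half-open
  })
  out <- dplyr::bind_rows(spans)
  if (nrow(out) == 0) empty else out
}
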