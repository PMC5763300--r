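#' Ontology class graphs
#'
#' An `ontology` is a queryable collection of classes (id, label, synonyms,
#' is_a parents, obsolescence flag) forming a directed acyclic graph under
#' the is_a relation. It is the substrate for lexicon compilation
#' ([extract_terms()]) and subclass-coverage statistics
#' ([class_representation()]).
#'
#' Only is_a edges are represented: the subclass statistics speak of
#' "subclasses", so other relationship types (develops_from, part_of, ...)
#' are ignored at parse time. Multiple parents are allowed (a DAG, not a
#' tree). Obsolete classes are retained in the graph but excluded from
#' closures and from dictionary extraction: they cannot be validly
#' annotated.
#'
#' @param classes A tibble with columns `id` (character), `label`
#'   (character), `synonyms` (list of character vectors), `parents` (list of
#'   character vectors), `obsolete` (logical).
#' @return An object of class `ontology`: the validated `classes` tibble
#'   plus a cached igraph of is_a edges (child -> parent).
#' @seealso [read_obo()], [read_term_table()], [subclasses()]
#' @export
ontology <- function(classes) {
  stopifnot(is.data.frame(classes))
  required <- c("id", "label", "synonyms", "parents", "obsolete")
  missing_cols <- setdiff(required, names(classes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "ontology classes table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "cellmine_format_error")
  }
  classes <- tibble::as_tibble(classes)[required]

  if (any(is.na(classes$id) | classes$id == "")) {
    rlang::abort("class ids must be non-empty", class = "cellmine_load_error")
  }
  dup <- classes$id[duplicated(classes$id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate class id: ", dup[[1]]),
      class = "cellmine_load_error")
  }
  bad_label <- !classes$obsolete & (is.na(classes$label) | classes$label == "")
  if (any(bad_label)) {
    rlang::abort(paste0(
      "non-obsolete class without a label: ", classes$id[bad_label][[1]]
    ), class = "cellmine_load_error")
  }
  all_parents <- unique(unlist(classes$parents, use.names = FALSE))
  dangling <- setdiff(all_parents, classes$id)
  if (length(dangling) > 0) {
    rlang::abort(paste0("is_a target not defined: ", dangling[[1]]),
      class = "cellmine_load_error")
  }

  edges <- tidyr::unnest(
    classes[c("id", "parents")],
    cols = "parents"
  )
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$id, to = edges$parents),
    directed = TRUE,
    vertices = data.frame(name = classes$id)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- if (length(cyc) > 0) {
      igraph::as_ids(igraph::head_of(g, cyc[[1]]))
    } else {
      "unknown"
    }
    rlang::abort(paste0("is_a cycle involving class: ", member),
      class = "cellmine_structure_error")
  }

  structure(
    list(classes = classes, graph = g),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  n <- nrow(x$classes)
  n_obs <- sum(x$classes$obsolete)
  cat(sprintf(
    "<ontology> %d classes (%d obsolete), %d roots\n",
    n, n_obs, length(ontology_roots(x))
  ))
  invisible(x)
}

#' Root classes of an ontology
#'
#' @param onto An [ontology()].
#' @return Character vector of ids with no is_a parents.
#' @export
ontology_roots <- function(onto) {
  onto$classes$id[lengths(onto$classes$parents) == 0]
}

#' Ids of non-obsolete classes
#'
#' @param onto An [ontology()].
#' @return Character vector of ids.
#' @export
active_classes <- function(onto) {
  onto$classes$id[!onto$classes$obsolete]
}

#' @method glance ontology
#' @export
glance.ontology <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_active = sum(!x$classes$obsolete),
    n_obsolete = sum(x$classes$obsolete),
    n_roots = length(ontology_roots(x)),
    n_synonyms = sum(lengths(x$classes$synonyms))
  )
}

#' @method tidy ontology
#' @export
tidy.ontology <- function(x, ...) {
  x$classes
}

#' Parse an OBO flat file into an ontology
#'
#' Reads the line-oriented OBO 1.4 subset used for exchanging ontologies
#' like the Cell Ontology: `[Term]` stanzas with `id`, `name`, `synonym`,
#' `is_a` and `is_obsolete` tags. Unknown tags and non-Term stanzas are
#' ignored. Synonym scope qualifiers (EXACT, RELATED, ...) and trailing
#' cross-references are stripped; the quoted synonym text is retained
#' verbatim.
#'
#' @param source Path to an OBO file, or a character vector of lines.
#' @return An [ontology()].
#' @examples
#' obo <- c(
#'   "[Term]", "id: CL_0000000", "name: cell", "",
#'   "[Term]", "id: CL_0000586", "name: germ cell",
#'   "synonym: \"gamete precursor\" EXACT []", "is_a: CL_0000000 ! cell"
#' )
#' onto <- read_obo(obo)
#' ontology_roots(onto)
#' @export
read_obo <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(stringi::stri_split_lines(source))
  }
  lines <- stringi::stri_trim_both(lines)

  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1]] <- cur
    terms
  }
  for (line in lines) {
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(synonyms = character(), parents = character(),
        obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (stringi::stri_detect_regex(line, "^\\[")) {
      # some other stanza type ([Typedef], ...)
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || line == "") next
    m <- stringi::stri_match_first_regex(line, "^([A-Za-z_]+):\\s*(.*)$")
    if (is.na(m[1, 1])) next
    tag <- m[1, 2]
    value <- m[1, 3]
    if (tag == "id") {
      cur$id <- value
    } else if (tag == "name") {
      cur$label <- value
    } else if (tag == "synonym") {
      syn <- stringi::stri_match_first_regex(value, "^\"(.*)\"")[1, 2]
      if (!is.na(syn)) cur$synonyms <- c(cur$synonyms, syn)
    } else if (tag == "is_a") {
      target <- stringi::stri_trim_both(
        stringi::stri_split_fixed(value, "!", n = 2)[[1]][1]
      )
      cur$parents <- c(cur$parents, target)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(value), "true")
    }
    # unknown tags ignored
  }
  terms <- flush(cur, terms)

  if (length(terms) == 0) {
    return(ontology(tibble::tibble(
      id = character(), label = character(),
      synonyms = list(), parents = list(), obsolete = logical()
    )))
  }
  ontology(tibble::tibble(
    id = purrr::map_chr(terms, "id"),
    label = purrr::map_chr(terms, ~ .x$label %||% NA_character_),
    synonyms = purrr::map(terms, "synonyms"),
    parents = purrr::map(terms, ~ unique(.x$parents)),
    obsolete = purrr::map_lgl(terms, "obsolete")
  ))
}

#' Parse a tab-separated term table into an ontology
#'
#' A plain-text fallback format equivalent to the supported OBO subset:
#' one row per class with columns `id`, `label`, `synonyms`
#' (pipe-delimited) and `parents` (pipe-delimited). Parsing the same
#' content as OBO or as a term table yields identical graphs.
#'
#' @param source Path to a TSV file, or a character vector of lines.
#' @return An [ontology()].
#' @export
read_term_table <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(stringi::stri_split_lines(source))
  }
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    rlang::abort("term table has no header row",
      class = "cellmine_format_error")
  }
  header <- stringi::stri_split_fixed(lines[[1]], "\t")[[1]]
  required <- c("id", "label", "synonyms", "parents")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "term table missing column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "cellmine_format_error")
  }
  split_pipe <- function(x) {
    if (is.na(x) || x == "") character() else
      stringi::stri_split_fixed(x, "|")[[1]]
  }
  rows <- stringi::stri_split_fixed(lines[-1], "\t")
  col <- function(name) {
    i <- match(name, header)
    purrr::map_chr(rows, ~ if (length(.x) >= i) .x[[i]] else "")
  }
  obsolete <- if ("obsolete" %in% header) {
    tolower(col("obsolete")) %in% c("true", "1", "yes")
  } else {
    rep(FALSE, length(rows))
  }
  ontology(tibble::tibble(
    id = col("id"),
    label = col("label"),
    synonyms = purrr::map(col("synonyms"), split_pipe),
    parents = purrr::map(col("parents"), split_pipe),
    obsolete = obsolete
  ))
}

#' Write an ontology as a term table
#'
#' @param onto An [ontology()].
#' @param path Output file path; if `NULL`, returns the lines invisibly.
#' @return The lines, invisibly.
#' @export
write_term_table <- function(onto, path = NULL) {
  join_pipe <- function(x) paste(x, collapse = "|")
  lines <- c(
    "id\tlabel\tsynonyms\tparents\tobsolete",
    sprintf(
      "%s\t%s\t%s\t%s\t%s",
      onto$classes$id,
      onto$classes$label,
      purrr::map_chr(onto$classes$synonyms, join_pipe),
      purrr::map_chr(onto$classes$parents, join_pipe),
      tolower(as.character(onto$classes$obsolete))
    )
  )
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Transitive subclasses of a class
#'
#' All classes reachable from `class_id` by inverted is_a edges, i.e. the
#' transitive subclass closure used as the denominator of the
#' class-representation statistic. Obsolete classes are traversed but
#' excluded from the result. Diamonds do not double-count: the closure is
#' a set.
#'
#' @param onto An [ontology()].
#' @param class_id A class identifier present in `onto`.
#' @param include_self Include `class_id` itself in the result?
#' @return Character vector of class ids (unordered set).
#' @export
subclasses <- function(onto, class_id, include_self = FALSE) {
  stopifnot(inherits(onto, "ontology"))
  if (!class_id %in% onto$classes$id) {
    rlang::abort(paste0("unknown class id: ", class_id),
      class = "cellmine_lookup_error")
  }
  # edges point child -> parent, so descendants are vertices that reach
  # class_id, i.e. mode = "in"
  reach <- igraph::as_ids(
    igraph::subcomponent(onto$graph, class_id, mode = "in")
  )
  out <- setdiff(reach, class_id)
  if (include_self) out <- c(class_id, out)
  obsolete_ids <- onto$classes$id[onto$classes$obsolete]
  setdiff(out, obsolete_ids)
}
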