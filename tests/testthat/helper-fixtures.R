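# Fixtures and independent oracles used across the suite.

chain_obo <- c(
  "[Term]", "id: A", "name: cell", "",
  "[Term]", "id: B", "name: native cell", "is_a: A ! cell", "",
  "[Term]", "id: C", "name: germ cell",
  "synonym: \"gamete precursor cell\" EXACT []",
  "is_a: B ! native cell"
)

chain_tsv <- c(
  "id\tlabel\tsynonyms\tparents",
  "A\tcell\t\t",
  "B\tnative cell\t\tA",
  "C\tgerm cell\tgamete precursor cell\tB"
)

diamond_onto <- function() {
  ontology(tibble::tibble(
    id = c("A", "B", "C", "D"),
    label = c("root cell", "left cell", "right cell", "leaf cell"),
    synonyms = list(character(), character(), character(), character()),
    parents = list(character(), "A", "A", c("B", "C")),
    obsolete = FALSE
  ))
}

# random is_a DAG on n nodes: node i may take parents among 1..(i-1)
random_dag_onto <- function(n, p_edge = 0.25) {
  parents <- vector("list", n)
  parents[[1]] <- character()
  ids <- sprintf("N%02d", seq_len(n))
  for (i in seq_len(n)[-1]) {
    ps <- which(stats::runif(i - 1) < p_edge)
    parents[[i]] <- ids[ps]
  }
  ontology(tibble::tibble(
    id = ids,
    label = paste("class", ids),
    synonyms = replicate(n, character(), simplify = FALSE),
    parents = parents,
    obsolete = FALSE
  ))
}

# oracle: transitive descendants by iterating edge expansion to fixpoint
reach_descendants <- function(onto, target) {
  cls <- onto$classes
  child_of <- function(ids) {
    cls$id[purrr::map_lgl(cls$parents, ~ any(.x %in% ids))]
  }
  acc <- character()
  frontier <- target
  repeat {
    nxt <- setdiff(child_of(frontier), acc)
    if (length(nxt) == 0) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

# oracle: all boundary-respecting matches by testing every
# (position, surface) pair with plain substring comparison
brute_matches <- function(text, surfaces, ci, boundary = TRUE) {
  n <- stringi::stri_length(text)
  out <- list()
  for (s_i in seq_along(surfaces)) {
    surf <- surfaces[[s_i]]
    len <- stringi::stri_length(surf)
    if (len == 0 || len > n) next
    for (pos in 0:(n - len)) { # 0-based start
      frag <- substr(text, pos + 1, pos + len)
      hit <- if (ci[[s_i]]) tolower(frag) == tolower(surf) else frag == surf
      if (!hit) next
      if (boundary) {
        before <- if (pos == 0) "" else substr(text, pos, pos)
        after <- if (pos + len >= n) "" else
          substr(text, pos + len + 1, pos + len + 1)
        wordish <- function(ch) ch != "" && grepl("[[:alnum:]]", ch)
        if (wordish(before) || wordish(after)) next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        start = pos, end = pos + len, surface_idx = s_i
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
      surface_idx = integer()))
  }
  dplyr::arrange(dplyr::distinct(res, start, end), start, end)
}

# oracle: greedy longest-leftmost reduction of a match set
greedy_reduce <- function(spans) {
  spans <- spans[order(spans$start, -spans$end), ]
  cursor <- -1
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    if (spans$start[[i]] >= cursor) {
      keep[[i]] <- TRUE
      cursor <- spans$end[[i]]
    }
  }
  spans[keep, ]
}

# oracle: maximum bipartite matching size between prediction and gold
# spans under exact-span equality, by brute force over assignments
max_matching_exact <- function(pred, gold) {
  if (nrow(pred) == 0 || nrow(gold) == 0) return(0L)
  best <- 0L
  recurse <- function(gi, used_pred, count) {
    if (gi > nrow(gold)) {
      best <<- max(best, count)
      return()
    }
    recurse(gi + 1, used_pred, count) # leave this gold unmatched
    for (pj in seq_len(nrow(pred))) {
      if (used_pred[[pj]]) next
      same <- gold$doc_id[[gi]] == pred$doc_id[[pj]] &&
        gold$start[[gi]] == pred$start[[pj]] &&
        gold$end[[gi]] == pred$end[[pj]]
      if (same) {
        used_pred[[pj]] <- TRUE
        recurse(gi + 1, used_pred, count + 1L)
        used_pred[[pj]] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nrow(pred)), 0L)
  best
}

span_texts <- function(text, spans) {
  purrr::map2_chr(spans$start, spans$end,
    ~ substr(text, .x + 1, .y))
}

# tiny lexicon straight from surface/class pairs
lexicon_from <- function(surface, class_id,
                         config = refinement_config(min_length = 1,
                           stop_terms = character(),
                           drop_digit_only = FALSE)) {
  refine(
    tibble::tibble(surface = surface, class_id = class_id,
      provenance = "label"),
    config
  )
}
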