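# Word pools for the surface grammar. Filler vocabulary is disjoint from
# every word that can occur in a generated surface, so a surface can never
# arise in filler text by chance: gold annotations are complete by
# construction (declared homonym distractors are the only exception).
syn_adjectives <- c(
  "basal", "luminal", "cortical", "medullary", "ciliated", "granular",
  "pigmented", "columnar", "squamous", "cuboidal", "dendritic", "mucosal",
  "serous", "germinal", "stellate", "fusiform", "multinucleated",
  "vacuolated", "keratinized", "myelinated"
)
syn_tissues <- c(
  "hepatic", "renal", "splenic", "gastric", "dermal", "retinal",
  "alveolar", "bronchial", "cardiac", "osseous", "neural", "thymic",
  "pancreatic", "ovarian", "testicular", "duodenal", "lingual",
  "tracheal", "adrenal", "synovial"
)
syn_fillers <- c(
  "the", "observed", "samples", "were", "cultured", "under", "standard",
  "conditions", "and", "analysed", "after", "incubation", "with",
  "reagent", "controls", "showing", "stable", "growth", "profiles",
  "during", "each", "passage", "experiments", "repeated", "independent",
  "measurements", "confirmed", "expression", "levels", "reported"
)

#' Specification for synthetic ontologies and corpora
#'
#' Bundles the knobs of the synthetic generator: a random is_a DAG with
#' labelled, synonym-bearing classes, and a yearly corpus with planted
#' class mentions and complete gold annotations. The defaults describe a
#' small but structurally realistic study: a 50-class ontology, moderate
#' synonymy, 10% ambiguous surfaces, 5% homonym surfaces, and a corpus
#' whose article count grows across years.
#'
#' @param n_classes Number of ontology classes.
#' @param max_depth Maximum is_a depth of the DAG.
#' @param synonyms_per_class Mean number of extra synonyms per class
#'   (Poisson).
#' @param ambiguity_rate Fraction of classes receiving a shared surface
#'   (one surface form mapping to two classes).
#' @param homonym_rate Fraction of classes whose code-style surface also
#'   occurs in text as a non-cell distractor (planted as a casing variant,
#'   the gene-name-versus-cell-line mechanism).
#' @param years Inclusive integer pair `c(from, to)`.
#' @param articles_per_year Integer vector, one entry per year.
#' @param planted_class_fraction Fraction of classes that are ever
#'   mentioned in the corpus (drawn without replacement, so the distinct
#'   planted-class count is exact).
#' @param mentions_per_article Mean planted mentions per article
#'   (Poisson; zero-mention articles are legitimate).
#' @param classes_per_year Optional integer vector (one per year): the
#'   planted-class pool available in each year is the first so-many
#'   planted classes, letting nomenclature usage grow more slowly than
#'   the literature. `NULL` = all planted classes available every year.
#' @param seed Integer seed governing all randomness of the generator.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 50,
                           max_depth = 4,
                           synonyms_per_class = 1.5,
                           ambiguity_rate = 0.1,
                           homonym_rate = 0.05,
                           years = c(2000, 2009),
                           articles_per_year = rep(20L, 10),
                           planted_class_fraction = 0.5,
                           mentions_per_article = 2,
                           classes_per_year = NULL,
                           seed = 42L) {
  n_years <- years[[2]] - years[[1]] + 1
  stopifnot(
    n_classes >= 1, max_depth >= 1,
    ambiguity_rate >= 0, ambiguity_rate <= 1,
    homonym_rate >= 0, homonym_rate <= 1,
    planted_class_fraction >= 0, planted_class_fraction <= 1,
    length(articles_per_year) == n_years,
    is.null(classes_per_year) || length(classes_per_year) == n_years
  )
  structure(
    list(
      n_classes = as.integer(n_classes),
      max_depth = as.integer(max_depth),
      synonyms_per_class = synonyms_per_class,
      ambiguity_rate = ambiguity_rate,
      homonym_rate = homonym_rate,
      years = as.integer(years),
      articles_per_year = as.integer(articles_per_year),
      planted_class_fraction = planted_class_fraction,
      mentions_per_article = mentions_per_article,
      classes_per_year = classes_per_year,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# unique code-style surface like "XQ-17B": uppercase + digits, length >= 5,
# no lowercase letter => matched exactly under smart case
make_codes <- function(n, taken = character()) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(
      paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
      "-", sample(10:99, 1), sample(LETTERS, 1)
    )
    if (!cand %in% c(out, taken)) out <- c(out, cand)
  }
  out
}

make_phrases <- function(n, taken = character()) {
  combos <- expand.grid(a = syn_adjectives, t = syn_tissues,
    stringsAsFactors = FALSE)
  all_p <- paste(combos$a, combos$t, "cell")
  avail <- setdiff(all_p, taken)
  if (length(avail) < n) {
    avail <- setdiff(
      c(avail, paste(combos$a, combos$t, "progenitor cell")), taken
    )
  }
  sample(avail, n)
}

#' Generate a synthetic ontology with lexicon ground truth
#'
#' Builds a random is_a DAG of `n_classes` classes (depth-bounded,
#' multiple parents allowed) whose labels alternate between multiword
#' lowercase phrases (cell-type-like) and alphanumeric codes
#' (cell-line-like). Classes receive extra synonyms; a controlled share
#' of surfaces is ambiguous (one surface, two classes), a share of code
#' surfaces is marked as homonyms for corpus distractors, and some
#' synonyms deliberately violate refinement filters (digit-only or
#' too-short) to exercise dictionary refinement. Labels always pass the
#' filters. Deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_ontology` list: `onto` (an [ontology()]),
#'   `truth` (tibble `surface`, `class_id`, `provenance`,
#'   `passes_filter`), `homonyms` (character vector of homonym surfaces),
#'   `spec`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_classes
  ids <- sprintf("SYN_%04d", seq_len(n))

  # labels: even index -> phrase, odd -> code; all filter-passing
  n_phrase <- ceiling(n / 2)
  phrases <- make_phrases(n_phrase)
  codes <- make_codes(n - n_phrase, taken = phrases)
  labels <- character(n)
  labels[seq(1, n, by = 2)] <- phrases
  if (n > 1) labels[seq(2, n, by = 2)] <- codes

  # random DAG: class i attaches to 1-2 earlier classes of depth < max
  depth <- integer(n)
  parents <- vector("list", n)
  parents[[1]] <- character()
  depth[[1]] <- 0L
  for (i in seq_len(n)[-1]) {
    if (stats::runif(1) < 0.05) { # occasional extra root
      parents[[i]] <- character()
      depth[[i]] <- 0L
      next
    }
    eligible <- which(depth[seq_len(i - 1)] < spec$max_depth - 1)
    if (length(eligible) == 0) eligible <- 1L
    k <- min(length(eligible), sample(1:2, 1))
    ps <- sample(eligible, k)
    parents[[i]] <- ids[ps]
    depth[[i]] <- max(depth[ps]) + 1L
  }

  # synonyms: filter-passing codes, plus deliberate filter violations
  syn_counts <- stats::rpois(n, spec$synonyms_per_class)
  synonyms <- vector("list", n)
  taken <- labels
  for (i in seq_len(n)) {
    k <- syn_counts[[i]]
    syns <- character()
    if (k > 0) {
      syns <- make_codes(k, taken = taken)
      taken <- c(taken, syns)
    }
    if (stats::runif(1) < 0.15) { # digit-only synonym, filtered later
      syns <- c(syns, as.character(sample(100:999, 1)))
    }
    if (stats::runif(1) < 0.15) { # too-short synonym, filtered later
      syns <- c(syns, paste0(sample(LETTERS, 1), sample(0:9, 1)))
    }
    synonyms[[i]] <- syns
  }

  # ambiguity: a shared surface added as synonym to two distinct classes
  n_amb <- round(spec$ambiguity_rate * n)
  amb_surfaces <- character()
  if (n_amb > 0 && n >= 2) {
    amb_surfaces <- make_codes(n_amb, taken = taken)
    taken <- c(taken, amb_surfaces)
    for (s in amb_surfaces) {
      pair <- sample(n, 2)
      synonyms[[pair[[1]]]] <- c(synonyms[[pair[[1]]]], s)
      synonyms[[pair[[2]]]] <- c(synonyms[[pair[[2]]]], s)
    }
  }

  onto <- ontology(tibble::tibble(
    id = ids, label = labels, synonyms = synonyms,
    parents = parents, obsolete = FALSE
  ))

  truth <- extract_terms(onto)
  cfg <- refinement_config(min_length = 3)
  keys <- surface_key(truth$surface)
  truth$passes_filter <- !is_digit_only(keys) &
    stringi::stri_length(keys) >= cfg$min_length &
    !keys %in% cfg$stop_terms

  # homonyms: code-style surfaces (no lowercase) that will also occur in
  # text as lowercased non-cell distractors
  n_hom <- round(spec$homonym_rate * n)
  code_pool <- unique(truth$surface[
    truth$passes_filter &
      !stringi::stri_detect_regex(truth$surface, "\\p{Ll}")
  ])
  homonyms <- if (n_hom > 0 && length(code_pool) > 0) {
    sample(code_pool, min(n_hom, length(code_pool)))
  } else {
    character()
  }

  structure(
    list(onto = onto, truth = truth, homonyms = homonyms, spec = spec),
    class = "synthetic_ontology"
  )
}

#' @export
print.synthetic_ontology <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ontology> %d classes, %d surfaces (%d filterable), %d homonyms, seed %d\n",
    nrow(x$onto$classes), length(unique(x$truth$surface)),
    length(unique(x$truth$surface[!x$truth$passes_filter])),
    length(x$homonyms), x$spec$seed
  ))
  invisible(x)
}

# build one document from mention surfaces + distractor surfaces,
# returning text and exact 0-based spans of each planted surface
compose_document <- function(mention_surfaces, distractor_surfaces = character()) {
  sentence_of <- function(surface) {
    pre <- sample(syn_fillers, sample(2:4, 1))
    post <- sample(syn_fillers, sample(1:3, 1))
    pre[[1]] <- stringi::stri_trans_totitle(pre[[1]])
    list(
      tokens = c(pre, surface, post),
      target_idx = length(pre) + 1L
    )
  }
  filler_sentence <- function() {
    toks <- sample(syn_fillers, sample(4:7, 1))
    toks[[1]] <- stringi::stri_trans_totitle(toks[[1]])
    list(tokens = toks, target_idx = NA_integer_)
  }

  planted <- c(
    lapply(mention_surfaces, sentence_of),
    lapply(distractor_surfaces, sentence_of)
  )
  kinds <- c(
    rep("mention", length(mention_surfaces)),
    rep("distractor", length(distractor_surfaces))
  )
  n_fill <- sample(1:2, 1)
  sentences <- c(planted, replicate(n_fill, filler_sentence(),
    simplify = FALSE))
  kinds <- c(kinds, rep("filler", n_fill))
  ord <- sample(length(sentences))
  sentences <- sentences[ord]
  kinds <- kinds[ord]

  pos <- 0L
  text_parts <- character(length(sentences))
  spans <- list()
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    toks <- s$tokens
    sent_txt <- paste0(paste(toks, collapse = " "), ".")
    if (!is.na(s$target_idx)) {
      offset_in_sent <- if (s$target_idx == 1) 0L else {
        stringi::stri_length(
          paste(toks[seq_len(s$target_idx - 1)], collapse = " ")
        ) + 1L
      }
      start <- pos + offset_in_sent
      end <- start + stringi::stri_length(toks[[s$target_idx]])
      spans[[length(spans) + 1]] <- tibble::tibble(
        start = start, end = end,
        surface = toks[[s$target_idx]], kind = kinds[[i]]
      )
    }
    text_parts[[i]] <- sent_txt
    pos <- pos + stringi::stri_length(sent_txt) + 1L # joining space
  }
  list(text = paste(text_parts, collapse = " "),
    spans = dplyr::bind_rows(spans))
}

#' Generate a synthetic corpus with gold annotations
#'
#' Produces, per year, the specified number of articles; each article
#' embeds a Poisson number of planted class mentions inside filler
#' sentences, with every planted span recorded in the gold standard at
#' exact character offsets. Mentions use only filter-passing surfaces of
#' the planted classes, cycled so that each available class is mentioned
#' whenever enough mention slots exist. Homonym distractors — lowercased
#' casing variants of homonym code surfaces — are inserted as
#' `label = "negative"` gold records (`error_tag = "homonym"`).
#' Deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param sonto A [generate_ontology()] result.
#' @return A `synthetic_corpus` list: `corpus` (corpus tibble), `gold`
#'   (gold tibble with `class_id`), `planted_classes` (character vector),
#'   `spec`.
#' @export
generate_corpus <- function(spec, sonto) {
  stopifnot(inherits(spec, "synthetic_spec"),
    inherits(sonto, "synthetic_ontology"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)

  ids <- sonto$onto$classes$id
  n_planted <- round(spec$planted_class_fraction * length(ids))
  planted <- sample(ids, n_planted)

  # filter-passing surfaces per planted class
  ok <- sonto$truth[sonto$truth$passes_filter &
      sonto$truth$class_id %in% planted, ]
  surfaces_of <- split(ok$surface, ok$class_id)

  years <- seq(spec$years[[1]], spec$years[[2]])
  gold <- list()
  docs <- list()
  doc_no <- 0L

  for (yi in seq_along(years)) {
    y <- years[[yi]]
    n_art <- spec$articles_per_year[[yi]]
    if (n_art == 0) next
    pool <- if (is.null(spec$classes_per_year)) {
      planted
    } else {
      planted[seq_len(min(spec$classes_per_year[[yi]], n_planted))]
    }
    counts <- stats::rpois(n_art, spec$mentions_per_article)
    total <- sum(counts)
    # cycle the pool over the year's mention slots: every pool class is
    # mentioned provided the year has at least |pool| mentions
    class_seq <- if (total > 0) {
      sample(rep(pool, length.out = max(total, length(pool)))[seq_len(total)])
    } else {
      character()
    }
    slot <- 1L
    for (a in seq_len(n_art)) {
      doc_no <- doc_no + 1L
      doc_id <- sprintf("doc%05d", doc_no)
      k <- counts[[a]]
      mention_classes <- if (k > 0) {
        class_seq[slot:(slot + k - 1)]
      } else {
        character()
      }
      slot <- slot + k
      mention_surfaces <- purrr::map_chr(mention_classes, function(cl) {
        opts <- surfaces_of[[cl]]
        if (is.null(opts)) sonto$onto$classes$label[match(cl, ids)]
        else sample(opts, 1)
      })
      distractors <- if (length(sonto$homonyms) > 0 &&
          stats::runif(1) < 0.3) {
        stringi::stri_trans_tolower(sample(sonto$homonyms, 1))
      } else {
        character()
      }
      made <- compose_document(mention_surfaces, distractors)
      docs[[doc_no]] <- tibble::tibble(
        doc_id = doc_id, year = y, text = made$text
      )
      if (nrow(made$spans) > 0) {
        sp <- made$spans
        # spans come back in sentence order; mention rows map to
        # mention_classes in planting order
        mrows <- which(sp$kind == "mention")
        cls <- rep(NA_character_, nrow(sp))
        # align classes by matching surfaces greedily
        remaining <- mention_classes
        rem_surf <- mention_surfaces
        for (r in mrows) {
          hit <- match(sp$surface[[r]], rem_surf)
          cls[[r]] <- remaining[[hit]]
          remaining <- remaining[-hit]
          rem_surf <- rem_surf[-hit]
        }
        gold[[length(gold) + 1]] <- tibble::tibble(
          doc_id = doc_id,
          start = sp$start, end = sp$end,
          class_id = cls,
          label = ifelse(sp$kind == "mention", "positive", "negative"),
          error_tag = ifelse(sp$kind == "mention", NA_character_,
            "homonym")
        )
      }
    }
  }

  structure(
    list(
      corpus = dplyr::bind_rows(docs),
      gold = dplyr::bind_rows(gold),
      planted_classes = sort(planted),
      spec = spec
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d documents, %d gold spans (%d positive), %d planted classes\n",
    nrow(x$corpus), nrow(x$gold), sum(x$gold$label == "positive"),
    length(x$planted_classes)
  ))
  invisible(x)
}
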