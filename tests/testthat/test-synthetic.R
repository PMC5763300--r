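test_that("synthetic ontology generation is deterministic and sized as specified", {
  spec <- synthetic_spec(n_classes = 30, seed = 7L,
    years = c(2000, 2002), articles_per_year = rep(5L, 3))
  g1 <- generate_ontology(spec)
  g2 <- generate_ontology(spec)
  expect_equal(g1$onto$classes, g2$onto$classes)
  expect_equal(g1$truth, g2$truth)
  expect_equal(nrow(g1$onto$classes), 30)

  single <- generate_ontology(synthetic_spec(n_classes = 1,
    years = c(2000, 2000), articles_per_year = 1L))
  expect_equal(ontology_roots(single$onto), single$onto$classes$id)
})

test_that("ambiguity rate controls the number of shared surfaces", {
  spec <- synthetic_spec(n_classes = 50, ambiguity_rate = 0.2,
    homonym_rate = 0, seed = 13L,
    years = c(2000, 2000), articles_per_year = 1L)
  g <- generate_ontology(spec)
  shared <- g$truth |>
    dplyr::count(surface) |>
    dplyr::filter(n >= 2)
  # 10 surfaces deliberately assigned to two classes each
  expect_equal(nrow(shared), 10)
})

test_that("generated labels pass refinement; planted filter-violations are caught", {
  g <- generate_ontology(synthetic_spec(n_classes = 40, seed = 3L,
    years = c(2000, 2000), articles_per_year = 1L))
  lex <- build_lexicon(g$onto)
  labels <- g$onto$classes$label
  expect_true(all(surface_key(labels) %in% lex$entries$key))

  bad <- unique(g$truth$surface[!g$truth$passes_filter])
  if (length(bad) > 0) {
    expect_true(all(surface_key(bad) %in% surface_key(lex$removed$surface)))
  }
})

test_that("corpus generation plants the exact distinct-class count with complete gold", {
  spec <- synthetic_spec(
    n_classes = 40, planted_class_fraction = 0.5,
    ambiguity_rate = 0, homonym_rate = 0,
    years = c(2000, 2003), articles_per_year = rep(15L, 4),
    mentions_per_article = 3, seed = 21L
  )
  g <- generate_ontology(spec)
  corp <- generate_corpus(spec, g)

  expect_equal(length(corp$planted_classes), 20) # drawn without replacement
  expect_equal(nrow(corp$corpus), 60)
  expect_setequal(
    unique(corp$gold$class_id[corp$gold$label == "positive"]),
    corp$planted_classes
  )
  # gold offsets are exact
  txt <- setNames(corp$corpus$text, corp$corpus$doc_id)
  got <- purrr::pmap_chr(
    corp$gold[c("doc_id", "start", "end")],
    function(doc_id, start, end) substr(txt[[doc_id]], start + 1, end)
  )
  planted_surface <- g$truth$surface[match(corp$gold$class_id,
    g$truth$class_id)]
  pos <- corp$gold$label == "positive"
  expect_true(all(
    got[pos] %in% g$truth$surface[g$truth$passes_filter]
  ))
})

test_that("zero mention rate yields an unannotated gold standard", {
  spec <- synthetic_spec(
    n_classes = 10, mentions_per_article = 0, homonym_rate = 0,
    years = c(2000, 2000), articles_per_year = 5L, seed = 5L
  )
  corp <- generate_corpus(spec, generate_ontology(spec))
  expect_equal(nrow(corp$gold), 0)
  expect_equal(nrow(corp$corpus), 5)
})

test_that("noise-free pipeline attains perfect recall and recovers the planted fraction", {
  spec <- synthetic_spec(
    n_classes = 50, planted_class_fraction = 0.5,
    ambiguity_rate = 0, homonym_rate = 0,
    years = c(2000, 2009), articles_per_year = rep(20L, 10),
    mentions_per_article = 2, seed = 99L
  )
  g <- generate_ontology(spec)
  corp <- generate_corpus(spec, g)
  lex <- build_lexicon(g$onto)
  m <- compile_matcher(lex, match_policy(case_mode = "smart"))
  ann <- annotate_corpus(corp$corpus, m)

  res <- score_annotations(ann, corp$gold)
  expect_equal(res$recall, 1.0)

  found <- distinct_classes(ann)
  frac <- identified_fraction(g$onto, found)
  expect_equal(frac$fraction, spec$planted_class_fraction)
})

test_that("smart casing strictly improves precision on a homonym-injected corpus", {
  spec <- synthetic_spec(
    n_classes = 50, planted_class_fraction = 0.6,
    ambiguity_rate = 0, homonym_rate = 0.3,
    years = c(2000, 2004), articles_per_year = rep(20L, 5),
    mentions_per_article = 2, seed = 123L
  )
  g <- generate_ontology(spec)
  corp <- generate_corpus(spec, g)
  expect_gt(sum(corp$gold$label == "negative"), 0)

  lex <- build_lexicon(g$onto)
  naive <- score_annotations(
    annotate_corpus(corp$corpus,
      compile_matcher(lex, match_policy(case_mode = "case_insensitive"))),
    corp$gold
  )
  smart <- score_annotations(
    annotate_corpus(corp$corpus,
      compile_matcher(lex, match_policy(case_mode = "smart"))),
    corp$gold
  )
  expect_lt(naive$precision, 1)
  expect_gt(smart$precision, naive$precision)
})

test_that("geometric article growth with linear class growth decreases the per-article average", {
  spec <- synthetic_spec(
    n_classes = 60, planted_class_fraction = 0.5,
    ambiguity_rate = 0, homonym_rate = 0,
    years = c(2000, 2004),
    articles_per_year = c(8L, 16L, 32L, 64L, 128L),
    classes_per_year = c(10L, 12L, 14L, 16L, 18L),
    mentions_per_article = 2, seed = 31L
  )
  g <- generate_ontology(spec)
  corp <- generate_corpus(spec, g)
  ann <- annotate_corpus(corp$corpus,
    compile_matcher(build_lexicon(g$onto)))
  tr <- yearly_trends(ann, corp$corpus, c(2000, 2004))
  expect_true(all(diff(tr$avg_distinct_per_article) < 0))
})
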