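test_that("matcher compilation enforces non-empty lexica and finds its surfaces", {
  empty <- refine(tibble::tibble(surface = character(),
    class_id = character(), provenance = character()))
  expect_error(compile_matcher(empty), class = "cellmine_config_error")

  lex <- lexicon_from(c("T cell", "B cell"), c("t", "b"))
  m <- compile_matcher(lex, match_policy(case_mode = "exact"))
  ann <- annotate_text("Both T cell and B cell populations.", m)
  expect_equal(ann$surface, c("T cell", "B cell"))
  expect_equal(unlist(ann$class_ids), c("t", "b"))
})

test_that("smart case protects short symbols but relaxes long lowercase terms", {
  lex <- lexicon_from(c("HeLa", "natural killer cell"), c("h", "nk"))
  m <- compile_matcher(lex, match_policy(case_mode = "smart"))

  expect_equal(nrow(annotate_text("grown in hela flasks", m)), 0)
  expect_equal(nrow(annotate_text("grown in HeLa flasks", m)), 1)

  up <- annotate_text("A Natural Killer Cell was sorted.", m)
  expect_equal(nrow(up), 1)
  expect_equal(up$surface, "Natural Killer Cell")
  expect_equal(unlist(up$class_ids), "nk")
})

test_that("boundary mode blocks matches flanked by letters or digits", {
  lex <- lexicon_from("SMC", "s")
  m <- compile_matcher(lex, match_policy(case_mode = "exact"))
  expect_equal(nrow(annotate_text("three SMCs attached", m)), 0)
  expect_equal(nrow(annotate_text("the SMC attached", m)), 1)
  expect_equal(nrow(annotate_text("the SMC, attached", m)), 1)
  expect_equal(nrow(annotate_text("xSMC attached", m)), 0)

  plural <- compile_matcher(lex,
    match_policy(case_mode = "exact", match_plural = TRUE))
  hit <- annotate_text("three SMCs attached", plural)
  expect_equal(hit$surface, "SMCs")
})

test_that("longest-leftmost keeps the longest match and drops nested ones", {
  lex <- lexicon_from(c("neuron", "hippocampal neurons"), c("n", "hn"))
  m <- compile_matcher(lex, match_policy(case_mode = "exact"))
  ann <- annotate_text("hippocampal neurons were imaged", m)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$surface, "hippocampal neurons")

  # partially covered coordination: only the explicitly listed form is found
  lex2 <- lexicon_from("hippocampal neurons", "hn")
  m2 <- compile_matcher(lex2, match_policy(case_mode = "exact"))
  ann2 <- annotate_text("cortical and hippocampal neurons", m2)
  expect_equal(nrow(ann2), 1)
  expect_equal(ann2$surface, "hippocampal neurons")

  # without the boundary requirement, "neuron" also fires inside "neurons"
  all_mode <- compile_matcher(lex,
    match_policy(case_mode = "exact", overlap_mode = "all",
      boundary = FALSE))
  expect_equal(nrow(annotate_text("hippocampal neurons were imaged",
    all_mode)), 2)
})

test_that("empty text yields no annotations and spans round-trip to surfaces", {
  lex <- lexicon_from("germ cell", "g")
  m <- compile_matcher(lex)
  expect_equal(nrow(annotate_text("", m)), 0)

  txt <- "One germ cell; another germ cell."
  ann <- annotate_text(txt, m)
  expect_equal(nrow(ann), 2)
  expect_equal(span_texts(txt, ann), ann$surface)
})

test_that("annotations on identical spans from several patterns merge class ids", {
  lex <- lexicon_from(c("ARL6", "ARL6"), c("line1", "gene1"))
  m <- compile_matcher(lex, match_policy(case_mode = "exact"))
  ann <- annotate_text("the ARL6 sample", m)
  expect_equal(nrow(ann), 1)
  expect_setequal(unlist(ann$class_ids), c("line1", "gene1"))
  expect_setequal(distinct_classes(ann), c("line1", "gene1"))
})

test_that("distinct_classes unions candidate ids across annotations", {
  expect_equal(distinct_classes(tibble::tibble(class_ids = list())),
    character())
  ann <- tibble::tibble(class_ids = list(c("X", "Y"), "X", c("Y", "X")))
  expect_setequal(distinct_classes(ann), c("X", "Y"))
})

test_that("hyphen/space variant expansion is off by default and optional", {
  lex <- lexicon_from("HEK 293", "hek")
  plain <- compile_matcher(lex, match_policy(case_mode = "exact"))
  expect_equal(nrow(annotate_text("used HEK-293 cells", plain)), 0)

  expanded <- compile_matcher(lex,
    match_policy(case_mode = "exact", expand_hyphens = TRUE))
  hit <- annotate_text("used HEK-293 cells", expanded)
  expect_equal(hit$surface, "HEK-293")
  expect_equal(unlist(hit$class_ids), "hek")
})

test_that("tagger agrees with the brute-force matching oracle on random instances", {
  vocab <- c(
    "alpha cell", "beta cell", "alpha", "beta", "cellx", "AB-12",
    "ab", "a cell", "long alpha cell", "X1"
  )
  fillers <- c("the", "of", "with", "and", "grown", "in", "lab", "x", "9")
  withr::with_seed(77, {
    for (rep in 1:120) {
      surfaces <- sample(vocab, sample(2:8, 1))
      tokens <- sample(c(fillers, surfaces), sample(5:25, 1),
        replace = TRUE)
      text <- paste(tokens, collapse = sample(c(" ", " ", ", "), 1))
      lex <- lexicon_from(surfaces, sprintf("c%d", seq_along(surfaces)))
      for (cm in c("exact", "case_insensitive", "smart")) {
        ci <- switch(cm,
          exact = rep(FALSE, length(surfaces)),
          case_insensitive = rep(TRUE, length(surfaces)),
          smart = grepl("[a-z]", surfaces) & nchar(surfaces) >= 6
        )
        oracle_all <- brute_matches(text, surfaces, ci, boundary = TRUE)
        m_all <- compile_matcher(lex,
          match_policy(case_mode = cm, overlap_mode = "all"))
        got_all <- annotate_text(text, m_all)
        expect_equal(got_all[c("start", "end")],
          oracle_all[c("start", "end")], ignore_attr = TRUE)

        m_ll <- compile_matcher(lex,
          match_policy(case_mode = cm, overlap_mode = "longest_leftmost"))
        got_ll <- annotate_text(text, m_ll)
        oracle_ll <- greedy_reduce(oracle_all)
        expect_equal(got_ll[c("start", "end")],
          oracle_ll[c("start", "end")], ignore_attr = TRUE)
      }
    }
  })
})

test_that("adding a surface never removes annotations in all-overlap mode", {
  withr::with_seed(88, {
    base <- c("alpha cell", "beta cell", "AB-12")
    text <- "the alpha cell and AB-12 with beta cell in alpha media"
    lex1 <- lexicon_from(base, c("a", "b", "c"))
    m1 <- compile_matcher(lex1,
      match_policy(case_mode = "exact", overlap_mode = "all"))
    before <- annotate_text(text, m1)

    lex2 <- lexicon_from(c(base, "alpha"), c("a", "b", "c", "d"))
    m2 <- compile_matcher(lex2,
      match_policy(case_mode = "exact", overlap_mode = "all"))
    after <- annotate_text(text, m2)

    key <- function(df) paste(df$start, df$end)
    expect_true(all(key(before) %in% key(after)))
  })
})

test_that("annotate_corpus applies one or several matchers across documents", {
  corp <- tibble::tibble(
    doc_id = c("d1", "d2"),
    year = c(2001L, 2002L),
    text = c("a germ cell divides", "the XQ-17B line and a germ cell")
  )
  types <- compile_matcher(lexicon_from("germ cell", "g"),
    lexicon_id = "cell_type")
  lines <- compile_matcher(lexicon_from("XQ-17B", "x"),
    match_policy(case_mode = "exact"), lexicon_id = "cell_line")
  ann <- annotate_corpus(corp, list(types, lines))
  expect_equal(sum(ann$lexicon_id == "cell_type"), 2)
  expect_equal(sum(ann$lexicon_id == "cell_line"), 1)
  expect_setequal(unique(ann$doc_id), c("d1", "d2"))
})
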