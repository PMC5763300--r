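test_that("extract_terms enumerates labels and synonyms of non-obsolete classes", {
  onto <- read_obo(chain_obo)
  terms <- extract_terms(onto)
  expect_equal(nrow(terms), 4) # 3 labels + 1 synonym
  germ <- terms[terms$class_id == "C", ]
  expect_setequal(germ$surface, c("germ cell", "gamete precursor cell"))
  expect_setequal(germ$provenance, c("label", "synonym"))

  # label-only class yields exactly one tuple
  lone <- extract_terms(read_term_table(c(
    "id\tlabel\tsynonyms\tparents", "X\tsolo cell\t\t"
  )))
  expect_equal(nrow(lone), 1)

  # shared synonym across two classes keeps both class ids
  shared <- extract_terms(read_term_table(c(
    "id\tlabel\tsynonyms\tparents",
    "S1\tsmooth muscle cell\tSMC\t",
    "S2\tsoil microbial community cell\tSMC\t"
  )))
  smc <- shared[shared$surface == "SMC", ]
  expect_setequal(smc$class_id, c("S1", "S2"))
})

test_that("extract_terms normalizes whitespace and skips obsolete classes", {
  onto <- ontology(tibble::tibble(
    id = c("A", "B"),
    label = c("germ   cell", "old cell"),
    synonyms = list(" spaced   synonym ", character()),
    parents = list(character(), character()),
    obsolete = c(FALSE, TRUE)
  ))
  terms <- extract_terms(onto)
  expect_setequal(terms$surface, c("germ cell", "spaced synonym"))
})

test_that("refinement removes short, digit-only and generic terms with reasons", {
  raw <- tibble::tibble(
    surface = c("S2", "548", "2-2", "mouse cell", "Mouse Cell",
      "germ cell", "HEK293T"),
    class_id = c("c1", "c2", "c3", "c4", "c4", "c5", "c6"),
    provenance = "label"
  )
  lex <- refine(raw, refinement_config(min_length = 4))
  reasons <- setNames(lex$removed$reason, surface_key(lex$removed$surface))
  expect_equal(unname(reasons[["s2"]]), "too_short")
  expect_equal(unname(reasons[["548"]]), "digit_only")
  expect_equal(unname(reasons[["2-2"]]), "digit_only")
  expect_equal(unname(reasons[["mouse cell"]]), "stop_term")
  expect_setequal(lex$entries$surface, c("germ cell", "HEK293T"))

  # min_length = 3 retains "germ cell"
  lex3 <- refine(raw, refinement_config(min_length = 3))
  expect_true("germ cell" %in% lex3$entries$surface)

  # digits inside names are never stripped
  expect_true("HEK293T" %in% lex$entries$surface)
})

test_that("stop-term comparison is case-insensitive and extensible", {
  raw <- tibble::tibble(
    surface = c("Human", "hela cell line"),
    class_id = c("x", "y"), provenance = "label"
  )
  lex <- refine(raw, refinement_config(
    min_length = 3, stop_terms = c("human", "HeLa Cell Line")
  ))
  expect_equal(nrow(lex$entries), 0)
  expect_setequal(lex$removed$reason, "stop_term")
})

test_that("ambiguous surfaces merge into one entry with all class ids", {
  lex <- lexicon_from(c("SMCX", "SMCX", "other cell"), c("a", "b", "c"))
  smc <- lex$entries[lex$entries$key == "smcx", ]
  expect_equal(smc$class_ids[[1]], c("a", "b"))
  expect_equal(lexicon_stats(lex)$term_count, 2)
  expect_equal(lexicon_stats(lex)$distinct_class_count, 3)
})

test_that("lexicon_stats counts surfaces and distinct classes", {
  empty <- refine(tibble::tibble(surface = character(),
    class_id = character(), provenance = character()))
  expect_equal(unlist(lexicon_stats(empty)),
    c(term_count = 0L, distinct_class_count = 0L))

  two_one <- lexicon_from(c("alpha cell", "first cell"), c("k", "k"))
  expect_equal(lexicon_stats(two_one)$term_count, 2)
  expect_equal(lexicon_stats(two_one)$distinct_class_count, 1)

  five_three <- lexicon_from(
    c("one cell", "two cell", "three cell", "four cell", "five cell"),
    c("p", "p", "q", "r", "r")
  )
  expect_equal(unlist(lexicon_stats(five_three)),
    c(term_count = 5L, distinct_class_count = 3L))
})

test_that("refinement is idempotent and partitions the raw surfaces", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      n <- sample(5:40, 1)
      surfaces <- c(
        replicate(n, paste(sample(letters, sample(1:8, 1)), collapse = "")),
        as.character(sample(10:999, 3)), "S2", "mouse cell"
      )
      raw <- tibble::tibble(
        surface = surfaces,
        class_id = sample(sprintf("c%02d", 1:10), length(surfaces),
          replace = TRUE),
        provenance = "label"
      )
      cfg <- refinement_config(min_length = sample(2:5, 1))
      lex <- refine(raw, cfg)

      # partition: entries + removed = distinct raw surfaces
      expect_equal(
        nrow(lex$entries) + nrow(lex$removed),
        length(unique(tolower(trimws(raw$surface))))
      )
      # no retained surface violates any predicate
      keys <- lex$entries$key
      expect_true(all(nchar(keys) >= cfg$min_length))
      expect_false(any(grepl("^[0-9[:punct:][:space:]]+$", keys) &
          grepl("[0-9]", keys)))
      expect_false(any(keys %in% cfg$stop_terms))

      # idempotence: re-refining the retained terms changes nothing
      again <- refine(lex$terms, cfg)
      expect_equal(again$entries, lex$entries)
      expect_equal(nrow(again$removed), 0)
    }
  })
})

test_that("lexicon TSV serialization round-trips surfaces and class ids", {
  lex <- lexicon_from(c("germ cell", "SMCX", "SMCX"), c("g1", "a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_setequal(df$surface, c("germ cell", "SMCX"))
  expect_equal(df$class_ids[df$surface == "SMCX"], "a|b")
})
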