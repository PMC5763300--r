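---
title: "Methods: dictionary-based mining of cell nomenclature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-based mining of cell nomenclature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmine)
library(dplyr)
```

## The problem

Cell types (in vivo) and cell lines (in vitro) are described in publications
with a vocabulary that is only partially standardised. Ontologies such as the
Cell Ontology (CL) and the Cell Line Ontology (CLO) provide formal class
hierarchies with preferred labels and synonyms, but how much of that
nomenclature scientists actually use in text is an empirical question.
`cellmine` implements the full measurement pipeline: compile a refined term
dictionary from an ontology, tag a document corpus by dictionary matching,
and summarise the result as ontology coverage statistics, publication-year
trends, and precision/recall evaluations against manually adjudicated gold
annotations.

## Pipeline and models

### Ontology model

An `ontology()` is a set of classes (id, label, synonyms, obsolescence flag)
with is_a edges forming a DAG; multiple parents are allowed. Two plain-text
input formats are supported — the OBO 1.4 flat-file subset (`[Term]` stanzas
with `id`, `name`, `synonym`, `is_a`, `is_obsolete`) and an equivalent TSV
term table — and parsing either representation of the same content yields
identical graphs. Only is_a is traversed: the coverage statistic below is
defined over *subclasses*, so other relationship types (develops_from,
part_of) are ignored. Cycles, duplicate ids and dangling is_a targets are
load errors.

`subclasses(onto, id)` is the transitive closure over inverted is_a edges,
computed as graph reachability (igraph). It is set-valued, so diamond
inheritance never double-counts. Obsolete classes are retained in the graph
(they may sit on a path) but are excluded from closures, from dictionaries
and from coverage denominators: an obsolete class cannot be validly
annotated. Published ontology-wide class counts do not always state whether
obsolete classes are included; this package always excludes them and reports
denominators explicitly.

### Dictionary compilation and refinement

`extract_terms()` enumerates one (surface, class) pair per label and per
synonym of every non-obsolete class; synonym scope qualifiers are not
distinguished, since labels and synonyms are tagged identically downstream.
`refine()` then applies the precision-oriented filters typical of cell
nomenclature dictionaries, each removal logged with a reason:

* `digit_only` — surfaces with no letters ("548", "2-2"); interpreted as
  removing digit-only surfaces, *not* stripping digits out of surfaces,
  which would corrupt names like "HEK293T".
* `too_short` — surfaces shorter than `min_length` characters (counting
  internal spaces and hyphens). The conventional thresholds are 3 for
  cell-type dictionaries and 4 for cell-line dictionaries, reflecting how
  much more often short cell-line codes ("C2", "S2") collide with other
  symbols; `min_length` is set per dictionary.
* `stop_term` — case-insensitive membership in a generic-term stop list.
  The shipped default holds the canonical examples ("P1", "mouse cell",
  "cell line", "human", "mammalian"); real deployments extend it via a
  one-term-per-line file, since no complete list is published.

A surface violating several predicates is logged once, under the first
reason in the order above, so number-only names form their own audit class.
Entries are keyed by a whitespace-collapsed, case-folded surface; original
casing is preserved for display and for case-sensitive matching. A surface
naming several classes (the "SMC" situation) is kept as a single ambiguous
entry carrying all class ids — ambiguity is a property of the vocabulary
that the tagger and the evaluation must see, not something to resolve away
at compile time. Refinement is idempotent, and retained plus removed
surfaces exactly partition the distinct raw surfaces.

### Matching policy

Dictionary tagging with a fixed surface set is intentionally simple; all the
judgement sits in the `match_policy()`:

* **Case.** `smart` (default) matches a surface case-insensitively only if
  it contains a lowercase letter *and* has at least 6 characters. Long
  natural-language terms ("natural killer cell") then match under sentence
  capitalisation, while short codes ("MCF2", "HeLa", "ARL6") must match
  exactly — the cheapest effective defence against gene-name and
  abbreviation homonyms, favouring precision over recall. `exact` and
  `case_insensitive` are available for comparison; the package's own
  synthetic experiments (below) quantify the difference.
* **Boundaries.** A match must not be flanked by letters or digits, so
  "SMC" does not fire inside "SMCs". An optional plural rule (surface +
  "s"/"es") is off by default: inflection handling is a corpus-dependent
  choice with no published reference behaviour.
* **Overlap.** `longest_leftmost` (default) scans left to right, keeps the
  longest match at each position and resumes after it — one annotation for
  "hippocampal neurons" even when "neuron" is also in the dictionary.
  `all` returns every boundary-satisfying match and exists mainly for the
  oracle equivalence tests.
* **Variants.** Hyphen/space variants ("HEK-293" vs "HEK 293") are *not*
  generated by default; `expand_hyphens = TRUE` enables a symmetric
  swap-expander. Synonym gaps of this kind are a documented false-negative
  class, not something the tagger silently papers over.

Matching is implemented with stringi fixed-pattern search (overlapping
occurrences included) per pattern, followed by the boundary and overlap
reductions; on small instances it is tested for exact agreement with a
brute-force every-(position, surface) oracle.

### Coverage statistics

`class_representation()` reports, for a class, the fraction of its
transitive subclasses (excluding itself) found in the corpus. For a
childless class the ratio is undefined; the package defines it as the
class's own found-indicator and reports `n_sub_total = 0` alongside, so the
convention is always visible. `identified_fraction()` is the ontology-wide
share of non-obsolete classes mentioned at least once. "Referred to in the
literature" means appearing in at least one annotation; candidate ids of
ambiguous surfaces all count, since a mention of an ambiguous surface is
evidence for each of its readings. Percentages are rounded half-up to the
conventional printed precision (integers for ontology-wide fractions, two
decimals for per-class representation); exact rationals are always
returned beside them.

### Trends

`yearly_trends()` bins annotations by publication year: distinct annotated
classes, annotated articles, and their ratio (average distinct annotations
per article). A "distinct annotation" is a distinct *class*, not a distinct
surface — the coverage denominators are class counts, so the numerator must
be too. The default counts per-year-only; a `cumulative` flag is exposed
because either reading of a yearly "distribution" is defensible.
`growth_rates()` is cumulative relative to the first year with a positive
count (the baseline emits 0; earlier years are dropped as the baseline is
undefined there); a year-over-year mode is exposed as well. Cumulative is
the default because comparing two series against a common early baseline is
what makes "literature grows faster than nomenclature usage" a visible,
scale-free statement. Documents without a year are skipped and tallied in
an attribute rather than silently dropped.

### Evaluation

`score_annotations()` matches predicted spans against gold spans, greedily
by position, each gold matching at most one prediction; under exact-span
matching the greedy count equals the brute-force optimal matching (tested).
Mention-level exact-span is the default granularity. Precision is defined
as 1 when there are no predictions, recall as 1 when there are no positive
golds. Gold records may carry `error_tag`s (homonym, missing_synonym,
missing_class, boundary), which `tidy()` aggregates into an FP/FN taxonomy
table. `sample_sentences()` reproduces the manual-evaluation workflow:
a seeded uniform sample of sentences that contain an annotation or a
keyword; the seed and pool size are recorded on the output. Sentence
splitting is deliberately simple (terminator + whitespace + capital/digit,
with an abbreviation guard list) — it exists for sampling, and the tagger
always runs on full text.

## What the synthetic generator emulates

`generate_ontology()` and `generate_corpus()` produce a random is_a DAG and
a yearly corpus with *complete* gold annotations, emulating the structural
features the pipeline must cope with:

* realistic surface shapes — multiword lowercase phrases for cell-type-like
  classes, uppercase alphanumeric codes ("XQ-17B") for cell-line-like ones;
* synonymy (Poisson-distributed extra synonyms per class, default mean 1.5);
* ambiguity (`ambiguity_rate`: surfaces shared by two classes);
* homonymy (`homonym_rate`: code surfaces that also occur in text as
  lowercased non-cell distractors, recorded as negative gold — the
  gene-name-versus-cell-line casing mechanism);
* deliberately filterable synonyms (digit-only, too-short) to exercise
  refinement — labels always pass the filters, and filterable synonyms are
  never planted in text, so filter behaviour and recall can be measured
  independently;
* literature growth (`articles_per_year`, and optionally `classes_per_year`
  to let the available nomenclature pool grow more slowly than the corpus).

Filler text is drawn from a fixed word list disjoint from every word that
can appear in a surface, so no surface arises in filler text by chance and
gold completeness holds by construction. A single seed governs all
randomness; every output embeds its spec.

What it does **not** emulate: real linguistic context (anaphora,
coordination like "cortical and hippocampal neurons", marker-based
descriptions), real synonym-gap structure, journal or citation effects, and
realistic class-frequency skew. Passing the synthetic recovery tests
therefore shows the *machinery* is correct (offsets, filtering, matching,
counting), not that any particular recall level would be attained on real
literature — on real text, dictionary recall is bounded by ontology
coverage, which is precisely what the coverage statistics measure.

## Numerical and design choices

* Character offsets are 0-based, half-open, into the normalized document
  text — uniform across annotations, sentences and gold records.
* Year extraction from article XML takes the minimum year over all pub-date
  elements (the earliest publication event).
* Half-up rounding (`round_half_up()`) is used for printed percentages;
  base R's round-half-even would print 58.58% as 58%.
* Default study sizes in the test suite and acceptance script: a 50-class
  ontology with 200 articles for recovery runs, 100 articles for the
  homonym experiment, 248 articles across five years for the trend
  mechanism, and 1000 random small instances for the matcher oracle. These
  sizes give stable statistics while keeping a full run in the order of
  minutes on one core.
* The evaluation's F-score obeys the harmonic-mean identity and
  `f <= (p + r) / 2`; both are asserted as properties.

## Known limitations

* The OBO parser covers the flat-file subset it documents (Term stanzas,
  five tags); OWL, logical axioms and cross-ontology imports are out of
  scope — convert richer ontologies to OBO or the TSV term table first.
* No machine-learning disambiguation of ambiguous matches; annotations
  carry all candidate class ids instead.
* Corpus-scale published counts (e.g. how many classes of a 2017 CL/CLO
  release occur in ~1.5M open-access articles) depend on those exact
  releases and that archive; this package reproduces the statistics'
  arithmetic and mechanisms at desk scale, not those corpus-bound totals.
* The matcher scans per pattern with a vectorised fixed-string search;
  for dictionaries of ~10^5 surfaces over millions of documents a dedicated
  multi-pattern automaton would be the next step.

## A worked run

```{r pipeline}
spec <- synthetic_spec(
  n_classes = 30, planted_class_fraction = 0.5,
  ambiguity_rate = 0, homonym_rate = 0,
  years = c(2000, 2004), articles_per_year = rep(10L, 5),
  mentions_per_article = 2, seed = 11L
)
g <- generate_ontology(spec)
corp <- generate_corpus(spec, g)

lex <- build_lexicon(g$onto)
glance(lex)

ann <- annotate_corpus(corp$corpus, compile_matcher(lex))
identified_fraction(g$onto, distinct_classes(ann))

glance(score_annotations(ann, corp$gold))

yearly_trends(ann, corp$corpus, c(2000, 2004))
```
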