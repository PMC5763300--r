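#' Yearly nomenclature-usage trends
#'
#' Bins annotations by their document's publication year and computes,
#' per year: the number of distinct annotated classes, the number of
#' annotated articles (documents with at least one annotation), their
#' ratio (the average number of distinct annotations per article), and
#' the cumulative growth of distinct-class usage relative to the first
#' year with any usage. "Distinct annotation" counts distinct classes,
#' not distinct surfaces, per scope: each class is counted once per year
#' (or once overall in cumulative mode), matching how class-level
#' denominators are used in coverage statistics.
#'
#' Documents without a year are skipped and tallied in the
#' `n_skipped_no_year` attribute.
#'
#' @param annotations An annotation tibble ([annotate_corpus()]).
#' @param corpus The corpus tibble the annotations refer to (`doc_id`,
#'   `year`).
#' @param year_range Inclusive `c(from, to)` integer pair.
#' @param cumulative Count distinct classes cumulatively up to each year
#'   instead of per-year-only?
#' @return A `trend_table` tibble: `year`, `n_distinct_annotations`,
#'   `n_annotated_articles`, `n_articles`, `avg_distinct_per_article`,
#'   `growth_rate_pct` (relative to the first year with usage; `NA`
#'   before it).
#' @export
yearly_trends <- function(annotations, corpus, year_range,
                          cumulative = FALSE) {
  stopifnot(length(year_range) == 2)
  if (year_range[[1]] > year_range[[2]]) {
    rlang::abort("year_range must be increasing",
      class = "cellmine_argument_error")
  }
  years <- seq(as.integer(year_range[[1]]), as.integer(year_range[[2]]))

  unresolved <- setdiff(annotations$doc_id, corpus$doc_id)
  if (length(unresolved) > 0) {
    rlang::abort(paste0("annotation doc_id not in corpus: ", unresolved[[1]]),
      class = "cellmine_argument_error")
  }
  ann <- annotations
  ann$year <- corpus$year[match(ann$doc_id, corpus$doc_id)]
  n_skipped <- length(unique(ann$doc_id[is.na(ann$year)]))
  ann <- ann[!is.na(ann$year), ]

  per_year <- purrr::map(years, function(y) {
    in_scope <- if (cumulative) ann$year <= y else ann$year == y
    a <- ann[in_scope, ]
    docs_y <- corpus$doc_id[!is.na(corpus$year) & corpus$year == y]
    n_annotated <- length(unique(a$doc_id[a$year == y]))
    tibble::tibble(
      year = y,
      n_distinct_annotations = length(distinct_classes(a)),
      n_annotated_articles = n_annotated,
      n_articles = length(docs_y)
    )
  })
  out <- dplyr::bind_rows(per_year)
  out$avg_distinct_per_article <- ifelse(
    out$n_annotated_articles > 0,
    out$n_distinct_annotations / out$n_annotated_articles,
    0
  )
  gr <- if (all(out$n_distinct_annotations == 0)) {
    tibble::tibble(year = integer(), growth_pct = numeric())
  } else {
    growth_rates(out[c("year", "n_distinct_annotations")])
  }
  out$growth_rate_pct <- gr$growth_pct[match(out$year, gr$year)]
  attr(out, "n_skipped_no_year") <- n_skipped
  class(out) <- c("trend_table", class(out))
  out
}

#' Growth rates of a yearly count series
#'
#' Cumulative mode (default): growth in year *y* is
#' `100 * (count(y) - count(y0)) / count(y0)` where *y0* is the first
#' year with a positive count; the baseline year emits 0 and years before
#' it are dropped. Year-over-year mode compares each year with the
#' previous one instead. Comparing the literature's article-count growth
#' curve against the distinct-annotation growth curve on the same scale
#' shows which grows faster.
#'
#' @param series A data frame whose first two columns are year and count
#'   (counts >= 0, sorted by year).
#' @param mode `"cumulative"` or `"yoy"`.
#' @return A tibble `year`, `growth_pct`.
#' @export
growth_rates <- function(series, mode = c("cumulative", "yoy")) {
  mode <- match.arg(mode)
  series <- tibble::as_tibble(series)
  year <- series[[1]]
  count <- series[[2]]
  stopifnot(!is.unsorted(year), all(count >= 0))
  pos <- which(count > 0)
  if (length(pos) == 0) {
    rlang::warn("all counts are zero; no growth baseline")
    return(tibble::tibble(year = integer(), growth_pct = numeric()))
  }
  i0 <- pos[[1]]
  year <- year[i0:length(year)]
  count <- count[i0:length(count)]
  growth <- if (mode == "cumulative") {
    100 * (count - count[[1]]) / count[[1]]
  } else {
    c(0, 100 * diff(count) / utils::head(count, -1))
  }
  tibble::tibble(year = year, growth_pct = growth)
}

#' Write a trend table as TSV
#'
#' @param trends A [yearly_trends()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trends_tsv <- function(trends, path) {
  lines <- c(
    "year\tn_distinct\tn_annotated_articles\tn_articles\tavg\tgrowth_pct",
    sprintf(
      "%d\t%d\t%d\t%d\t%.4f\t%s",
      trends$year, trends$n_distinct_annotations,
      trends$n_annotated_articles, trends$n_articles,
      trends$avg_distinct_per_article,
      ifelse(is.na(trends$growth_rate_pct), "NA",
        sprintf("%.2f", trends$growth_rate_pct))
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @method autoplot trend_table
#' @export
autoplot.trend_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c(
      "year", "n_distinct_annotations", "n_annotated_articles",
      "avg_distinct_per_article"
    )],
    cols = -year, names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(year, value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "publication year", y = NULL,
      title = "Cell nomenclature usage by year"
    )
}

#' @rdname autoplot.trend_table
#' @param trends A [yearly_trends()] tibble.
#' @param ... Passed to `autoplot`.
#' @export
plot_trends <- function(trends, ...) {
  ggplot2::autoplot(trends, ...)
}
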