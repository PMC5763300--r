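#' Class representation in the literature
#'
#' The representation of a class is the ratio between the number of its
#' subclasses referred to in the corpus and its total number of
#' subclasses, computed over the transitive is_a closure excluding the
#' class itself. A childless class has no subclasses to represent; its
#' representation is defined as its own found-indicator (1 if the class
#' itself is in `found`, else 0).
#'
#' @param onto An [ontology()].
#' @param found Character vector of class ids referred to at least once
#'   (e.g. [distinct_classes()] of a corpus annotation run).
#' @param class_id Class to report on.
#' @return A one-row tibble: `class_id`, `label`, `n_sub_found`,
#'   `n_sub_total`, `representation` (fraction in \[0, 1\]),
#'   `representation_pct` (half-up, 2 decimals).
#' @export
class_representation <- function(onto, found, class_id) {
  closure <- subclasses(onto, class_id, include_self = FALSE)
  n_total <- length(closure)
  n_found <- length(intersect(closure, found))
  rep_frac <- if (n_total > 0) {
    n_found / n_total
  } else {
    as.numeric(class_id %in% found)
  }
  lab <- onto$classes$label[match(class_id, onto$classes$id)]
  tibble::tibble(
    class_id = class_id,
    label = lab,
    n_sub_found = n_found,
    n_sub_total = n_total,
    representation = rep_frac,
    representation_pct = round_half_up(100 * rep_frac, 2)
  )
}

#' Fraction of an ontology identified in a corpus
#'
#' The headline coverage figure: the share of all non-obsolete classes
#' mentioned at least once.
#'
#' @inheritParams class_representation
#' @return A one-row tibble: `n_found`, `n_classes`, `fraction` (exact),
#'   `pct` (integer, rounded half-up).
#' @export
identified_fraction <- function(onto, found) {
  ids <- active_classes(onto)
  n_found <- length(intersect(ids, found))
  frac <- if (length(ids) > 0) n_found / length(ids) else 0
  tibble::tibble(
    n_found = n_found,
    n_classes = length(ids),
    fraction = frac,
    pct = round_half_up(100 * frac, 0)
  )
}

#' Representation report for selected ontology branches
#'
#' One [class_representation()] row per requested parent class, sorted
#' descending by representation — the per-branch view used to spot
#' well-covered versus poorly covered regions of an ontology.
#'
#' @inheritParams class_representation
#' @param parent_ids Character vector of branch-root class ids.
#' @return A `coverage_report` tibble (see [class_representation()]),
#'   sorted by decreasing representation.
#' @export
branch_report <- function(onto, found, parent_ids) {
  rows <- purrr::map(parent_ids, ~ class_representation(onto, found, .x))
  if (length(rows) == 0) {
    rows <- list(class_representation(
      ontology(tibble::tibble(id = "x", label = "x", synonyms = list(character()),
        parents = list(character()), obsolete = FALSE)),
      character(), "x"
    )[0, ])
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(representation))
  class(out) <- c("coverage_report", class(out))
  out
}

#' Write a coverage report as TSV
#'
#' @param report A [branch_report()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(report, path) {
  lines <- c(
    "class_id\tlabel\tn_sub_found\tn_sub_total\trepresentation_pct",
    sprintf(
      "%s\t%s\t%d\t%d\t%.2f",
      report$class_id, report$label, report$n_sub_found,
      report$n_sub_total, report$representation_pct
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  object$label <- factor(
    ifelse(is.na(object$label), object$class_id, object$label),
    levels = rev(ifelse(is.na(object$label), object$class_id, object$label))
  )
  ggplot2::ggplot(object,
    ggplot2::aes(x = representation_pct, y = label)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "subclasses found in literature (%)", y = NULL,
      title = "Class representation in literature"
    ) +
    ggplot2::xlim(0, 100)
}

#' @rdname autoplot.coverage_report
#' @param report A [branch_report()] tibble.
#' @param ... Passed to `autoplot`.
#' @export
plot_coverage <- function(report, ...) {
  ggplot2::autoplot(report, ...)
}
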