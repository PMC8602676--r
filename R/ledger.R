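#' Construct a filter ledger
#'
#' A filter ledger records, for each ordered filtration stage, how many
#' peptides entered, were removed, and survived, plus the removed peptide
#' lists. Construction enforces the conservation invariants: within every
#' stage `n_in = n_removed + n_out`, consecutive stages chain
#' (`n_out[k] = n_in[k+1]`), and the final survivor count equals the initial
#' input minus the sum of removals.
#'
#' @param stages Tibble with columns `stage`, `n_in`, `n_removed`, `n_out`
#'   and optionally a `removed` list-column.
#' @return A `filter_ledger`.
#' @export
new_filter_ledger <- function(stages) {
  stopifnot(all(c("stage", "n_in", "n_removed", "n_out") %in% names(stages)))
  if (!"removed" %in% names(stages)) {
    stages$removed <- rep(list(character()), nrow(stages))
  }
  x <- structure(list(stages = stages), class = "filter_ledger")
  check_ledger(x)
  x
}

#' Verify ledger conservation invariants
#'
#' @param ledger A `filter_ledger`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
check_ledger <- function(ledger) {
  s <- ledger$stages
  if (!all(s$n_in == s$n_removed + s$n_out)) {
    stop("ledger stage violates n_in = n_removed + n_out", call. = FALSE)
  }
  if (nrow(s) > 1L && !all(s$n_out[-nrow(s)] == s$n_in[-1L])) {
    stop("ledger stages do not chain (n_out[k] != n_in[k+1])", call. = FALSE)
  }
  if (ledger_survivors(ledger) != s$n_in[1] - sum(s$n_removed)) {
    stop("ledger end-to-end conservation violated", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a ledger from stage counts alone
#'
#' Useful for reproducing published cascade bookkeeping when only per-stage
#' removal counts are available.
#'
#' @param n_in Number of peptides entering the first stage.
#' @param removals Named integer vector: removals per stage, in order.
#' @return A `filter_ledger`.
#' @export
ledger_from_counts <- function(n_in, removals) {
  ins <- n_in - cumsum(c(0L, unname(removals)[-length(removals)]))
  new_filter_ledger(tibble::tibble(
    stage = names(removals),
    n_in = ins,
    n_removed = unname(removals),
    n_out = ins - unname(removals)
  ))
}

#' Final survivor count of a ledger
#' @param ledger A `filter_ledger`.
#' @return Integer.
#' @export
ledger_survivors <- function(ledger) {
  ledger$stages$n_out[nrow(ledger$stages)]
}

#' Per-stage removal percentages relative to the first stage's input
#' @param ledger A `filter_ledger`.
#' @return Named numeric vector of percentages.
#' @export
ledger_removal_pct <- function(ledger) {
  s <- ledger$stages
  stats::setNames(100 * s$n_removed / s$n_in[1], s$stage)
}

#' @export
print.filter_ledger <- function(x, ...) {
  s <- x$stages
  cat("<filter_ledger>\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s in %6d  removed %6d  out %6d\n",
                s$stage[i], s$n_in[i], s$n_removed[i], s$n_out[i]))
  }
  cat(sprintf("  survivors: %d of %d\n", ledger_survivors(x), s$n_in[1]))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.filter_ledger <- function(x, ...) {
  x$stages
}

#' Write a ledger as JSON and human-readable TSV
#'
#' @param ledger A `filter_ledger`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return The ledger, invisibly.
#' @export
write_ledger <- function(ledger, json_path = NULL, tsv_path = NULL) {
  s <- ledger$stages
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(stages = lapply(seq_len(nrow(s)), function(i) {
        list(stage = s$stage[i], n_in = s$n_in[i],
             n_removed = s$n_removed[i], n_out = s$n_out[i],
             removed = s$removed[[i]])
      }), survivors = ledger_survivors(ledger)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(s[, c("stage", "n_in", "n_removed", "n_out")], tsv_path)
  }
  invisible(ledger)
}

#' Waterfall plot of a filter ledger
#'
#' @param object A `filter_ledger`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_ledger <- function(object, ...) {
  s <- object$stages |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stage)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_in), fill = "grey80") +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_out), fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "peptides",
                  title = "Filtration cascade: entering (grey) vs surviving (blue)") +
    ggplot2::theme_minimal()
}

#' Published discovery-cohort stage counts
#'
#' Stage counts and compositions reported for the 46-tumor medulloblastoma
#' discovery cohort, the single-patient workflow (subject 7316-3778) and the
#' four cell lines that motivated this package's cascade design. They serve
#' as worked-example inputs for ledger arithmetic; they are data, not
#' results this package computes.
#'
#' @return Nested list with elements `cohort` (identified candidates and
#'   per-stage removals), `cohort_composition` (survivors per event kind),
#'   `patient` (the single-subject ledger and composition) and `cell_lines`
#'   (per-line survivor counts and event-kind composition).
#' @export
published_cohort_counts <- function() {
  list(
    cohort = list(identified = 481L,
                  removals = c(normal_peptides = 17L, event_catalog = 102L)),
    cohort_composition = c(junction = 230L, snv = 85L, fusion = 49L),
    patient = list(identified = 25L,
                   removals = c(normal_peptides = 3L, event_catalog = 6L),
                   composition = c(junction = 14L, snv = 2L, fusion = 1L)),
    cell_lines = list(
      per_line = c(D556 = 47L, MB002 = 62L, MB004 = 68L, D283 = 100L),
      composition = c(junction = 157L, snv = 37L, fusion = 75L),
      unique_total = 269L)
  )
}
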