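#' Empty novel-protein-entry tibble
#'
#' The common currency of the database builders: one row per translated
#' tumor-specific sequence, carrying enough provenance to reconstruct the
#' generating event (needed by the event-catalog filtration stage).
#'
#' @return Zero-row tibble with columns `sequence`, `event_kind`
#'   (snv/indel/junction/fusion), `contig`, `loc` (0-based half-open
#'   `contig:start-end`, two arms separated by `;` for fusions), `strand`,
#'   `frame`, `junction_class`, `sample_id`, `provenance`.
#' @export
novel_entry_tibble <- function() {
  tibble::tibble(
    sequence = character(), event_kind = character(), contig = character(),
    loc = character(), strand = character(), frame = integer(),
    junction_class = character(), sample_id = character(),
    provenance = character()
  )
}

validate_novel_entries <- function(entries) {
  stopifnot(all(nzchar(entries$sequence)))
  if (any(grepl("\\*", entries$sequence))) {
    stop("novel entry with internal stop codon", call. = FALSE)
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", entries$sequence)
  if (any(bad)) {
    stop("novel entry outside the 20 aa + X alphabet", call. = FALSE)
  }
  invisible(entries)
}

#' Assemble the tumor-specific search database
#'
#' Deduplicates novel entries by exact amino-acid sequence (provenance of
#' merged duplicates is concatenated), assigns stable entry identifiers,
#' appends the reference proteome unmodified, writes a search FASTA and
#' returns it together with a manifest of per-kind counts and mean ORF
#' lengths. Isoleucine and leucine are distinct at build time; I/L
#' equivalence is a filtering-time option only.
#'
#' @param entries Tibble of novel protein entries.
#' @param reference_proteome Path to the reference proteome FASTA.
#' @param fasta_out Optional path; when given, the merged FASTA is written
#'   there. Novel headers follow
#'   `>nep|<id>|kind=...|loc=...|strand=...|frame=...|class=...|sample=...`;
#'   reference records keep their original headers.
#' @return List of class `search_database`: `novel` (deduplicated entry
#'   tibble with `entry_id`), `reference` (named character vector of
#'   reference proteins), `manifest` (list; see Details).
#' @details The manifest reports `n_<kind>` for each event kind, `n_novel`,
#'   `n_reference`, `n_total` (= novel + reference, an enforced invariant)
#'   and `mean_orf_aa` per kind.
#' @export
assemble_database <- function(entries, reference_proteome,
                              fasta_out = NULL) {
  validate_novel_entries(entries)
  ref <- Biostrings::readAAStringSet(reference_proteome)
  reference <- as.character(ref)
  if (nrow(entries) == 0L) {
    warning("no novel entries; writing reference-only database",
            call. = FALSE)
  }
  novel <- entries |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      event_kind = .data$event_kind[1],
      contig = .data$contig[1], loc = .data$loc[1],
      strand = .data$strand[1], frame = .data$frame[1],
      junction_class = .data$junction_class[1],
      sample_id = paste(sort(unique(.data$sample_id)), collapse = ","),
      provenance = paste(.data$provenance, collapse = " | "),
      all_kinds = list(unique(.data$event_kind)),
      all_locs = list(unique(paste0(.data$event_kind, "@", .data$loc))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$event_kind, .data$loc, .data$sequence) |>
    dplyr::mutate(entry_id = sprintf("NEP%05d", dplyr::row_number())) |>
    dplyr::relocate("entry_id")

  kinds <- c("snv", "indel", "junction", "fusion")
  per_kind <- lapply(kinds, function(k) sum(novel$event_kind == k))
  names(per_kind) <- paste0("n_", kinds)
  mean_orf <- lapply(kinds, function(k) {
    s <- novel$sequence[novel$event_kind == k]
    if (length(s) == 0L) NA_real_ else mean(nchar(s))
  })
  names(mean_orf) <- kinds
  manifest <- c(per_kind, list(
    n_novel = nrow(novel),
    n_reference = length(reference),
    n_total = nrow(novel) + length(reference),
    mean_orf_aa = mean_orf
  ))
  stopifnot(manifest$n_total ==
              sum(unlist(per_kind)) + manifest$n_reference)

  db <- structure(list(novel = novel, reference = reference,
                       manifest = manifest), class = "search_database")
  if (!is.null(fasta_out)) write_search_fasta(db, fasta_out)
  db
}

#' @export
print.search_database <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<search_database> %d novel (%d snv, %d indel, %d junction, %d fusion) + %d reference = %d entries\n",
    m$n_novel, m$n_snv, m$n_indel, m$n_junction, m$n_fusion,
    m$n_reference, m$n_total))
  invisible(x)
}

#' Write a search database to FASTA
#'
#' @param db A `search_database`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_search_fasta <- function(db, path) {
  headers <- sprintf(
    "nep|%s|kind=%s|loc=%s|strand=%s|frame=%d|class=%s|sample=%s",
    db$novel$entry_id, db$novel$event_kind, db$novel$loc, db$novel$strand,
    db$novel$frame,
    ifelse(is.na(db$novel$junction_class), "NA", db$novel$junction_class),
    db$novel$sample_id)
  seqs <- c(db$novel$sequence, unname(db$reference))
  names(seqs) <- c(headers, names(db$reference))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a search database back from FASTA
#'
#' Reconstructs a `search_database` from a FASTA written by
#' [write_search_fasta()]: records whose header starts with `nep|` are
#' parsed back into the novel-entry schema; all other records are treated
#' as reference proteins. Provenance merged at deduplication time is not
#' recoverable from headers; each entry carries its primary event location.
#'
#' @param path FASTA path.
#' @return A `search_database`.
#' @export
read_search_fasta <- function(path) {
  rec <- Biostrings::readAAStringSet(path)
  is_novel <- grepl("^nep\\|", names(rec))
  nov <- rec[is_novel]
  field <- function(key) {
    sub(sprintf("^.*\\|%s=([^|]*)(\\|.*)?$", key), "\\1", names(nov))
  }
  novel <- tibble::tibble(
    entry_id = sub("^nep\\|([^|]+)\\|.*$", "\\1", names(nov)),
    sequence = unname(as.character(nov)),
    event_kind = field("kind"),
    loc = field("loc"),
    strand = field("strand"),
    frame = as.integer(field("frame")),
    junction_class = dplyr::na_if(field("class"), "NA"),
    sample_id = field("sample"),
    provenance = "read_search_fasta"
  ) |>
    dplyr::mutate(
      contig = sub(":.*$", "", .data$loc),
      all_kinds = purrr::map(.data$event_kind, identity),
      all_locs = purrr::map2(.data$event_kind, .data$loc,
                             ~ paste0(.x, "@", .y)))
  reference <- as.character(rec[!is_novel])
  kinds <- c("snv", "indel", "junction", "fusion")
  per_kind <- lapply(kinds, function(k) sum(novel$event_kind == k))
  names(per_kind) <- paste0("n_", kinds)
  mean_orf <- lapply(kinds, function(k) {
    s <- novel$sequence[novel$event_kind == k]
    if (length(s) == 0L) NA_real_ else mean(nchar(s))
  })
  names(mean_orf) <- kinds
  manifest <- c(per_kind, list(n_novel = nrow(novel),
                               n_reference = length(reference),
                               n_total = nrow(novel) + length(reference),
                               mean_orf_aa = mean_orf))
  structure(list(novel = novel, reference = reference, manifest = manifest),
            class = "search_database")
}

#' Write a database manifest to JSON
#'
#' @param db A `search_database`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(db, path) {
  jsonlite::write_json(db$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
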