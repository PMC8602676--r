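#' Load a PSM export table
#'
#' Reads a tab-separated peptide-spectrum-match export with columns
#' `peptide`, `xcorr`, `q_value`, `rt`, `accessions`, `sample`, `spectrum`.
#' Bracketed modification annotations (e.g. `M[+15.995]`) are stripped to
#' the bare sequence and peptides are uppercased. Rows above the q-value
#' threshold are dropped at load, mirroring a 1% target FDR.
#'
#' @param path Path to the PSM TSV.
#' @param fdr_threshold Maximum q-value retained (default 0.01).
#' @return Tibble of PSM records.
#' @export
load_psm_table <- function(path, fdr_threshold = 0.01) {
  if (!file.exists(path)) stop("PSM table not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("peptide", "xcorr", "q_value", "rt", "accessions", "sample",
              "spectrum")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0L) {
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tb |>
    dplyr::mutate(
      peptide = toupper(gsub("\\[[^]]*\\]", "", .data$peptide)),
      xcorr = as.numeric(.data$xcorr),
      q_value = as.numeric(.data$q_value),
      rt = as.numeric(.data$rt),
      accessions = as.character(.data$accessions)
    )
  if (any(is.na(out$xcorr)) || any(is.na(out$q_value)) || any(is.na(out$rt))) {
    stop("unparsable numeric field in PSM table", call. = FALSE)
  }
  stopifnot(all(out$xcorr >= 0), all(out$q_value >= 0 & out$q_value <= 1),
            all(nchar(out$peptide) >= 1L))
  out <- dplyr::filter(out, .data$q_value <= fdr_threshold)
  message(sprintf("load_psm_table: %d PSM(s) in, %d at q <= %g", nrow(tb),
                  nrow(out), fdr_threshold))
  out
}

#' Collapse PSMs to peptide candidates
#'
#' One candidate per distinct peptide sequence: the best (maximum) Xcorr
#' over its PSMs, the arithmetic mean retention time, the union of sample
#' identifiers, and references to every novel database entry containing the
#' peptide as an exact substring. A peptide matching no novel entry and
#' carrying no accession is incoherent input and raises an error.
#'
#' @param psms Tibble from [load_psm_table()].
#' @param db A `search_database` from [assemble_database()].
#' @return Tibble of peptide candidates: `peptide`, `best_xcorr`, `mean_rt`,
#'   `n_psms`, `samples` (list), `entry_ids` (list), `event_kinds` (list),
#'   `event_locs` (list of `kind@loc` strings).
#' @export
collapse_to_candidates <- function(psms, db) {
  cand <- psms |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      best_xcorr = max(.data$xcorr),
      mean_rt = mean(.data$rt),
      n_psms = dplyr::n(),
      samples = list(sort(unique(.data$sample))),
      accessions = paste(.data$accessions, collapse = ";"),
      .groups = "drop"
    )
  novel_seq <- db$novel$sequence
  hits <- purrr::map(cand$peptide, function(p) {
    which(stringr::str_detect(novel_seq, stringr::fixed(p)))
  })
  no_hit <- lengths(hits) == 0L &
    !nzchar(gsub("NA|;", "", cand$accessions))
  if (any(no_hit)) {
    stop("peptide(s) matching no novel entry and no accession: ",
         paste(utils::head(cand$peptide[no_hit], 3), collapse = ", "),
         call. = FALSE)
  }
  cand |>
    dplyr::mutate(
      entry_ids = purrr::map(hits, ~ db$novel$entry_id[.x]),
      event_kinds = purrr::map(hits, ~ sort(unique(db$novel$event_kind[.x]))),
      event_locs = purrr::map(hits, function(i) {
        sort(unique(unlist(db$novel$all_locs[i])))
      })
    ) |>
    dplyr::select(-"accessions")
}
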