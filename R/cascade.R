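#' Normal-tissue catalogs for tumor-specificity filtering
#'
#' Bundles the three normal-tissue knowledge sources used by the filtration
#' cascade: peptides observed in healthy tissue proteomics (e.g. childhood
#' cerebellum), splice-junction coordinates observed in normal-tissue
#' RNA-seq (a GTEx-style catalog), and fusion breakpoint pairs observed in
#' normal tissue. Coordinates use the package-wide 0-based convention.
#'
#' @param peptides Character vector of normal peptide sequences.
#' @param junctions Tibble with columns `contig`, `donor`, `acceptor`.
#' @param fusions Tibble with columns `contig5`, `break5`, `contig3`,
#'   `break3`.
#' @return A list of class `normal_catalogs`.
#' @export
normal_catalogs <- function(peptides = character(),
                            junctions = NULL, fusions = NULL) {
  if (is.null(junctions)) {
    junctions <- tibble::tibble(contig = character(), donor = integer(),
                                acceptor = integer())
  }
  if (is.null(fusions)) {
    fusions <- tibble::tibble(contig5 = character(), break5 = integer(),
                              contig3 = character(), break3 = integer())
  }
  structure(list(peptides = toupper(peptides), junctions = junctions,
                 fusions = fusions), class = "normal_catalogs")
}

#' Read a normal peptide list (one sequence per line)
#' @param path File path.
#' @return Character vector of uppercased sequences.
#' @export
read_normal_peptides <- function(path) {
  toupper(readr::read_lines(path, progress = FALSE))
}

#' Read a normal junction catalog (TSV: contig, donor, acceptor; 0-based)
#' @param path File path.
#' @return Tibble with columns `contig`, `donor`, `acceptor`.
#' @export
read_normal_junctions <- function(path) {
  readr::read_tsv(path, col_names = c("contig", "donor", "acceptor"),
                  col_types = "cii", progress = FALSE)
}

#' Read a normal fusion catalog (TSV: contig5, break5, contig3, break3)
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_normal_fusions <- function(path) {
  readr::read_tsv(path, col_names = c("contig5", "break5", "contig3",
                                      "break3"),
                  col_types = "cici", progress = FALSE)
}

#' Cascade configuration
#'
#' @param min_len Minimum peptide length retained (default 8: shorter than
#'   8-mers are culled).
#' @param min_xcorr Xcorr threshold; retention requires `best_xcorr >
#'   min_xcorr` (strict, default 1).
#' @param fdr_threshold q-value cutoff applied at PSM load (default 0.01).
#' @param il_equivalence Treat I and L as identical during proteome
#'   substring matching (default FALSE).
#' @param slop_nt Coordinate tolerance for normal event-catalog matching
#'   (default 0 = exact).
#' @param stages Character vector of stage names to run, in canonical order.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(min_len = 8L, min_xcorr = 1, fdr_threshold = 0.01,
                           il_equivalence = FALSE, slop_nt = 0L,
                           stages = c("reference_match", "quality",
                                      "normal_peptides", "proteome_scan",
                                      "event_catalog")) {
  structure(list(min_len = as.integer(min_len), min_xcorr = min_xcorr,
                 fdr_threshold = fdr_threshold,
                 il_equivalence = isTRUE(il_equivalence),
                 slop_nt = as.integer(slop_nt), stages = stages),
            class = "cascade_config")
}

new_stage <- function(name, candidates, keep) {
  tibble::tibble(stage = name, n_in = length(keep),
                 n_removed = sum(!keep), n_out = sum(keep),
                 removed = list(sort(candidates$peptide[!keep])))
}

#' Stage 1 — remove peptides matching annotated reference proteins
#'
#' Removes every candidate whose sequence occurs as an exact substring of
#' any reference protein. Matching is by sequence, not by search-engine
#' accession assignment, which is export-dialect-free and strictly stronger.
#'
#' @param candidates Candidate tibble from [collapse_to_candidates()].
#' @param proteomes List of protein sequence vectors and/or FASTA paths.
#' @return List with `candidates` (retained) and `stage` (ledger row).
#' @export
stage_reference_match <- function(candidates, proteomes) {
  seqs <- load_proteome_seqs(proteomes)
  keep <- !peptide_in_proteome(candidates$peptide, seqs, il_equivalence = FALSE)
  list(candidates = candidates[keep, ],
       stage = new_stage("reference_match", candidates, keep))
}

#' Stage 2 — peptide quality (length and Xcorr)
#'
#' Retains candidates of at least `min_len` residues with best Xcorr
#' strictly above `min_xcorr`.
#'
#' @inheritParams stage_reference_match
#' @param min_len,min_xcorr See [cascade_config()].
#' @return List with `candidates` and `stage`.
#' @export
stage_quality <- function(candidates, min_len = 8L, min_xcorr = 1) {
  keep <- nchar(candidates$peptide) >= min_len &
    candidates$best_xcorr > min_xcorr
  list(candidates = candidates[keep, ],
       stage = new_stage("quality", candidates, keep))
}

#' Stage 3 — remove peptides observed in normal-tissue proteomics
#'
#' @inheritParams stage_reference_match
#' @param catalogs A [normal_catalogs()].
#' @return List with `candidates` and `stage`.
#' @export
stage_normal_peptides <- function(candidates, catalogs) {
  keep <- !(candidates$peptide %in% catalogs$peptides)
  list(candidates = candidates[keep, ],
       stage = new_stage("normal_peptides", candidates, keep))
}

#' Stage 4 — exact-match scan against additional proteome annotations
#'
#' Removes candidates occurring as exact full-length substrings in any of
#' the provided proteomes (the role BLASTP 100%-identity/100%-coverage hits
#' play in the original workflow). With `il_equivalence`, isoleucine and
#' leucine are treated as identical during matching, since MS cannot
#' distinguish them.
#'
#' @inheritParams stage_reference_match
#' @param il_equivalence Logical.
#' @return List with `candidates` and `stage`.
#' @export
stage_proteome_scan <- function(candidates, proteomes,
                                il_equivalence = FALSE) {
  seqs <- load_proteome_seqs(proteomes)
  keep <- !peptide_in_proteome(candidates$peptide, seqs, il_equivalence)
  list(candidates = candidates[keep, ],
       stage = new_stage("proteome_scan", candidates, keep))
}

#' Stage 5 — remove peptides whose generating events occur in normal tissue
#'
#' A junction-derived candidate is removed when its exact (contig, donor,
#' acceptor) coordinates appear in the normal junction catalog; a
#' fusion-derived candidate when both breakpoint arms match a normal fusion
#' pair. SNV/indel-derived candidates pass unchanged (this stage is scoped
#' to fusion and junction events). A candidate with several generating
#' events is removed only when every one of them is normal: a single
#' tumor-only source suffices for tumor specificity.
#'
#' @inheritParams stage_reference_match
#' @param catalogs A [normal_catalogs()].
#' @param slop_nt Coordinate tolerance (default 0 = exact).
#' @return List with `candidates` and `stage`.
#' @export
stage_event_catalog <- function(candidates, catalogs, slop_nt = 0L) {
  if (!all(c("event_locs", "event_kinds") %in% names(candidates))) {
    stop("candidate table lacking event provenance columns", call. = FALSE)
  }
  all_normal <- vapply(candidates$event_locs, function(locs) {
    if (length(locs) == 0L) return(FALSE)  # reference-only: not removable here
    all(vapply(locs, event_is_normal, logical(1),
               catalogs = catalogs, slop_nt = slop_nt))
  }, logical(1))
  keep <- !all_normal
  list(candidates = candidates[keep, ],
       stage = new_stage("event_catalog", candidates, keep))
}

# one "kind@loc" string against the normal catalogs; snv/indel are never
# normal-event removable
event_is_normal <- function(loc, catalogs, slop_nt = 0L) {
  kind <- sub("@.*$", "", loc)
  body <- sub("^[^@]*@", "", loc)
  if (kind %in% c("snv", "indel")) return(FALSE)
  if (kind == "junction") {
    m <- regmatches(body, regexec("^(.+):(\\d+)-(\\d+)$", body))[[1]]
    nj <- catalogs$junctions
    return(any(nj$contig == m[2] &
                 abs(nj$donor - as.integer(m[3])) <= slop_nt &
                 abs(nj$acceptor - as.integer(m[4])) <= slop_nt))
  }
  if (kind == "fusion") {
    arms <- strsplit(body, ";", fixed = TRUE)[[1]]
    p5 <- regmatches(arms[1], regexec("^(.+):(\\d+)-", arms[1]))[[1]]
    p3 <- regmatches(arms[2], regexec("^(.+):(\\d+)-", arms[2]))[[1]]
    nf <- catalogs$fusions
    return(any(nf$contig5 == p5[2] &
                 abs(nf$break5 - as.integer(p5[3])) <= slop_nt &
                 nf$contig3 == p3[2] &
                 abs(nf$break3 - as.integer(p3[3])) <= slop_nt))
  }
  FALSE
}

load_proteome_seqs <- function(proteomes) {
  if (length(proteomes) == 0L) return(character())
  unlist(lapply(proteomes, function(p) {
    if (length(p) == 1L && is.character(p) && file.exists(p)) {
      as.character(Biostrings::readAAStringSet(p))
    } else {
      as.character(p)
    }
  }), use.names = FALSE)
}

# exact full-length substring membership of each peptide in any proteome
# sequence, optionally with I/L collapsed
peptide_in_proteome <- function(peptides, proteome_seqs, il_equivalence) {
  if (length(proteome_seqs) == 0L || length(peptides) == 0L) {
    return(rep(FALSE, length(peptides)))
  }
  if (il_equivalence) {
    peptides <- gsub("I", "L", peptides, fixed = TRUE)
    proteome_seqs <- gsub("I", "L", proteome_seqs, fixed = TRUE)
  }
  haystack <- paste(proteome_seqs, collapse = "\x01")
  stringr::str_detect(haystack, stringr::fixed(peptides))
}

#' Run the five-stage tumor-specificity filtration cascade
#'
#' Canonical order: reference match, quality, normal-tissue peptides,
#' proteome scan, event catalog. Stages 1, 3, 4 and 5 are pure set
#' subtractions (idempotent and order-insensitive for the survivor set);
#' the per-stage ledger attribution is order-sensitive, and a peptide
#' qualifying for several removals is attributed to the earliest stage.
#'
#' @param psms Tibble from [load_psm_table()].
#' @param db A `search_database`.
#' @param proteomes List of FASTA paths / sequence vectors for the
#'   additional proteome scan (stage 4). Stage 1 uses the database's own
#'   reference proteome.
#' @param catalogs A [normal_catalogs()].
#' @param config A [cascade_config()].
#' @return List of class `cascade_result`: `candidates` (survivors with
#'   provenance) and `ledger` (a `filter_ledger`).
#' @export
run_cascade <- function(psms, db, proteomes = list(),
                        catalogs = normal_catalogs(),
                        config = cascade_config()) {
  cand <- collapse_to_candidates(psms, db)
  stages <- list()
  for (s in config$stages) {
    r <- switch(s,
      reference_match = stage_reference_match(cand, list(db$reference)),
      quality = stage_quality(cand, config$min_len, config$min_xcorr),
      normal_peptides = stage_normal_peptides(cand, catalogs),
      proteome_scan = stage_proteome_scan(cand, proteomes,
                                          config$il_equivalence),
      event_catalog = stage_event_catalog(cand, catalogs, config$slop_nt),
      stop("unknown stage: ", s, call. = FALSE))
    cand <- r$candidates
    stages <- c(stages, list(r$stage))
  }
  stage_tbl <- if (length(stages) == 0L) {
    tibble::tibble(stage = "identity", n_in = nrow(cand), n_removed = 0L,
                   n_out = nrow(cand))
  } else {
    dplyr::bind_rows(stages)
  }
  ledger <- new_filter_ledger(stage_tbl)
  structure(list(candidates = cand, ledger = ledger),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> ", nrow(x$candidates), " surviving candidate(s)\n",
      sep = "")
  print(x$ledger)
  invisible(x)
}

#' Cohort-level peptide frequency table
#'
#' @param candidates Final candidate tibble (with a `samples` list-column)
#'   or a long tibble with columns `peptide` and `sample_id`.
#' @param cohort_size Number of samples in the cohort; defaults to the
#'   number of distinct samples observed.
#' @return Tibble `peptide`, `event_kind`, `n_samples`, `fraction`, sorted
#'   by descending `n_samples` with lexicographic tie-break.
#' @export
cohort_frequency <- function(candidates, cohort_size = NULL) {
  if ("samples" %in% names(candidates)) {
    long <- candidates |>
      dplyr::mutate(event_kind = purrr::map_chr(.data$event_kinds, function(k)
        paste(k, collapse = "+"))) |>
      dplyr::select("peptide", "event_kind", "samples") |>
      tidyr::unnest_longer("samples", values_to = "sample_id")
  } else {
    long <- dplyr::mutate(candidates, event_kind = NA_character_)
  }
  if (is.null(cohort_size)) cohort_size <- dplyr::n_distinct(long$sample_id)
  long |>
    dplyr::distinct(.data$peptide, .data$event_kind, .data$sample_id) |>
    dplyr::count(.data$peptide, .data$event_kind, name = "n_samples") |>
    dplyr::mutate(fraction = .data$n_samples / cohort_size) |>
    dplyr::arrange(dplyr::desc(.data$n_samples), .data$peptide)
}
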