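#' Simulate a PSM table over an assembled database with known ground truth
#'
#' Draws peptides by in-silico digestion from four ground-truth classes —
#' tumor-specific (from entries whose generating events are tumor-only),
#' reference (from the reference proteome), normal-tissue (novel peptides
#' planted into the healthy-tissue peptide list), and normal-event (from
#' entries all of whose generating events were planted into the normal
#' event catalogs) — then emits spectrum-level rows with Xcorr and q-values
#' from the spec's distributions and retention times following
#' `RT = intercept + slope * HI + Gaussian(0, sigma)`. The first peptide of
#' every class in every sample receives a second PSM so retention-time
#' averaging is exercised, and one extra PSM above the q-value threshold is
#' planted to exercise load-time FDR filtering.
#'
#' @param spec A [fixture_spec()].
#' @param db A `search_database` built from the fixture's events.
#' @param events Event table from [make_events()] (`$events`).
#' @param reference Result of [make_reference()].
#' @param dir Output directory for the PSM TSV and normal peptide list.
#' @return List with `psms` (tibble), `truth` (tibble `peptide`, `label`),
#'   `normal_peptides` (character) and `paths`.
#' @export
simulate_psms <- function(spec, db, events, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 2L)
  coeffs <- hi_coefficients()

  label_of <- stats::setNames(events$label,
                              paste0(events$kind, "@", events$loc))
  entry_labels <- vapply(db$novel$all_locs, function(locs) {
    labs <- label_of[locs]
    if (all(!is.na(labs)) && all(labs == "normal_event")) "normal_event"
    else "tumor"
  }, character(1))
  tumor_entries <- db$novel$sequence[entry_labels == "tumor"]
  normal_entries <- db$novel$sequence[entry_labels == "normal_event"]

  usable <- function(peps) {
    peps <- unique(peps)
    peps[nchar(peps) >= 8L & nchar(peps) <= 30L &
           !grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)]
  }
  digest_pool <- function(seqs) {
    usable(unlist(lapply(seqs, digest_in_silico, enzyme = spec$enzyme,
                         max_missed = spec$max_missed)))
  }
  ref_seqs <- unname(reference$proteins)
  in_ref <- function(peps) peptide_in_proteome(peps, ref_seqs, FALSE)
  in_seqs <- function(peps, seqs) peptide_in_proteome(peps, seqs, FALSE)

  tumor_pool <- digest_pool(tumor_entries)
  tumor_pool <- tumor_pool[!in_ref(tumor_pool)]
  normal_event_pool <- digest_pool(normal_entries)
  normal_event_pool <- normal_event_pool[!in_ref(normal_event_pool) &
                                           !in_seqs(normal_event_pool,
                                                    tumor_entries)]
  reference_pool <- digest_pool(ref_seqs)

  # normal-tissue peptides come out of the tumor pool, then leave it
  n_nt <- min(spec$n_normal_psms, max(0L, length(tumor_pool) -
                                        spec$n_tumor_psms))
  normal_tissue_peps <- if (n_nt > 0L)
    sample(tumor_pool, n_nt) else character()
  tumor_pool <- setdiff(tumor_pool, normal_tissue_peps)

  pools <- list(tumor = tumor_pool, reference = reference_pool,
                normal_tissue = normal_tissue_peps,
                normal_event = normal_event_pool)
  wanted <- c(tumor = spec$n_tumor_psms, reference = spec$n_reference_psms,
              normal_tissue = length(normal_tissue_peps),
              normal_event = spec$n_normal_event_psms)
  empty <- names(wanted)[wanted > 0L & lengths(pools) == 0L]
  if (length(empty) > 0L) {
    stop("no peptides available for class(es): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }

  ref_accession <- function(pep) {
    hit <- which(in_seqs_single(pep, ref_seqs))
    if (length(hit) == 0L) "nep" else names(reference$proteins)[hit[1]]
  }

  rows <- list()
  truth <- list()
  spec_no <- 0L
  for (s in seq_len(spec$n_samples)) {
    sample_id <- sprintf("S%d", s)
    for (cls in names(pools)) {
      pool <- pools[[cls]]
      k <- min(wanted[[cls]], length(pool))
      if (k == 0L) next
      peps <- sample(pool, k)
      peps <- c(peps, peps[1])  # one duplicate PSM per class and sample
      hi <- predict_hi_all(peps, coeffs)
      rt_true <- spec$rt_intercept + spec$rt_slope * hi
      acc <- if (cls == "reference")
        vapply(peps, ref_accession, character(1)) else rep("nep", length(peps))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        peptide = peps,
        xcorr = pmax(1.05, stats::rnorm(length(peps), spec$xcorr_mean,
                                        spec$xcorr_sd)),
        q_value = stats::runif(length(peps), 5e-4, 9e-3),
        rt = rt_true + stats::rnorm(length(peps), 0, spec$rt_sigma),
        accessions = unname(acc),
        sample = sample_id,
        spectrum = sprintf("sc%05d", spec_no + seq_along(peps)))
      spec_no <- spec_no + length(peps)
      truth[[length(truth) + 1L]] <- tibble::tibble(peptide = peps,
                                                    label = cls)
    }
  }
  psms <- dplyr::bind_rows(rows)
  # one high-q distractor duplicating an already-planted tumor PSM
  if (nrow(psms) > 0L) {
    d <- psms[psms$accessions == "nep", ][1, ]
    d$q_value <- 0.02
    d$spectrum <- sprintf("sc%05d", spec_no + 1L)
    psms <- dplyr::bind_rows(psms, d)
  }
  truth <- dplyr::distinct(dplyr::bind_rows(truth))
  stopifnot(!anyDuplicated(truth$peptide))  # labels exclusive

  paths <- list(psms = file.path(dir, "psms.tsv"),
                normal_peptides = file.path(dir, "normal_peptides.txt"))
  readr::write_tsv(psms, paths$psms, progress = FALSE)
  writeLines(normal_tissue_peps, paths$normal_peptides)
  list(psms = psms, truth = truth, normal_peptides = normal_tissue_peps,
       paths = paths)
}

in_seqs_single <- function(pep, seqs) {
  stringr::str_detect(seqs, stringr::fixed(pep))
}

#' Generate a complete synthetic fixture
#'
#' End-to-end orchestration: reference (genome, annotation, proteome),
#' events (VCF, junction BED12, fusion TSV, normal catalogs), database
#' build through the package's own readers and builders, and a simulated
#' PSM table with ground truth. Everything is written under `dir` and is
#' byte-deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param quiet Suppress reader progress messages (default TRUE).
#' @return List with `reference`, `events`, `junctions` (filtered +
#'   classified tibble), `db` (`search_database`), `sim` (PSM simulation),
#'   `catalogs` (a [normal_catalogs()]) and `paths`.
#' @export
make_fixture <- function(spec, dir = tempfile("fixture"), quiet = TRUE) {
  run <- if (quiet) suppressMessages else identity
  run({
    reference <- make_reference(spec, dir)
    ev <- make_events(spec, reference, dir)
    junctions <- read_junction_bed(ev$paths$bed) |>
      filter_junctions(reference$annotation) |>
      classify_junctions(reference$annotation)
    variants <- read_vcf(ev$paths$vcf, reference$annotation)
    fusions <- read_fusion_calls(ev$paths$fusions)
    entries <- dplyr::bind_rows(
      translate_junctions(junctions, reference$genome),
      build_all_fusion_orfs(fusions, reference$genome,
                            flank_nt = spec$flank_nt),
      build_all_variant_proteins(variants, reference$annotation,
                                 reference$genome))
    db <- assemble_database(entries, reference$paths$proteome)
    sim <- simulate_psms(spec, db, ev$events, reference, dir)
    catalogs <- normal_catalogs(
      peptides = sim$normal_peptides,
      junctions = read_normal_junctions(ev$paths$normal_junctions),
      fusions = read_normal_fusions(ev$paths$normal_fusions))
  })
  list(reference = reference, events = ev, junctions = junctions,
       db = db, sim = sim, catalogs = catalogs,
       paths = c(reference$paths, ev$paths, sim$paths))
}
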