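#' Load transcript annotation from a GTF file
#'
#' Parses an Ensembl-dialect GTF (exon and CDS features with `gene_id` /
#' `transcript_id` attributes) into an indexed annotation object. All
#' coordinates are converted to the package-wide 0-based half-open
#' convention at parse time. Exons and CDS are stored in transcription order
#' (5' to 3' of the transcript), so minus-strand transcripts list their
#' genomically rightmost exon first.
#'
#' @param path Path to a GTF file.
#' @return A `transcript_annotation` object: a list with tibbles `genes`,
#'   `transcripts`, `exons`, `cds` and the deduplicated `splice_sites` set
#'   (one row per annotated intron: contig, donor, acceptor, strand; donor is
#'   the exclusive end of the upstream-in-genome exon, acceptor the 0-based
#'   start of the downstream-in-genome exon).
#' @export
load_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = if ("transcript_id" %in% names(GenomicRanges::mcols(gr)))
      gr$transcript_id else NA_character_
  )
  exons <- dplyr::filter(df, .data$type == "exon")
  cds <- dplyr::filter(df, .data$type == "CDS")
  if (nrow(exons) == 0L) stop("GTF contains no exon features", call. = FALSE)
  if (any(is.na(exons$transcript_id))) {
    stop("exon feature without transcript_id attribute", call. = FALSE)
  }
  order_tx <- function(x) {
    x |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(rank = ifelse(.data$strand == "-",
                                  dplyr::n() - dplyr::row_number() + 1L,
                                  dplyr::row_number())) |>
      dplyr::arrange(.data$rank, .by_group = TRUE) |>
      dplyr::ungroup() |>
      dplyr::select("transcript_id", "gene_id", "contig", "start", "end",
                    "strand", "rank")
  }
  exons <- order_tx(exons)
  cds <- order_tx(cds)

  genes <- exons |>
    dplyr::distinct(.data$gene_id, .data$contig, .data$strand)
  transcripts <- exons |>
    dplyr::distinct(.data$transcript_id, .data$gene_id, .data$contig,
                    .data$strand)

  # introns in genomic order within each transcript, then deduplicated
  splice_sites <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      contig = .data$contig[-dplyr::n()],
      donor = .data$end[-dplyr::n()],
      acceptor = .data$start[-1L],
      strand = .data$strand[-dplyr::n()]
    ) |>
    dplyr::distinct(.data$contig, .data$donor, .data$acceptor, .data$strand)

  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons, cds = cds,
         splice_sites = splice_sites),
    class = "transcript_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  # exon intervals within a transcript must not overlap
  ov <- ann$exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      bad = dplyr::n() > 1L && any(.data$start[-1L] < .data$end[-dplyr::n()])
    )
  if (any(ov$bad)) {
    stop("overlapping exons within transcript(s): ",
         paste(ov$transcript_id[ov$bad], collapse = ", "), call. = FALSE)
  }
  # every CDS interval must be contained in an exon of its transcript
  if (nrow(ann$cds) > 0L) {
    contained <- purrr::pmap_lgl(
      ann$cds[, c("transcript_id", "start", "end")],
      function(transcript_id, start, end) {
        ex <- ann$exons[ann$exons$transcript_id == transcript_id, ]
        any(ex$start <= start & end <= ex$end)
      }
    )
    if (!all(contained)) {
      stop("CDS interval(s) not contained in an exon of their transcript",
           call. = FALSE)
    }
  }
  invisible(ann)
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat("<transcript_annotation> ", nrow(x$genes), " gene(s), ",
      nrow(x$transcripts), " transcript(s), ", nrow(x$exons), " exon(s), ",
      nrow(x$splice_sites), " annotated intron(s)\n", sep = "")
  invisible(x)
}

#' Spliced CDS of a transcript with per-base genomic coordinates
#'
#' Concatenates a transcript's CDS intervals in transcription order and
#' returns the spliced coding sequence together with the genomic position of
#' every base (used for variant substitution).
#'
#' @param annotation A `transcript_annotation`.
#' @param transcript_id Transcript identifier.
#' @param genome A `genome_sequence`.
#' @return List with `seq` (coding sequence, 5'->3'), `genomic_pos`
#'   (0-based genomic position of each base), `contig`, `strand`.
#' @export
spliced_cds <- function(annotation, transcript_id, genome) {
  cds <- annotation$cds[annotation$cds$transcript_id == transcript_id, ]
  if (nrow(cds) == 0L) {
    stop("transcript has no annotated CDS: ", transcript_id, call. = FALSE)
  }
  strand <- cds$strand[1]
  pieces <- purrr::pmap(cds[, c("contig", "start", "end")],
                        function(contig, start, end) {
    list(seq = extract_region(genome, contig, start, end, strand),
         pos = if (strand == "+") start:(end - 1L) else (end - 1L):start)
  })
  list(seq = paste(vapply(pieces, `[[`, character(1), "seq"), collapse = ""),
       genomic_pos = unlist(lapply(pieces, `[[`, "pos")),
       contig = cds$contig[1], strand = strand)
}
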