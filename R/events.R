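#' Event-level inclusion filter configuration
#'
#' Defaults follow the discovery workflow this package implements: junctions
#' need at least 5 supporting reads, variants must carry FILTER=PASS and
#' overlap an annotated CDS.
#'
#' @param min_junction_reads Minimum read support for a junction (default 5).
#' @param require_variant_pass Keep only FILTER=PASS variants (default TRUE).
#' @param coding_only_variants Keep only variants overlapping an annotated
#'   CDS interval (default TRUE).
#' @return A list of class `event_filter_config`.
#' @export
event_filter_config <- function(min_junction_reads = 5L,
                                require_variant_pass = TRUE,
                                coding_only_variants = TRUE) {
  stopifnot(min_junction_reads >= 0L)
  structure(list(min_junction_reads = as.integer(min_junction_reads),
                 require_variant_pass = isTRUE(require_variant_pass),
                 coding_only_variants = isTRUE(coding_only_variants)),
            class = "event_filter_config")
}

#' Read somatic variant calls from a VCF file
#'
#' Multi-allelic records are split into one row per ALT allele. Positions are
#' converted to 0-based. With the default configuration only FILTER=PASS
#' records that overlap an annotated CDS are returned.
#'
#' @param path Path to a VCF 4.x file.
#' @param annotation A `transcript_annotation` (required when
#'   `coding_only_variants` is on).
#' @param config An [event_filter_config()].
#' @param sample_id Sample label attached to every event.
#' @return Tibble of variant events: `contig`, `pos` (0-based), `ref`, `alt`,
#'   `filter_status`, `variant_type` (snv/indel), `sample_id`.
#' @export
read_vcf <- function(path, annotation = NULL,
                     config = event_filter_config(),
                     sample_id = "sample") {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(as.matrix(fixm))  # single-record VCF
  fix <- tibble::as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter_status = character(),
                          variant_type = character(),
                          sample_id = character()))
  }
  ev <- fix |>
    dplyr::mutate(pos = as.integer(.data$POS) - 1L) |>
    dplyr::rename(contig = "CHROM", ref = "REF",
                  filter_status = "FILTER") |>
    dplyr::select("contig", "pos", "ref", alt = "ALT", "filter_status") |>
    tidyr::separate_longer_delim("alt", delim = ",") |>
    dplyr::mutate(
      ref = toupper(.data$ref), alt = toupper(.data$alt),
      variant_type = ifelse(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L,
                            "snv", "indel"),
      sample_id = sample_id
    )
  if (any(ev$ref == ev$alt) || any(!nzchar(ev$ref)) || any(!nzchar(ev$alt))) {
    stop("malformed variant record: empty allele or REF == ALT", call. = FALSE)
  }
  n_raw <- nrow(ev)
  if (config$require_variant_pass) {
    ev <- dplyr::filter(ev, .data$filter_status == "PASS")
  }
  if (config$coding_only_variants) {
    if (is.null(annotation)) {
      stop("coding_only_variants requires a transcript annotation",
           call. = FALSE)
    }
    in_cds <- purrr::map2_lgl(ev$contig, ev$pos, function(ct, p) {
      any(annotation$cds$contig == ct & annotation$cds$start <= p &
            p < annotation$cds$end)
    })
    ev <- ev[in_cds, ]
  }
  message(sprintf("read_vcf: %d record(s) in, %d retained", n_raw, nrow(ev)))
  ev
}

#' Read splice junctions from a BED12 file
#'
#' Expects the junction-extraction dialect: one record per junction, exactly
#' two blocks (the flanking exonic anchors, sized by the longest spliced
#' read), read support in the score column. The donor coordinate is the
#' exclusive end of the left block (`chromStart + blockSizes[1]`) and the
#' acceptor the 0-based start of the right block
#' (`chromEnd - blockSizes[2]`). Records with a block count other than two
#' are rejected with a warning and parsing continues.
#'
#' @param path Path to a BED12 file.
#' @param sample_id Sample label attached to every event.
#' @return Tibble of junction events: `contig`, `donor`, `acceptor`, `strand`
#'   (`+`, `-` or `*` for unknown), `read_support`, `left_block`,
#'   `right_block`, `name`, `sample_id`.
#' @export
read_junction_bed <- function(path, sample_id = "sample") {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("not a BED12 file (no blocks): ", path,
                               call. = FALSE)
  n_blocks <- lengths(gr$blocks)
  bad <- n_blocks != 2L
  if (any(bad)) {
    warning(sum(bad), " junction record(s) without exactly 2 blocks rejected",
            call. = FALSE)
  }
  gr <- gr[!bad]
  if (any(is.na(gr$score))) stop("non-numeric score column", call. = FALSE)
  left <- vapply(gr$blocks, function(b) IRanges::width(b)[1], integer(1))
  right <- vapply(gr$blocks, function(b) IRanges::width(b)[2], integer(1))
  chrom_start <- GenomicRanges::start(gr) - 1L
  chrom_end <- GenomicRanges::end(gr)
  out <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    donor = chrom_start + left,
    acceptor = chrom_end - right,
    strand = as.character(GenomicRanges::strand(gr)),
    read_support = as.integer(gr$score),
    left_block = left,
    right_block = right,
    name = if (is.null(gr$name)) NA_character_ else gr$name,
    sample_id = sample_id
  )
  stopifnot(all(out$donor < out$acceptor), all(out$left_block >= 1L),
            all(out$right_block >= 1L), all(out$read_support >= 0L))
  message(sprintf("read_junction_bed: %d record(s) retained", nrow(out)))
  out
}

#' Read normalized fusion breakpoint calls
#'
#' Consumes a tab-separated table with one row per caller-level fusion call.
#' Duplicate breakpoints reported by different callers are retained as
#' distinct rows; deduplication happens at database-build time.
#'
#' @param path Path to a TSV with header columns `contig5`, `break5`,
#'   `strand5`, `contig3`, `break3`, `strand3`, `caller`, `reads`.
#' @param sample_id Sample label attached to every event.
#' @return Tibble of fusion events with those columns plus `sample_id`;
#'   breakpoints 0-based.
#' @export
read_fusion_calls <- function(path, sample_id = "sample") {
  if (!file.exists(path)) stop("fusion TSV not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("contig5", "break5", "strand5", "contig3", "break3", "strand3",
              "caller", "reads")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0L) {
    stop("fusion table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(suppressWarnings(as.integer(tb$reads))))) {
    stop("non-integer value in 'reads' column", call. = FALSE)
  }
  out <- tb |>
    dplyr::mutate(break5 = as.integer(.data$break5),
                  break3 = as.integer(.data$break3),
                  reads = as.integer(.data$reads),
                  sample_id = sample_id) |>
    dplyr::select(dplyr::all_of(needed), "sample_id")
  message(sprintf("read_fusion_calls: %d call(s) retained", nrow(out)))
  out
}

#' Filter junctions by read support and annotation membership
#'
#' Retains junctions with `read_support >= min_junction_reads` whose exact
#' (contig, donor, acceptor) coordinates are absent from the annotated intron
#' set. Strand is ignored for membership because unstranded junction callers
#' emit `.`; identity is exact genomic coordinates. Input order is preserved
#' and the operation is idempotent.
#'
#' @param junctions Tibble from [read_junction_bed()].
#' @param annotation A `transcript_annotation`.
#' @param config An [event_filter_config()].
#' @return The retained subset of `junctions`.
#' @export
filter_junctions <- function(junctions, annotation,
                             config = event_filter_config()) {
  known <- paste(annotation$splice_sites$contig, annotation$splice_sites$donor,
                 annotation$splice_sites$acceptor)
  keep <- junctions$read_support >= config$min_junction_reads &
    !(paste(junctions$contig, junctions$donor, junctions$acceptor) %in% known)
  out <- junctions[keep, ]
  message(sprintf("filter_junctions: %d in, %d retained", nrow(junctions),
                  nrow(out)))
  out
}
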