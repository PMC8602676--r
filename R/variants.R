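#' Build variant proteins from a coding variant
#'
#' For every transcript whose spliced CDS fully contains the variant's
#' reference allele, the alternate allele is substituted into the coding
#' sequence (reverse-complemented for minus-strand transcripts) and the
#' edited CDS is translated from the annotated start. SNVs yield a full
#' variant protein truncated at the first stop; frameshift indels continue
#' in the shifted frame to the first downstream stop. Proteins identical to
#' the reference translation (synonymous changes) are dropped, and distinct
#' transcripts yielding the same variant protein produce one entry.
#'
#' @param variant One-row tibble (or list) with `contig`, `pos` (0-based),
#'   `ref`, `alt`, `variant_type`, `sample_id`.
#' @param annotation A `transcript_annotation`.
#' @param genome A `genome_sequence`.
#' @return Tibble of novel protein entries (see [novel_entry_tibble()]).
#' @export
build_variant_proteins <- function(variant, annotation, genome) {
  v <- as.list(variant)
  ref_len <- nchar(v$ref)
  ref_span <- v$pos:(v$pos + ref_len - 1L)
  hits <- annotation$cds |>
    dplyr::filter(.data$contig == v$contig, .data$start <= v$pos,
                  v$pos < .data$end) |>
    dplyr::distinct(.data$transcript_id)
  out <- purrr::map(hits$transcript_id, function(tx) {
    cds <- spliced_cds(annotation, tx, genome)
    idx <- match(ref_span, cds$genomic_pos)
    if (anyNA(idx)) return(NULL)  # ref allele not fully within this CDS
    if (cds$strand == "+") {
      ref_tx <- v$ref
      alt_tx <- v$alt
    } else {
      idx <- rev(idx)               # transcript order of the ref bases
      ref_tx <- reverse_complement(v$ref)
      alt_tx <- reverse_complement(v$alt)
    }
    if (any(diff(idx) != 1L)) return(NULL)  # ref interrupted by an intron
    tx_start <- idx[1]
    observed <- substr(cds$seq, tx_start, tx_start + ref_len - 1L)
    if (!identical(observed, ref_tx)) {
      stop(sprintf(
        "variant %s:%d ref '%s' inconsistent with genome ('%s' in %s)",
        v$contig, v$pos, v$ref, observed, tx), call. = FALSE)
    }
    edited <- paste0(substr(cds$seq, 1L, tx_start - 1L), alt_tx,
                     substr(cds$seq, tx_start + ref_len, nchar(cds$seq)))
    ref_prot <- truncate_at_stop(translate_frame(cds$seq, 0L))
    var_prot <- truncate_at_stop(translate_frame(edited, 0L))
    if (identical(var_prot, ref_prot) || nchar(var_prot) == 0L) return(NULL)
    tibble::tibble(
      sequence = var_prot,
      event_kind = ifelse(identical(v$variant_type, "indel"), "indel", "snv"),
      contig = v$contig,
      loc = sprintf("%s:%d-%d", v$contig, v$pos, v$pos + ref_len),
      strand = cds$strand, frame = 0L,
      junction_class = NA_character_,
      sample_id = v$sample_id %||% NA_character_,
      provenance = sprintf("%s;%s>%s;tx=%s", v$variant_type, v$ref, v$alt, tx)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(novel_entry_tibble())
  res |>
    dplyr::group_by(.data$sequence) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

truncate_at_stop <- function(peptide) {
  sub("\\*.*$", "", peptide)
}

#' Build variant proteins for a table of variants
#'
#' @param variants Tibble from [read_vcf()].
#' @inheritParams build_variant_proteins
#' @return Tibble of novel protein entries for all variants.
#' @export
build_all_variant_proteins <- function(variants, annotation, genome) {
  if (nrow(variants) == 0L) return(novel_entry_tibble())
  dplyr::bind_rows(purrr::map(seq_len(nrow(variants)), function(i) {
    build_variant_proteins(variants[i, ], annotation, genome)
  }))
}
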