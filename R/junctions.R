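#' Classify unannotated junctions into the six aberrant-junction types
#'
#' Each junction end is labeled against the annotated exons of its contig:
#' `boundary` when it coincides with the matching exon edge (the donor with
#' an exon end, the acceptor with an exon start, 0-based half-open),
#' `overlap` when it falls strictly inside an exon, and `none` otherwise.
#' The label pair maps to exactly one type:
#'
#' * 1 — both ends on known exon boundaries; subtype `a` when the matched
#'   exons share a gene (alternative splicing), `b` otherwise (fusion-like);
#' * 2 — one end on an exon boundary, the other inside a known exon;
#' * 3 — one end on an exon boundary, the other in a non-exon region;
#' * 4 — both ends inside known exons;
#' * 5 — one end inside a known exon, the other in a non-exon region;
#' * 6 — both ends in non-exon regions (intronic or intergenic).
#'
#' The six types are exhaustive: every junction receives exactly one class.
#'
#' @param junctions Tibble from [read_junction_bed()] /
#'   [filter_junctions()].
#' @param annotation A `transcript_annotation`.
#' @return The input tibble with columns `junction_class` (e.g. `"1a"`,
#'   `"3"`) appended, plus the per-end labels `donor_label`, `acceptor_label`.
#' @export
classify_junctions <- function(junctions, annotation) {
  ex <- annotation$exons
  cls <- purrr::pmap(junctions[, c("contig", "donor", "acceptor")],
                     function(contig, donor, acceptor) {
    exc <- ex[ex$contig == contig, ]
    d_bound <- exc$end == donor
    a_bound <- exc$start == acceptor
    d_lab <- end_label(donor, exc, any(d_bound))
    a_lab <- end_label(acceptor, exc, any(a_bound))
    if (d_lab == "boundary" && a_lab == "boundary") {
      shared <- intersect(exc$gene_id[d_bound], exc$gene_id[a_bound])
      cls <- if (length(shared) > 0L) "1a" else "1b"
    } else {
      key <- paste(sort(c(d_lab, a_lab)), collapse = "/")
      cls <- switch(key,
        "boundary/overlap" = "2",
        "boundary/none" = "3",
        "overlap/overlap" = "4",
        "none/overlap" = "5",
        "none/none" = "6")
    }
    list(junction_class = cls, donor_label = d_lab, acceptor_label = a_lab)
  })
  dplyr::bind_cols(
    junctions,
    tibble::tibble(
      junction_class = vapply(cls, `[[`, character(1), "junction_class"),
      donor_label = vapply(cls, `[[`, character(1), "donor_label"),
      acceptor_label = vapply(cls, `[[`, character(1), "acceptor_label")
    )
  )
}

# label one junction end: boundary beats overlap; a coordinate strictly
# inside any exon (not just touching its edge) is an overlap
end_label <- function(coord, exons_on_contig, is_boundary) {
  if (is_boundary) return("boundary")
  inside <- any(exons_on_contig$start < coord & coord < exons_on_contig$end)
  if (inside) "overlap" else "none"
}

#' Translate a junction's spliced sequence in three frames per strand
#'
#' The spliced sequence is the left block (ending at the donor) concatenated
#' with the right block (starting at the acceptor), oriented by the junction
#' strand. Each frame's translation is split at stop codons; every stop-free
#' segment that spans the splice boundary (draws at least one nucleotide from
#' each block) and has at least `min_orf_aa` residues is emitted. Junctions
#' with unknown strand (`*`) are translated on both strands.
#'
#' @param junction One-row tibble (or list) with `contig`, `donor`,
#'   `acceptor`, `strand`, `left_block`, `right_block`, `sample_id` and
#'   optionally `junction_class`.
#' @param genome A `genome_sequence`.
#' @param min_orf_aa Minimum emitted segment length in amino acids
#'   (default 7, mirroring the fusion rule of more than 6 consecutive
#'   residues).
#' @return Tibble of novel protein entries (see [novel_entry_tibble()]).
#' @export
translate_junction <- function(junction, genome, min_orf_aa = 7L) {
  j <- as.list(junction)
  left_start <- j$donor - j$left_block
  right_end <- j$acceptor + j$right_block
  left <- extract_region(genome, j$contig, left_start, j$donor, "+")
  right <- extract_region(genome, j$contig, j$acceptor, right_end, "+")
  spliced <- paste0(left, right)
  strands <- if (identical(j$strand, "+") || identical(j$strand, "-"))
    j$strand else c("+", "-")
  out <- purrr::map(strands, function(st) {
    seq <- if (st == "+") spliced else reverse_complement(spliced)
    brk <- if (st == "+") nchar(left) else nchar(right)
    purrr::map(0:2, function(f) {
      segs <- spanning_orf_segments(translate_frame(seq, f), f, brk,
                                    min_orf_aa)
      if (nrow(segs) == 0L) return(NULL)
      tibble::tibble(
        sequence = segs$sequence,
        event_kind = "junction",
        contig = j$contig,
        loc = sprintf("%s:%d-%d", j$contig, j$donor, j$acceptor),
        strand = st, frame = f,
        junction_class = j$junction_class %||% NA_character_,
        sample_id = j$sample_id %||% NA_character_,
        provenance = sprintf("junction;support=%s",
                             j$read_support %||% NA)
      )
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(res) == 0L) novel_entry_tibble() else res
}

# split a frame's translation at stops; return stop-free segments whose
# nucleotide footprint crosses `break_nt` (0-based index of the first
# nucleotide of the right-hand part) with >= min_aa residues
spanning_orf_segments <- function(peptide, frame, break_nt, min_aa) {
  if (nchar(peptide) == 0L) {
    return(tibble::tibble(sequence = character(), aa_start = integer()))
  }
  aa <- strsplit(peptide, "")[[1]]
  runs <- rle(aa != "*")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_aa
  if (!any(keep)) {
    return(tibble::tibble(sequence = character(), aa_start = integer()))
  }
  seg <- tibble::tibble(aa_start = starts[keep], aa_end = ends[keep]) |>
    dplyr::mutate(
      nt_start = frame + 3L * (.data$aa_start - 1L),
      nt_end = frame + 3L * .data$aa_end,
      sequence = substring(peptide, .data$aa_start, .data$aa_end)
    ) |>
    dplyr::filter(.data$nt_start < break_nt, .data$nt_end > break_nt)
  seg[, c("sequence", "aa_start")]
}

#' Translate many junctions
#'
#' @param junctions Tibble of (classified) junction events.
#' @inheritParams translate_junction
#' @return Tibble of novel protein entries for all junctions.
#' @export
translate_junctions <- function(junctions, genome, min_orf_aa = 7L) {
  if (nrow(junctions) == 0L) return(novel_entry_tibble())
  dplyr::bind_rows(purrr::map(seq_len(nrow(junctions)), function(i) {
    translate_junction(junctions[i, ], genome, min_orf_aa)
  }))
}
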