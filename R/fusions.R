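#' Build fusion open reading frames across a breakpoint
#'
#' The fused nucleotide sequence joins the strand-oriented `flank_nt`
#' nucleotides ending at the 5' arm's breakpoint to the `flank_nt`
#' nucleotides starting at the 3' arm's breakpoint. It is translated in all
#' six frames; every maximal stop-to-stop amino-acid run with more than six
#' residues whose codons draw sequence from both arms is emitted. Flanks
#' that would run off a contig are clipped with a warning.
#'
#' @param fusion One-row tibble (or list) with `contig5`, `break5`,
#'   `strand5`, `contig3`, `break3`, `strand3`, `caller`, `reads`,
#'   `sample_id` (breakpoints 0-based).
#' @param genome A `genome_sequence`.
#' @param flank_nt Nucleotides taken from each arm (default 999 = 333 codons).
#' @param require_spanning Emit only breakpoint-spanning ORFs (default TRUE);
#'   turn off to keep every stop-to-stop run longer than six residues.
#' @param min_orf_aa Minimum ORF length; default 7 (more than 6 residues).
#' @return Tibble of novel protein entries (see [novel_entry_tibble()]).
#' @export
build_fusion_orfs <- function(fusion, genome, flank_nt = 999L,
                              require_spanning = TRUE, min_orf_aa = 7L) {
  stopifnot(flank_nt >= 3L)
  f <- as.list(fusion)
  arm5 <- fusion_arm_seq(genome, f$contig5, f$break5, f$strand5,
                         flank_nt, upstream = TRUE)
  arm3 <- fusion_arm_seq(genome, f$contig3, f$break3, f$strand3,
                         flank_nt, upstream = FALSE)
  fused <- paste0(arm5, arm3)
  brk <- nchar(arm5)
  frames <- translate_six_frames(fused)
  out <- purrr::pmap(frames, function(strand, frame, peptide) {
    b <- if (strand == "+") brk else nchar(fused) - brk
    segs <- if (require_spanning) {
      spanning_orf_segments(peptide, frame, b, min_orf_aa)
    } else {
      all_orf_segments(peptide, min_orf_aa)
    }
    if (nrow(segs) == 0L) return(NULL)
    tibble::tibble(
      sequence = segs$sequence,
      event_kind = "fusion",
      contig = f$contig5,
      loc = sprintf("%s:%d-%d;%s:%d-%d", f$contig5, f$break5, f$break5,
                    f$contig3, f$break3, f$break3),
      strand = strand, frame = frame,
      junction_class = NA_character_,
      sample_id = f$sample_id %||% NA_character_,
      provenance = sprintf("fusion;caller=%s;reads=%s",
                           f$caller %||% NA, f$reads %||% NA)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) novel_entry_tibble() else res
}

# stop-to-stop runs of >= min_aa residues, no spanning requirement
all_orf_segments <- function(peptide, min_aa) {
  if (nchar(peptide) == 0L) {
    return(tibble::tibble(sequence = character(), aa_start = integer()))
  }
  aa <- strsplit(peptide, "")[[1]]
  runs <- rle(aa != "*")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_aa
  tibble::tibble(sequence = substring(peptide, starts[keep], ends[keep]),
                 aa_start = starts[keep])
}

# strand-oriented flank around a breakpoint; `upstream` takes the sequence
# transcribed before the breakpoint (5' arm), otherwise after it (3' arm)
fusion_arm_seq <- function(genome, contig, brk, strand, flank_nt, upstream) {
  len <- contig_lengths(genome)[[contig]]
  take_left <- (upstream && strand == "+") || (!upstream && strand == "-")
  if (take_left) {
    start <- max(0L, brk - flank_nt); end <- brk
  } else {
    start <- brk; end <- min(len, brk + flank_nt)
  }
  if (end - start < flank_nt) {
    warning(sprintf("fusion flank clipped to [%d,%d) on %s", start, end,
                    contig), call. = FALSE)
  }
  if (end <= start) return("")
  extract_region(genome, contig, start, end, strand)
}

#' Build fusion ORFs for a table of fusion calls
#'
#' Calls are first deduplicated by breakpoint pair (caller provenance
#' merged), then each unique fusion is translated.
#'
#' @param fusions Tibble from [read_fusion_calls()].
#' @inheritParams build_fusion_orfs
#' @return Tibble of novel protein entries.
#' @export
build_all_fusion_orfs <- function(fusions, genome, flank_nt = 999L,
                                  require_spanning = TRUE, min_orf_aa = 7L) {
  if (nrow(fusions) == 0L) return(novel_entry_tibble())
  uniq <- fusions |>
    dplyr::group_by(.data$contig5, .data$break5, .data$strand5,
                    .data$contig3, .data$break3, .data$strand3,
                    .data$sample_id) |>
    dplyr::summarise(caller = paste(sort(unique(.data$caller)),
                                    collapse = "+"),
                     reads = max(.data$reads), .groups = "drop")
  dplyr::bind_rows(purrr::map(seq_len(nrow(uniq)), function(i) {
    build_fusion_orfs(uniq[i, ], genome, flank_nt, require_spanning,
                      min_orf_aa)
  }))
}
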