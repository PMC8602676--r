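#' Load a genome FASTA into an indexed, uppercase-normalized object
#'
#' Reads every record of a FASTA file into memory and normalizes sequences to
#' uppercase. Contig names are taken as the first whitespace-delimited token
#' of each header and must be unique. Sequences may only contain A, C, G, T
#' and N.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_sequence` object (named list of contig strings with a
#'   `contig_lengths()` accessor via [contig_lengths()]).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path),
      warning = function(w) {
        if (grepl("invalid one-letter sequence", conditionMessage(w))) {
          stop("malformed FASTA '", path, "': invalid sequence characters",
               call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  contigs <- toupper(as.character(seqs))
  names(contigs) <- nm
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig(s) with characters outside {A,C,G,T,N}: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(contigs = contigs), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x$contigs), " contig(s), ",
      format(sum(nchar(x$contigs)), big.mark = ","), " nt total\n", sep = "")
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome A `genome_sequence`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  vapply(genome$contigs, nchar, integer(1))
}

#' Extract a strand-aware genomic interval
#'
#' Coordinates are 0-based, half-open. Plus strand returns the slice as-is;
#' minus strand returns its reverse complement. Out-of-bounds or empty
#' intervals are an error, never a silent truncation.
#'
#' @param genome A `genome_sequence`.
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must be > `start`.
#' @param strand `"+"` or `"-"`.
#' @return A nucleotide string.
#' @export
extract_region <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!contig %in% names(genome$contigs)) {
    stop("unknown contig: ", contig, call. = FALSE)
  }
  seq <- genome$contigs[[contig]]
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (start < 0 || end > nchar(seq) || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds or empty on %s (length %d)",
                 start, end, contig, nchar(seq)), call. = FALSE)
  }
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string over {A,C,G,T,N}.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' The standard codon table
#'
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids, stops as `"*"`.
#' @export
standard_codon_table <- function() {
  Biostrings::GENETIC_CODE
}

#' Translate a nucleotide string in one frame
#'
#' Translation starts at offset `frame` (0, 1 or 2) and drops any trailing
#' partial codon. Stop codons are emitted as `*`. Codons containing `N`
#' translate to `X`; any character outside {A,C,G,T,N} is an error.
#'
#' @param seq Nucleotide string.
#' @param frame Integer 0, 1 or 2.
#' @param table Codon table, as from [standard_codon_table()].
#' @return Amino-acid string (possibly empty), alphabet 20 aa + `*` + `X`.
#' @export
translate_frame <- function(seq, frame = 0L, table = standard_codon_table()) {
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  n_codons <- (nchar(seq) - frame) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(table[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Frames 0-2 on the given sequence and 0-2 on its reverse complement.
#'
#' @param seq Nucleotide string.
#' @param table Codon table.
#' @return Tibble with columns `strand` (+/-), `frame`, `peptide`.
#' @export
translate_six_frames <- function(seq, table = standard_codon_table()) {
  rc <- reverse_complement(seq)
  tibble::tibble(
    strand = rep(c("+", "-"), each = 3L),
    frame = rep(0:2, 2L),
    peptide = c(
      vapply(0:2, function(f) translate_frame(seq, f, table), character(1)),
      vapply(0:2, function(f) translate_frame(rc, f, table), character(1))
    )
  )
}
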