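# Independent brute-force oracles. These deliberately avoid the package's
# own translation / classification / matching code paths: translation is a
# plain codon loop over Biostrings::GENETIC_CODE, interval logic is a naive
# O(n*m) scan, substring matching is a per-position compare.

oracle_translate <- function(seq, frame) {
  tab <- Biostrings::GENETIC_CODE
  out <- character()
  i <- frame + 1L
  while (i + 2L <= nchar(seq)) {
    cod <- substr(seq, i, i + 2L)
    out <- c(out, if (grepl("N", cod)) "X" else unname(tab[cod]))
    i <- i + 3L
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

oracle_six_frames <- function(seq) {
  c(vapply(0:2, function(f) oracle_translate(seq, f), character(1)),
    vapply(0:2, function(f) oracle_translate(oracle_revcomp(seq), f),
           character(1)))
}

# naive per-end junction labeling and six-type mapping over an exon tibble
# (columns contig, start, end, gene_id; 0-based half-open)
oracle_classify <- function(contig, donor, acceptor, exons) {
  lab <- function(coord, is_donor) {
    boundary <- FALSE
    overlap <- FALSE
    genes <- character()
    for (i in seq_len(nrow(exons))) {
      if (exons$contig[i] != contig) next
      edge <- if (is_donor) exons$end[i] else exons$start[i]
      if (edge == coord) {
        boundary <- TRUE
        genes <- c(genes, exons$gene_id[i])
      } else if (exons$start[i] < coord && coord < exons$end[i]) {
        overlap <- TRUE
      }
    }
    state <- if (boundary) "boundary" else if (overlap) "overlap" else "none"
    list(state = state, genes = unique(genes))
  }
  d <- lab(donor, TRUE)
  a <- lab(acceptor, FALSE)
  if (d$state == "boundary" && a$state == "boundary") {
    if (length(intersect(d$genes, a$genes)) > 0L) "1a" else "1b"
  } else {
    key <- paste(sort(c(d$state, a$state)), collapse = "/")
    switch(key, "boundary/overlap" = "2", "boundary/none" = "3",
           "overlap/overlap" = "4", "none/overlap" = "5", "none/none" = "6")
  }
}

# per-position substring membership of pep in any of seqs
oracle_substring <- function(pep, seqs) {
  np <- nchar(pep)
  for (s in seqs) {
    ns <- nchar(s)
    if (ns < np) next
    for (i in seq_len(ns - np + 1L)) {
      if (substr(s, i, i + np - 1L) == pep) return(TRUE)
    }
  }
  FALSE
}

# maximal stop-to-stop runs (> min_aa - 1 residues) in a translation,
# keeping only runs whose codon span crosses nucleotide index break_nt
oracle_spanning_orfs <- function(seq, break_nt_plus, min_aa = 7L) {
  out <- character()
  rc <- oracle_revcomp(seq)
  for (st in c("+", "-")) {
    s <- if (st == "+") seq else rc
    b <- if (st == "+") break_nt_plus else nchar(seq) - break_nt_plus
    for (f in 0:2) {
      pep <- oracle_translate(s, f)
      if (nchar(pep) == 0L) next
      aa <- strsplit(pep, "")[[1]]
      i <- 1L
      while (i <= length(aa)) {
        if (aa[i] == "*") { i <- i + 1L; next }
        j <- i
        while (j < length(aa) && aa[j + 1L] != "*") j <- j + 1L
        nt_start <- f + 3L * (i - 1L)
        nt_end <- f + 3L * j
        if (j - i + 1L >= min_aa && nt_start < b && nt_end > b) {
          out <- c(out, paste(aa[i:j], collapse = ""))
        }
        i <- j + 1L
      }
    }
  }
  sort(unique(out))
}

# write a one-gene toy reference (single exon = whole CDS) and load it
toy_single_gene <- function(cds_nt, strand = "+", pad = 30L) {
  dir <- tempfile("toy")
  dir.create(dir)
  lead <- paste(rep("C", pad), collapse = "")
  tail_ <- paste(rep("G", pad), collapse = "")
  insert <- if (strand == "+") cds_nt else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_nt)))
  contig <- paste0(lead, insert, tail_)
  genome_path <- file.path(dir, "g.fa")
  writeLines(c(">chrT", contig), genome_path)
  s0 <- pad            # 0-based start of the CDS on the genome
  e0 <- pad + nchar(cds_nt)
  attr_str <- 'gene_id "gT"; transcript_id "gT.t1";'
  gtf <- c(
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s", s0 + 1L, e0, strand,
            attr_str),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t%s", s0 + 1L, e0, strand,
            attr_str))
  gtf_path <- file.path(dir, "g.gtf")
  writeLines(gtf, gtf_path)
  list(genome = load_genome(genome_path), annotation = load_gtf(gtf_path),
       cds_start = s0, cds_end = e0, dir = dir)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
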