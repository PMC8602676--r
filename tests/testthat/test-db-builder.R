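test_that("junction classification matches hand-built cases", {
  fx <- make_fixture(fixture_spec(seed = 5))
  ann <- fx$reference$annotation
  g <- fx$reference$genes
  a <- g[g$contig == "chr1", ][1, ]
  b <- g[g$contig == "chr1", ][2, ]
  cases <- tibble::tibble(
    contig = "chr1",
    donor = c(a$exon_ends[[1]][1], a$exon_ends[[1]][1],
              a$exon_ends[[1]][1] - 5L),
    acceptor = c(a$exon_starts[[1]][3], b$exon_starts[[1]][2],
                 a$gene_end + 500L),
    strand = "+", read_support = 10L, left_block = 30L, right_block = 30L,
    name = c("same-gene", "cross-gene", "exonic-to-intergenic"),
    sample_id = "S1")
  got <- classify_junctions(cases, ann)
  expect_identical(got$junction_class, c("1a", "1b", "5"))
  # exon boundary to intron interior is type 3
  t3 <- classify_junctions(tibble::tibble(
    contig = "chr1", donor = a$exon_ends[[1]][1],
    acceptor = a$exon_ends[[1]][1] + 50L,  # inside intron 1
    strand = "+", read_support = 10L, left_block = 30L, right_block = 30L,
    name = "t3", sample_id = "S1"), ann)
  expect_identical(t3$junction_class, "3")
})

test_that("planted fixture junctions recover their intended classes", {
  for (seed in c(21, 22)) {
    fx <- make_fixture(fixture_spec(seed = seed))
    planted <- fx$events$junctions |>
      dplyr::filter(.data$read_support >= 5)
    got <- classify_junctions(planted, fx$reference$annotation)
    expect_identical(got$junction_class, planted$planted_class)
  }
})

test_that("junction translation emits exactly the spanning stop-free segments", {
  # genome: left block ATGGAT | intron CCCC | right block GAATAA
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c", "ATGGATCCCCGAATAA"), f)
  g <- load_genome(f)
  j <- tibble::tibble(contig = "c", donor = 6L, acceptor = 10L, strand = "+",
                      read_support = 9L, left_block = 6L, right_block = 6L,
                      sample_id = "S1")
  got <- translate_junction(j, g, min_orf_aa = 3L)
  expect_true("MDE" %in% got$sequence)
  expect_true(all(got$frame %in% 0:2))
  # frame 2 (GGA TGA ATA: the stop falls on the junction codon) emits
  # no spanning segment
  expect_identical(nrow(got[got$strand == "+" & got$frame == 2L, ]), 0L)
  # unknown strand translates both strands
  j$strand <- "*"
  both <- translate_junction(j, g, min_orf_aa = 2L)
  expect_setequal(unique(both$strand), c("+", "-"))
})

test_that("fusion ORFs are spanning, maximal, >6 aa, and oracle-identical", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 120L
    seq5 <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    seq3 <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    f <- tempfile(fileext = ".fa")
    writeLines(c(">cA", seq5, ">cB", seq3), f)
    g <- load_genome(f)
    fus <- tibble::tibble(contig5 = "cA", break5 = n, strand5 = "+",
                          contig3 = "cB", break3 = 0L, strand3 = "+",
                          caller = "x", reads = 10L, sample_id = "S1")
    got <- suppressWarnings(build_fusion_orfs(fus, g, flank_nt = n))
    fused <- paste0(seq5, seq3)
    expect_setequal(got$sequence, oracle_spanning_orfs(fused, n, 7L))
    expect_true(all(nchar(got$sequence) >= 7L))
    # maximality: each emitted run is flanked by stop or sequence end in
    # its frame's full translation
    for (i in seq_len(nrow(got))) {
      s <- if (got$strand[i] == "+") fused else oracle_revcomp(fused)
      pep <- oracle_translate(s, got$frame[i])
      hit <- regexpr(got$sequence[i], pep, fixed = TRUE)[1]
      left_ok <- hit == 1L || substr(pep, hit - 1L, hit - 1L) == "*"
      right <- hit + nchar(got$sequence[i])
      right_ok <- right > nchar(pep) ||
        substr(pep, right, right) == "*"
      expect_true(left_ok && right_ok)
    }
  }
})

test_that("fusion ORF rules: 6-mers excluded, non-spanning excluded", {
  # frame 0 of fused sequence: *MAAAAAA* spanning; and a 6-aa run elsewhere
  left <- paste0("TAA", "ATGGCTGCAGCT")            # * M A A A
  right <- paste0("GCAGCTGCA", "TAA", "ATGGCTTAA")  # A A A * M A *
  f <- tempfile(fileext = ".fa")
  writeLines(c(">cA", left, ">cB", right), f)
  g <- load_genome(f)
  fus <- tibble::tibble(contig5 = "cA", break5 = nchar(left), strand5 = "+",
                        contig3 = "cB", break3 = 0L, strand3 = "+",
                        caller = "x", reads = 3L, sample_id = "S1")
  got <- suppressWarnings(build_fusion_orfs(fus, g, flank_nt = 30L))
  expect_true("MAAAAAA" %in% got$sequence)  # 7 aa spanning run
  # the 2-aa MA run after the downstream stop is not emitted
  expect_false(any(got$sequence == "MA"))
  # with a 6-residue spanning run only, nothing is emitted
  left6 <- paste0("TAA", "ATGGCTGCA")   # * M A A
  right6 <- paste0("GCTGCAGCT", "TAAT") # A A A *
  writeLines(c(">cA", left6, ">cB", right6), f)
  g6 <- load_genome(f)
  fus6 <- dplyr::mutate(fus, break5 = nchar(left6))
  got6 <- suppressWarnings(build_fusion_orfs(fus6, g6, flank_nt = 30L))
  expect_false(any(got6$strand == "+" & got6$frame == 0L))
})

test_that("variant proteins: missense, synonymous, frameshift", {
  toy <- toy_single_gene("ATGGATGAAAAAGGGTGTTAA")  # MDEKGC
  # GAT -> GTT : D2V (genomic pos of the codon's middle base = cds_start+4)
  v <- tibble::tibble(contig = "chrT", pos = toy$cds_start + 4L, ref = "A",
                      alt = "T", variant_type = "snv", sample_id = "S1")
  got <- build_variant_proteins(v, toy$annotation, toy$genome)
  expect_identical(got$sequence, "MVEKGC")
  # GAT -> GAC : synonymous, dropped
  v2 <- tibble::tibble(contig = "chrT", pos = toy$cds_start + 5L, ref = "T",
                       alt = "C", variant_type = "snv", sample_id = "S1")
  expect_identical(nrow(build_variant_proteins(v2, toy$annotation,
                                               toy$genome)), 0L)
  # incoherent ref allele errors
  v3 <- dplyr::mutate(v, ref = "G")
  expect_error(build_variant_proteins(v3, toy$annotation, toy$genome),
               "inconsistent")
  # 1-nt deletion: frameshift tail equals an independent re-translation
  cds <- "ATGGATGAAAAAGGGTGTTAA"
  v4 <- tibble::tibble(contig = "chrT", pos = toy$cds_start + 6L,
                       ref = "GA", alt = "G", variant_type = "indel",
                       sample_id = "S1")
  got4 <- build_variant_proteins(v4, toy$annotation, toy$genome)
  edited <- paste0(substr(cds, 1, 7), substr(cds, 9, nchar(cds)))
  expected <- sub("\\*.*$", "", oracle_translate(edited, 0))
  expect_identical(got4$sequence, expected)
  expect_identical(got4$event_kind, "indel")
})

test_that("minus-strand variants are substituted in transcript orientation", {
  toy <- toy_single_gene("ATGGATGAAAAAGGGTGTTAA", strand = "-")
  # middle base of codon 2 (D) sits at genomic position cds_end - 5
  v <- tibble::tibble(contig = "chrT", pos = toy$cds_end - 5L, ref = "T",
                      alt = "A", variant_type = "snv", sample_id = "S1")
  got <- build_variant_proteins(v, toy$annotation, toy$genome)
  expect_identical(got$sequence, "MVEKGC")
})

test_that("database assembly deduplicates and keeps manifest arithmetic", {
  prot <- tempfile(fileext = ".fa")
  writeLines(c(">ref|P1|x", "MAAAAAAK", ">ref|P2|y", "MCCCCCCK",
               ">ref|P3|z", "MDDDDDDK", ">ref|P4|w", "MEEEEEEK",
               ">ref|P5|v", "MFFFFFFK"), prot)
  entries <- dplyr::bind_rows(
    tibble::tibble(sequence = "MKWVTFISLLK", event_kind = "junction",
                   contig = "c", loc = "c:10-90", strand = "+", frame = 0L,
                   junction_class = "1a", sample_id = "S1",
                   provenance = "junction"),
    tibble::tibble(sequence = "MKWVTFISLLK", event_kind = "junction",
                   contig = "c", loc = "c:10-90", strand = "+", frame = 2L,
                   junction_class = "1a", sample_id = "S1",
                   provenance = "junction"),
    tibble::tibble(sequence = "MDECCCK", event_kind = "snv", contig = "c",
                   loc = "c:44-45", strand = "+", frame = 0L,
                   junction_class = NA_character_, sample_id = "S1",
                   provenance = "snv"),
    tibble::tibble(sequence = "MWWPPPK", event_kind = "fusion", contig = "c",
                   loc = "c:1-1;c:9-9", strand = "+", frame = 1L,
                   junction_class = NA_character_, sample_id = "S1",
                   provenance = "fusion"))
  db <- assemble_database(entries, prot)
  expect_identical(db$manifest$n_novel, 3L)      # identical pair collapsed
  expect_identical(db$manifest$n_total, 8L)      # 3 novel + 5 reference
  dup <- db$novel[db$novel$sequence == "MKWVTFISLLK", ]
  expect_match(dup$provenance, "junction \\| junction")
  # manifest mean ORF lengths equal an independent recomputation from FASTA
  fa <- tempfile(fileext = ".fa")
  write_search_fasta(db, fa)
  rec <- Biostrings::readAAStringSet(fa)
  novel_rec <- rec[grepl("^nep\\|", names(rec))]
  kinds <- sub("^.*kind=([a-z]+)\\|.*$", "\\1", names(novel_rec))
  for (k in c("snv", "junction", "fusion")) {
    expect_equal(db$manifest$mean_orf_aa[[k]],
                 mean(Biostrings::width(novel_rec[kinds == k])))
  }
  # entries with internal stops are rejected
  badent <- dplyr::mutate(entries[3, ], sequence = "MDE*K")
  expect_error(assemble_database(badent, prot), "stop")
})

test_that("search FASTA round-trips through read_search_fasta", {
  fx <- make_fixture(fixture_spec(seed = 19))
  fa <- tempfile(fileext = ".fa")
  write_search_fasta(fx$db, fa)
  back <- read_search_fasta(fa)
  expect_identical(back$novel$sequence, fx$db$novel$sequence)
  expect_identical(back$novel$event_kind, fx$db$novel$event_kind)
  expect_identical(back$novel$loc, fx$db$novel$loc)
  expect_identical(back$manifest$n_total, fx$db$manifest$n_total)
  # a cascade run against the re-read database finds the same survivors
  res1 <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs))
  res2 <- suppressMessages(run_cascade(
    fx$sim$psms, back, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs))
  expect_identical(res1$candidates$peptide, res2$candidates$peptide)
})
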