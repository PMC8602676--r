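#' Specification for a synthetic proteogenomic fixture
#'
#' Describes a seeded toy dataset: a random genome with multi-exon
#' protein-coding genes, tumor-specific events of every class, normal-tissue
#' catalogs, and a simulated PSM table with known ground-truth labels.
#' Defaults are desk-scale: two contigs of 9 kb, three 3-exon genes per
#' contig, one junction per aberrant-junction class, and PSM score/retention
#' distributions separable enough that the filtration cascade's behavior is
#' determined by peptide identity, not score noise.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_contigs,contig_length Genome shape.
#' @param genes_per_contig,exons_per_gene,exon_aa Gene model shape
#'   (`exon_aa` codons per exon).
#' @param intron_nt Intron length between consecutive exons.
#' @param junction_classes Junction classes to plant (subset of
#'   `c("1a","1b","2","3","4","5","6")`).
#' @param n_low_support_junctions Junctions planted below the read-support
#'   threshold (support `low_support`).
#' @param low_support Read support of the low-support junctions (default 3).
#' @param n_fusions Fusion events planted.
#' @param n_snvs,n_indels Coding variants planted.
#' @param normal_event_fraction Fraction of support-passing junctions and of
#'   fusions copied into the normal event catalogs (the planted
#'   "seen-in-normal-tissue" events).
#' @param n_samples Number of tumor samples simulated.
#' @param n_tumor_psms,n_reference_psms,n_normal_psms,n_normal_event_psms
#'   PSMs drawn per sample for each ground-truth peptide class.
#' @param xcorr_mean,xcorr_sd Xcorr distribution (truncated below at just
#'   above the retention threshold of 1).
#' @param rt_intercept,rt_slope,rt_sigma Retention-time model: RT (minutes)
#'   = intercept + slope * HI + Gaussian(0, sigma).
#' @param enzyme,max_missed In-silico digestion used to draw peptides.
#' @param flank_nt Fusion flank length used at database build.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_contigs = 2L, contig_length = 9000L,
                         genes_per_contig = 3L, exons_per_gene = 3L,
                         exon_aa = 40L, intron_nt = 200L,
                         junction_classes = c("1a", "1b", "2", "3", "4",
                                              "5", "6"),
                         n_low_support_junctions = 1L, low_support = 3L,
                         n_fusions = 2L, n_snvs = 2L, n_indels = 1L,
                         normal_event_fraction = 0.34,
                         n_samples = 2L,
                         n_tumor_psms = 6L, n_reference_psms = 5L,
                         n_normal_psms = 3L, n_normal_event_psms = 3L,
                         xcorr_mean = 2.5, xcorr_sd = 0.5,
                         rt_intercept = 5, rt_slope = 0.45, rt_sigma = 1,
                         enzyme = "lysc", max_missed = 1L,
                         flank_nt = 120L) {
  spec <- as.list(environment())
  stopifnot(spec$seed == as.integer(spec$seed),
            all(unlist(spec[c("n_contigs", "contig_length",
                              "genes_per_contig", "exons_per_gene",
                              "exon_aa", "intron_nt", "n_fusions", "n_snvs",
                              "n_indels", "n_samples")]) >= 0),
            normal_event_fraction >= 0, normal_event_fraction <= 1,
            all(junction_classes %in% c("1a", "1b", "2", "3", "4", "5", "6")))
  structure(spec, class = "fixture_spec")
}

aa_sample_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

# back-translate an amino-acid string with uniformly drawn synonymous codons
back_translate <- function(protein) {
  tab <- standard_codon_table()
  by_aa <- split(names(tab), unname(tab))
  paste(vapply(strsplit(protein, "")[[1]], function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Generate the synthetic reference: genome, annotation, proteome
#'
#' Builds a random genome, plants `genes_per_contig` protein-coding genes per
#' contig (alternating strand, `exons_per_gene` exons, valid start/stop,
#' in-frame, no internal stop), writes genome FASTA, Ensembl-dialect GTF and
#' the reference proteome (the translation of every annotated CDS), then
#' re-loads genome and annotation through the package's own readers.
#' Deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `genome` (`genome_sequence`), `annotation`
#'   (`transcript_annotation`), `proteins` (named character vector),
#'   `genes` (layout tibble) and `paths`.
#' @export
make_reference <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  gene_span <- spec$exons_per_gene * (spec$exon_aa * 3L) +
    (spec$exons_per_gene - 1L) * spec$intron_nt + 3L  # + stop codon
  slot <- (spec$contig_length - 400L) %/% spec$genes_per_contig
  if (gene_span + 200L > slot) {
    stop("infeasible fixture spec: genes exceed contig capacity",
         call. = FALSE)
  }
  contigs <- stats::setNames(
    vapply(seq_len(spec$n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$contig_length, replace = TRUE),
            collapse = "")
    }, character(1)),
    paste0("chr", seq_len(spec$n_contigs)))

  gtf_lines <- character()
  proteins <- character()
  genes <- list()
  g_idx <- 0L
  for (ct in names(contigs)) {
    for (gi in seq_len(spec$genes_per_contig)) {
      g_idx <- g_idx + 1L
      gene_id <- sprintf("g%d", g_idx)
      strand <- if (g_idx %% 2L == 1L) "+" else "-"
      g_start <- 200L + (gi - 1L) * slot  # 0-based
      prot <- paste(c("M", sample(aa_sample_alphabet(),
                                  spec$exons_per_gene * spec$exon_aa - 1L,
                                  replace = TRUE)), collapse = "")
      cds_nt <- paste0(back_translate(prot), "TAA")
      # transcript-order exon chunks; stop codon joins the last exon
      chunk_nt <- rep(spec$exon_aa * 3L, spec$exons_per_gene)
      chunk_nt[spec$exons_per_gene] <- chunk_nt[spec$exons_per_gene] + 3L
      chunks <- substring(cds_nt, cumsum(c(1L, chunk_nt[-length(chunk_nt)])),
                          cumsum(chunk_nt))
      # genomic order: plus strand keeps transcript order; minus reverses
      genomic_chunks <- if (strand == "+") chunks else
        unname(vapply(rev(chunks), reverse_complement, character(1)))
      widths <- nchar(genomic_chunks)
      starts <- g_start + cumsum(c(0L, (widths + spec$intron_nt)[-length(widths)]))
      ends <- starts + widths
      for (k in seq_along(starts)) {
        substr(contigs[[ct]], starts[k] + 1L, ends[k]) <- genomic_chunks[k]
      }
      tx_id <- paste0(gene_id, ".t1")
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id, tx_id)
      feat <- function(type, s, e) {
        sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s", ct, type, s + 1L, e,
                strand, attr_str)
      }
      gtf_lines <- c(gtf_lines,
                     feat("gene", min(starts), max(ends)),
                     feat("transcript", min(starts), max(ends)),
                     unlist(lapply(seq_along(starts), function(k)
                       c(feat("exon", starts[k], ends[k]),
                         feat("CDS", starts[k], ends[k])))))
      proteins[[sprintf("ref|%s|%s", toupper(gene_id), gene_id)]] <- prot
      genes[[g_idx]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = tx_id, contig = ct,
        strand = strand, gene_start = min(starts), gene_end = max(ends),
        exon_starts = list(starts), exon_ends = list(ends))
    }
  }
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                proteome = file.path(dir, "reference_proteome.fa"))
  writeLines(unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]]))), paths$genome)
  writeLines(gtf_lines, paths$gtf)
  writeLines(unlist(lapply(names(proteins), function(n)
    c(paste0(">", n), proteins[[n]]))), paths$proteome)
  list(genome = load_genome(paths$genome),
       annotation = load_gtf(paths$gtf),
       proteins = proteins,
       genes = dplyr::bind_rows(genes),
       paths = paths)
}

#' Generate tumor-specific events and normal catalogs for a fixture
#'
#' Plants one junction per requested class (constructed directly from the
#' toy annotation's exon layout), low-support junctions that must fall to
#' the read-support filter, fusion breakpoints, and coding SNVs/indels.
#' A `normal_event_fraction` of the support-passing junctions and of the
#' fusions is copied into the normal event catalogs, emulating events also
#' observed in normal-tissue RNA-seq. Writes VCF, junction BED12, fusion
#' TSV and the normal catalogs; returns the event-level ground truth.
#'
#' @param spec A [fixture_spec()].
#' @param reference Result of [make_reference()].
#' @param dir Output directory.
#' @return List with `paths`, `events` (tibble: kind, loc key, label
#'   `tumor` / `normal_event` / `below_support` / `distractor`) and the
#'   written tables.
#' @export
make_events <- function(spec, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  genes <- reference$genes
  ann <- reference$annotation
  sample_id <- "S1"

  exon_edge <- function(gene_row, which_exon, edge) {
    if (edge == "start") gene_row$exon_starts[[1]][which_exon]
    else gene_row$exon_ends[[1]][which_exon]
  }
  # midpoints of the gap after each gene on its contig (safe intergenic)
  intergenic_point <- function(contig, after_pos) {
    ex <- ann$exons[ann$exons$contig == contig, ]
    p <- after_pos + spec$intron_nt %/% 2L + 25L
    while (any(ex$start <= p & p < ex$end) || any(ex$end == p) ||
             any(ex$start == p)) p <- p + 7L
    p
  }

  per_contig <- split(genes, genes$contig)
  g1 <- per_contig[[1]]
  if (nrow(g1) < 3L && any(c("1b", "2", "4") %in% spec$junction_classes)) {
    stop("junction class 1b/2/4 not constructible: need 3 genes per contig",
         call. = FALSE)
  }
  jl <- list()
  add_j <- function(contig, donor, acceptor, strand, class) {
    tibble::tibble(contig = contig, donor = donor, acceptor = acceptor,
                   strand = strand, planted_class = class)
  }
  a <- g1[1, ]; b <- g1[2, ]; c_ <- g1[3, ]
  for (cl in spec$junction_classes) {
    jl[[cl]] <- switch(cl,
      "1a" = add_j(a$contig, exon_edge(a, 1, "end"),
                   exon_edge(a, 3, "start"), a$strand, "1a"),
      "1b" = add_j(a$contig, exon_edge(a, 2, "end"),
                   exon_edge(b, 2, "start"), a$strand, "1b"),
      "2" = add_j(b$contig, exon_edge(b, 1, "end"),
                  exon_edge(c_, 2, "start") + 10L, b$strand, "2"),
      "3" = add_j(c_$contig, exon_edge(c_, 1, "end"),
                  intergenic_point(c_$contig, c_$gene_end), c_$strand, "3"),
      "4" = add_j(a$contig, exon_edge(a, 1, "end") - 10L,
                  exon_edge(b, 1, "start") + 10L, "*", "4"),
      "5" = add_j(b$contig, exon_edge(b, 2, "end") - 10L,
                  intergenic_point(b$contig, b$gene_end), "*", "5"),
      "6" = add_j(a$contig, intergenic_point(a$contig, a$gene_end),
                  intergenic_point(a$contig, a$gene_end + 400L), "*", "6"))
  }
  junctions <- dplyr::bind_rows(jl) |>
    dplyr::mutate(read_support = sample(6:30, dplyr::n(), replace = TRUE),
                  label = "tumor")
  # low-support junctions: same construction as 1a on another gene
  if (spec$n_low_support_junctions > 0L) {
    g_other <- genes[nrow(genes), ]
    low <- add_j(g_other$contig, exon_edge(g_other, 1, "end"),
                 exon_edge(g_other, 3, "start"), g_other$strand, "1a") |>
      dplyr::mutate(read_support = spec$low_support, label = "below_support")
    junctions <- dplyr::bind_rows(
      junctions, low[rep(1L, spec$n_low_support_junctions), ])
  }
  # plant a fraction of passing junctions into the normal catalog
  passing <- which(junctions$label == "tumor")
  n_norm_j <- round(spec$normal_event_fraction * length(passing))
  if (n_norm_j > 0L) {
    norm_idx <- sample(passing, n_norm_j)
    junctions$label[norm_idx] <- "normal_event"
  }
  junctions <- junctions |>
    dplyr::mutate(left_block = 60L, right_block = 60L,
                  name = sprintf("J%03d", dplyr::row_number()),
                  sample_id = sample_id)

  # fusions: arm5 at an exon boundary of a gene on contig 1, arm3 on the
  # last contig; both-caller duplication for the first event
  fus <- list()
  for (i in seq_len(spec$n_fusions)) {
    ga <- genes[(i - 1L) %% nrow(g1) + 1L, ]
    gb <- genes[nrow(genes) - (i - 1L) %% spec$genes_per_contig, ]
    fus[[i]] <- tibble::tibble(
      contig5 = ga$contig, break5 = exon_edge(ga, 1, "end"),
      strand5 = ga$strand,
      contig3 = gb$contig, break3 = exon_edge(gb, 2, "start"),
      strand3 = gb$strand,
      caller = "callerA", reads = sample(5:40, 1L),
      sample_id = sample_id)
  }
  fusions <- dplyr::bind_rows(fus) |>
    dplyr::mutate(label = "tumor")
  n_norm_f <- round(spec$normal_event_fraction * nrow(fusions))
  if (n_norm_f > 0L) {
    fusions$label[sample.int(nrow(fusions), n_norm_f)] <- "normal_event"
  }

  # coding variants: brute-force an alternate base that changes the protein
  variants <- make_variant_records(spec, reference)

  paths <- list(vcf = file.path(dir, "variants.vcf"),
                bed = file.path(dir, "junctions.bed"),
                fusions = file.path(dir, "fusions.tsv"),
                normal_junctions = file.path(dir, "normal_junctions.tsv"),
                normal_fusions = file.path(dir, "normal_fusions.tsv"))
  write_fixture_vcf(variants, reference, paths$vcf)
  write_fixture_bed12(junctions, paths$bed)
  fus_out <- fusions |>
    dplyr::select("contig5", "break5", "strand5", "contig3", "break3",
                  "strand3", "caller", "reads")
  # first fusion confirmed by a second caller (dedup exercised downstream)
  if (nrow(fus_out) > 0L) {
    fus_out <- dplyr::bind_rows(
      fus_out, dplyr::mutate(fus_out[1, ], caller = "callerB"))
  }
  readr::write_tsv(fus_out, paths$fusions, progress = FALSE)
  nj <- junctions |>
    dplyr::filter(.data$label == "normal_event") |>
    dplyr::select("contig", "donor", "acceptor")
  readr::write_tsv(nj, paths$normal_junctions, col_names = FALSE,
                   progress = FALSE)
  nf <- fusions |>
    dplyr::filter(.data$label == "normal_event") |>
    dplyr::select("contig5", "break5", "contig3", "break3")
  readr::write_tsv(nf, paths$normal_fusions, col_names = FALSE,
                   progress = FALSE)

  events <- dplyr::bind_rows(
    junctions |>
      dplyr::transmute(kind = "junction",
                       loc = sprintf("%s:%d-%d", .data$contig, .data$donor,
                                     .data$acceptor),
                       planted_class = .data$planted_class,
                       label = .data$label),
    fusions |>
      dplyr::transmute(kind = "fusion",
                       loc = sprintf("%s:%d-%d;%s:%d-%d", .data$contig5,
                                     .data$break5, .data$break5,
                                     .data$contig3, .data$break3,
                                     .data$break3),
                       planted_class = NA_character_,
                       label = .data$label),
    variants |>
      dplyr::transmute(kind = .data$variant_type,
                       loc = sprintf("%s:%d-%d", .data$contig, .data$pos,
                                     .data$pos + nchar(.data$ref)),
                       planted_class = NA_character_,
                       label = .data$label)
  )
  list(paths = paths, events = events, junctions = junctions,
       fusions = fusions, variants = variants)
}

# pick coding positions and alternate alleles that change the protein; adds
# one non-PASS and one intronic distractor record
make_variant_records <- function(spec, reference) {
  genes <- reference$genes
  out <- list()
  n_var <- spec$n_snvs + spec$n_indels
  for (i in seq_len(n_var)) {
    g <- genes[(i - 1L) %% nrow(genes) + 1L, ]
    cds <- spliced_cds(reference$annotation, g$transcript_id,
                       reference$genome)
    ref_prot <- truncate_at_stop(translate_frame(cds$seq, 0L))
    is_indel <- i > spec$n_snvs
    found <- NULL
    tx_positions <- sample(5:(nchar(cds$seq) - 10L))
    for (tp in tx_positions) {
      gpos <- cds$genomic_pos[tp]
      ref_base <- extract_region(reference$genome, g$contig, gpos, gpos + 1L,
                                 "+")
      if (!is_indel) {
        for (alt_base in setdiff(c("A", "C", "G", "T"), ref_base)) {
          tx_alt <- if (g$strand == "+") alt_base else
            reverse_complement(alt_base)
          edited <- cds$seq
          substr(edited, tp, tp) <- tx_alt
          var_prot <- truncate_at_stop(translate_frame(edited, 0L))
          if (!identical(var_prot, ref_prot) && nchar(var_prot) >= 10L) {
            found <- tibble::tibble(contig = g$contig, pos = gpos,
                                    ref = ref_base, alt = alt_base,
                                    variant_type = "snv")
            break
          }
        }
      } else {
        # 1-nt deletion anchored on the previous base (frameshift)
        prev <- extract_region(reference$genome, g$contig, gpos - 1L, gpos,
                               "+")
        # anchored deletions need the anchor inside the same CDS too
        if ((gpos - 1L) %in% cds$genomic_pos) {
          found <- tibble::tibble(contig = g$contig, pos = gpos - 1L,
                                  ref = paste0(prev, ref_base), alt = prev,
                                  variant_type = "indel")
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      stop("could not construct a protein-changing variant in ", g$gene_id,
           call. = FALSE)
    }
    out[[i]] <- dplyr::mutate(found, filter = "PASS", label = "tumor")
  }
  # distractors: a non-PASS coding SNV and a PASS intronic SNV
  g <- genes[1, ]
  cds <- spliced_cds(reference$annotation, g$transcript_id, reference$genome)
  gpos <- cds$genomic_pos[20]
  rb <- extract_region(reference$genome, g$contig, gpos, gpos + 1L, "+")
  out[[n_var + 1L]] <- tibble::tibble(
    contig = g$contig, pos = gpos, ref = rb,
    alt = setdiff(c("A", "C", "G", "T"), rb)[1], variant_type = "snv",
    filter = "germline_risk", label = "distractor")
  ipos <- g$exon_ends[[1]][1] + 5L  # intronic
  rb2 <- extract_region(reference$genome, g$contig, ipos, ipos + 1L, "+")
  out[[n_var + 2L]] <- tibble::tibble(
    contig = g$contig, pos = ipos, ref = rb2,
    alt = setdiff(c("A", "C", "G", "T"), rb2)[1], variant_type = "snv",
    filter = "PASS", label = "distractor")
  dplyr::bind_rows(out) |>
    dplyr::mutate(sample_id = "S1")
}

write_fixture_vcf <- function(variants, reference, path) {
  lens <- contig_lengths(reference$genome)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           "##FILTER=<ID=germline_risk,Description=\"Possible germline\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", variants$contig,
                 variants$pos + 1L, variants$ref, variants$alt,
                 variants$filter)
  writeLines(c(hdr, rec), path)
}

write_fixture_bed12 <- function(junctions, path) {
  j <- junctions
  chrom_start <- j$donor - j$left_block
  chrom_end <- j$acceptor + j$right_block
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
                   j$contig, chrom_start, chrom_end, j$name, j$read_support,
                   ifelse(j$strand == "*", ".", j$strand),
                   chrom_start, chrom_end,
                   j$left_block, j$right_block,
                   0L, j$acceptor - chrom_start)
  writeLines(lines, path)
}
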