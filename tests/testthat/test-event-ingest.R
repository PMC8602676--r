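make_toy_vcf <- function(records) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=200>",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=lowqual,Description=\"no\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    records), f)
  f
}

test_that("VCF reading applies PASS and coding filters and splits ALTs", {
  toy <- toy_single_gene("ATGGATGAAAAATAA")  # CDS at [30,45) on chrT
  # one PASS in CDS, one non-PASS in CDS, one PASS outside CDS
  f <- make_toy_vcf(c(
    "chrT\t35\t.\tA\tT\t.\tPASS\t.",
    "chrT\t36\t.\tT\tC\t.\tlowqual\t.",
    "chrT\t5\t.\tC\tA\t.\tPASS\t."))
  got <- suppressMessages(read_vcf(f, toy$annotation))
  expect_identical(nrow(got), 1L)
  expect_identical(got$pos, 34L)  # 0-based

  all3 <- suppressMessages(read_vcf(
    f, toy$annotation,
    event_filter_config(require_variant_pass = FALSE,
                        coding_only_variants = FALSE)))
  expect_identical(nrow(all3), 3L)

  multi <- make_toy_vcf("chrT\t35\t.\tA\tT,G\t.\tPASS\t.")
  got2 <- suppressMessages(read_vcf(multi, toy$annotation))
  expect_identical(sort(got2$alt), c("G", "T"))
  expect_true(all(got2$variant_type == "snv"))
})

test_that("BED12 junction arithmetic follows the block convention", {
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t400\tJ1\t12\t+\t100\t400\t0\t2\t50,60\t0,240",
    "chr1\t500\t900\tJ2\t7\t.\t500\t900\t0\t2\t40,40\t0,360",
    "chr1\t100\t700\tJ3\t9\t+\t100\t700\t0\t3\t50,60,70\t0,240,530"), f)
  expect_warning(got <- suppressMessages(read_junction_bed(f)), "2 blocks")
  expect_identical(nrow(got), 2L)
  expect_identical(got$donor[1], 150L)
  expect_identical(got$acceptor[1], 340L)
  expect_identical(got$read_support[1], 12L)
  expect_identical(got$strand[2], "*")  # '.' means unknown strand
})

test_that("fusion table reading enforces its schema", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "contig5\tbreak5\tstrand5\tcontig3\tbreak3\tstrand3\tcaller\treads",
    "chr1\t1000\t+\tchr2\t2000\t-\tcallerA\t12",
    "chr1\t1000\t+\tchr2\t2000\t-\tcallerB\t9"), f)
  got <- suppressMessages(read_fusion_calls(f))
  expect_identical(nrow(got), 2L)  # duplicate breakpoints kept per caller
  expect_setequal(got$caller, c("callerA", "callerB"))

  miss <- tempfile(fileext = ".tsv")
  writeLines(c("contig5\tbreak5", "chr1\t10"), miss)
  expect_error(suppressMessages(read_fusion_calls(miss)), "strand5")

  na_reads <- tempfile(fileext = ".tsv")
  writeLines(c(
    "contig5\tbreak5\tstrand5\tcontig3\tbreak3\tstrand3\tcaller\treads",
    "chr1\t1000\t+\tchr2\t2000\t-\tcallerA\tNA"), na_reads)
  expect_error(suppressMessages(read_fusion_calls(na_reads)), "reads")
})

test_that("junction filtering drops low support and annotated introns", {
  fx <- make_fixture(fixture_spec(seed = 3))
  ann <- fx$reference$annotation
  intron <- ann$splice_sites[1, ]
  j <- tibble::tibble(
    contig = c(intron$contig, intron$contig, intron$contig),
    donor = c(intron$donor, intron$donor + 7L, intron$donor + 7L),
    acceptor = c(intron$acceptor, intron$acceptor + 7L, intron$acceptor + 7L),
    strand = "+",
    read_support = c(12L, 4L, 5L),
    left_block = 50L, right_block = 50L,
    name = c("annotated", "low", "boundary"), sample_id = "S1")
  kept <- suppressMessages(filter_junctions(j, ann))
  # annotated removed despite support 12; support 4 < 5 removed;
  # support exactly 5 and unannotated retained
  expect_identical(kept$name, "boundary")
  # idempotent
  expect_identical(suppressMessages(filter_junctions(kept, ann)), kept)
  # every junction annotated -> empty result
  all_ann <- ann$splice_sites |>
    dplyr::mutate(read_support = 50L, left_block = 50L, right_block = 50L,
                  name = "x", sample_id = "S1")
  expect_identical(nrow(suppressMessages(filter_junctions(all_ann, ann))), 0L)
})

test_that("fixture BED12 writing round-trips donor/acceptor/support", {
  fx <- make_fixture(fixture_spec(seed = 4))
  reread <- suppressMessages(read_junction_bed(fx$paths$bed))
  planted <- fx$events$junctions
  expect_identical(reread$donor, planted$donor)
  expect_identical(reread$acceptor, planted$acceptor)
  expect_identical(reread$read_support, planted$read_support)
})
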