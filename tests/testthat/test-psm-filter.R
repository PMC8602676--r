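write_psm_tsv <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("peptide", "xcorr", "q_value", "rt", "accessions",
                     "sample", "spectrum", sep = "\t"), rows), f)
  f
}

tiny_db <- function() {
  prot <- tempfile(fileext = ".fa")
  writeLines(c(">ref|P1|x", "MKWREFPEPTIDEKAAAGGG"), prot)
  entries <- dplyr::bind_rows(
    tibble::tibble(sequence = "MMDESTKWWPLK", event_kind = "junction",
                   contig = "c1", loc = "c1:100-500", strand = "+",
                   frame = 0L, junction_class = "1a", sample_id = "S1",
                   provenance = "junction"),
    tibble::tibble(sequence = "CCHQRNDEKVVK", event_kind = "junction",
                   contig = "c1", loc = "c1:900-1500", strand = "+",
                   frame = 1L, junction_class = "3", sample_id = "S1",
                   provenance = "junction"),
    tibble::tibble(sequence = "WYYFMILDNKGGK", event_kind = "fusion",
                   contig = "c1", loc = "c1:50-50;c2:70-70", strand = "+",
                   frame = 0L, junction_class = NA_character_,
                   sample_id = "S1", provenance = "fusion"),
    tibble::tibble(sequence = "MPPQQWWEEKHHK", event_kind = "snv",
                   contig = "c2", loc = "c2:40-41", strand = "+", frame = 0L,
                   junction_class = NA_character_, sample_id = "S1",
                   provenance = "snv"))
  assemble_database(entries, prot)
}

test_that("PSM loading strips modifications and applies the q-value gate", {
  f <- write_psm_tsv(c(
    "M[+15.995]DESTK\t2.2\t0.001\t10\tnep\tS1\tsc1",
    "MDESTK\t2.0\t0.02\t20\tnep\tS1\tsc2",
    "ndekvvk\t1.8\t0.004\t30\tnep\tS1\tsc3"))
  got <- suppressMessages(load_psm_table(f))
  expect_identical(nrow(got), 2L)           # q = 0.02 dropped
  expect_identical(got$peptide[1], "MDESTK")
  expect_identical(got$peptide[2], "NDEKVVK")

  miss <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\txcorr", "AAA\t2"), miss)
  expect_error(suppressMessages(load_psm_table(miss)), "q_value")
})

test_that("candidate collapse averages RT, unions samples, links entries", {
  db <- tiny_db()
  f <- write_psm_tsv(c(
    "MDESTK\t2.5\t0.001\t10\tnep\tS1\tsc1",
    "MDESTK\t3.1\t0.001\t20\tnep\tS2\tsc2",
    "NDEKVVK\t1.9\t0.002\t33\tnep\tS1\tsc3"))
  psms <- suppressMessages(load_psm_table(f))
  cand <- collapse_to_candidates(psms, db)
  m <- cand[cand$peptide == "MDESTK", ]
  expect_equal(m$mean_rt, 15)
  expect_equal(m$best_xcorr, 3.1)
  expect_identical(m$samples[[1]], c("S1", "S2"))
  expect_identical(m$event_kinds[[1]], "junction")
  # a peptide with no novel match and no accession is incoherent
  f2 <- write_psm_tsv("QQQQQQQQ\t2\t0.001\t5\tNA\tS1\tsc9")
  psms2 <- suppressMessages(load_psm_table(f2))
  expect_error(collapse_to_candidates(psms2, db), "no novel entry")
})

test_that("quality stage enforces the 8-mer and strict Xcorr rules", {
  cand <- tibble::tibble(
    peptide = c("MDESTKA", "AAAAAAAAAAAA", "MDESTKAB", "OKOKOKOK"),
    best_xcorr = c(3.0, 0.9, 1.2, 1.0))
  r <- stage_quality(cand, min_len = 8L, min_xcorr = 1)
  # 7-mer removed; Xcorr 0.9 removed; Xcorr exactly 1 removed (strict);
  # 8-mer with Xcorr 1.2 retained
  expect_identical(r$candidates$peptide, "MDESTKAB")
  expect_identical(r$stage$n_in, 4L)
  expect_identical(r$stage$n_removed, 3L)
})

test_that("reference and proteome scans remove exact substrings only", {
  cand <- tibble::tibble(peptide = c("REFPEPTIDEK", "MIDEKWWW", "MLDEKWWW"),
                         best_xcorr = 3)
  prote <- "AAREFPEPTIDEKCC"
  r1 <- stage_reference_match(cand, list(prote))
  expect_setequal(r1$candidates$peptide, c("MIDEKWWW", "MLDEKWWW"))
  # 1-aa mismatch is retained; I/L equivalence collapses it when enabled
  r4 <- stage_proteome_scan(cand, list("XXMLDEKWWWXX"), il_equivalence = FALSE)
  expect_false("MLDEKWWW" %in% r4$candidates$peptide)
  expect_true("MIDEKWWW" %in% r4$candidates$peptide)
  r4il <- stage_proteome_scan(cand, list("XXMLDEKWWWXX"), il_equivalence = TRUE)
  expect_false("MIDEKWWW" %in% r4il$candidates$peptide)
  # empty proteome list is the identity
  r0 <- stage_proteome_scan(cand, list())
  expect_identical(r0$candidates, cand)
})

test_that("normal-peptide and event-catalog stages respect provenance", {
  db <- tiny_db()
  f <- write_psm_tsv(c(
    "MMDESTKWWPLK\t2.5\t0.001\t10\tnep\tS1\tsc1",   # junction c1:100-500
    "CCHQRNDEKVVK\t2.5\t0.001\t12\tnep\tS1\tsc2",   # junction c1:900-1500
    "WYYFMILDNKGGK\t2.5\t0.001\t14\tnep\tS1\tsc3",  # fusion
    "MPPQQWWEEKHHK\t2.5\t0.001\t16\tnep\tS1\tsc4")) # snv
  cand <- collapse_to_candidates(suppressMessages(load_psm_table(f)), db)
  cat_norm <- normal_catalogs(
    peptides = "CCHQRNDEKVVK",
    junctions = tibble::tibble(contig = "c1", donor = 100L, acceptor = 500L),
    fusions = tibble::tibble(contig5 = "c1", break5 = 50L,
                             contig3 = "c2", break3 = 70L))
  r3 <- stage_normal_peptides(cand, cat_norm)
  expect_false("CCHQRNDEKVVK" %in% r3$candidates$peptide)
  r5 <- stage_event_catalog(cand, cat_norm)
  # junction with normal coordinates and fusion with both arms normal removed
  expect_false("MMDESTKWWPLK" %in% r5$candidates$peptide)
  expect_false("WYYFMILDNKGGK" %in% r5$candidates$peptide)
  # snv-derived peptides always pass the event-catalog stage
  expect_true("MPPQQWWEEKHHK" %in% r5$candidates$peptide)
  # fusion matching only one arm is retained
  cat_arm <- normal_catalogs(fusions = tibble::tibble(
    contig5 = "c1", break5 = 50L, contig3 = "c2", break3 = 999L))
  r5b <- stage_event_catalog(cand, cat_arm)
  expect_true("WYYFMILDNKGGK" %in% r5b$candidates$peptide)
  # slop window admits near-miss coordinates
  cat_slop <- normal_catalogs(junctions = tibble::tibble(
    contig = "c1", donor = 102L, acceptor = 498L))
  expect_true("MMDESTKWWPLK" %in%
                stage_event_catalog(cand, cat_slop)$candidates$peptide)
  expect_false("MMDESTKWWPLK" %in%
                 stage_event_catalog(cand, cat_slop,
                                     slop_nt = 2L)$candidates$peptide)
})

test_that("multi-event peptides survive unless every event is normal", {
  prot <- tempfile(fileext = ".fa")
  writeLines(c(">r|P|p", "MMMMMMMM"), prot)
  shared <- "WQENDYFHKPLR"
  entries <- dplyr::bind_rows(
    tibble::tibble(sequence = paste0("AAK", shared), event_kind = "junction",
                   contig = "c1", loc = "c1:10-20", strand = "+", frame = 0L,
                   junction_class = "1a", sample_id = "S1",
                   provenance = "j1"),
    tibble::tibble(sequence = paste0(shared, "CCK"), event_kind = "junction",
                   contig = "c1", loc = "c1:30-40", strand = "+", frame = 0L,
                   junction_class = "1a", sample_id = "S1",
                   provenance = "j2"))
  db <- assemble_database(entries, prot)
  f <- write_psm_tsv(sprintf("%s\t2.5\t0.001\t10\tnep\tS1\tsc1", shared))
  cand <- collapse_to_candidates(suppressMessages(load_psm_table(f)), db)
  expect_identical(lengths(cand$event_locs), 2L)
  one_normal <- normal_catalogs(junctions = tibble::tibble(
    contig = "c1", donor = 10L, acceptor = 20L))
  both_normal <- normal_catalogs(junctions = tibble::tibble(
    contig = "c1", donor = c(10L, 30L), acceptor = c(20L, 40L)))
  expect_identical(nrow(stage_event_catalog(cand, one_normal)$candidates), 1L)
  expect_identical(nrow(stage_event_catalog(cand, both_normal)$candidates), 0L)
})

test_that("cascade ledger conserves counts and stages are idempotent", {
  fx <- make_fixture(fixture_spec(seed = 8))
  res <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs))
  s <- res$ledger$stages
  expect_true(all(s$n_in == s$n_removed + s$n_out))
  expect_identical(s$n_out[-nrow(s)], s$n_in[-1])
  expect_identical(ledger_survivors(res$ledger),
                   s$n_in[1] - sum(s$n_removed))
  # removed lists match the counts
  expect_identical(lengths(s$removed), as.integer(s$n_removed))
  # set-subtraction stages are idempotent on their own output
  r <- stage_normal_peptides(res$candidates, fx$catalogs)
  expect_identical(stage_normal_peptides(r$candidates,
                                         fx$catalogs)$candidates,
                   r$candidates)
  # rerun on identical inputs is deterministic
  res2 <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs))
  expect_identical(res$ledger$stages, res2$ledger$stages)
  expect_identical(res$candidates$peptide, res2$candidates$peptide)
  # all-stages-disabled configuration is the identity on candidates
  res0 <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, config = cascade_config(stages = character())))
  expect_identical(nrow(res0$candidates),
                   length(unique(fx$sim$psms$peptide[
                     fx$sim$psms$q_value <= 0.01])))
})

test_that("survivor set is invariant to the order of subtraction stages", {
  fx <- make_fixture(fixture_spec(seed = 9))
  perm <- c("event_catalog", "proteome_scan", "reference_match",
            "normal_peptides", "quality")
  res_canon <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs))
  res_perm <- suppressMessages(run_cascade(
    fx$sim$psms, fx$db, proteomes = list(fx$reference$paths$proteome),
    catalogs = fx$catalogs, config = cascade_config(stages = perm)))
  expect_setequal(res_canon$candidates$peptide, res_perm$candidates$peptide)
})

test_that("cohort frequency computes fractions with lexicographic ties", {
  cand <- tibble::tibble(
    peptide = c("NSSVSGIFTFQK", "AAAAAAAK", "CCCCCCCK"),
    event_kinds = list("junction", "snv", "junction"),
    samples = list(sprintf("S%02d", 1:12), "S01", "S01"))
  freq <- cohort_frequency(cand, cohort_size = 46)
  expect_equal(freq$fraction[1], 12 / 46, tolerance = 1e-12)
  expect_equal(round(freq$fraction[1], 4), 0.2609)
  expect_identical(freq$peptide[2:3], c("AAAAAAAK", "CCCCCCCK"))
  expect_equal(freq$fraction[2], 1 / 46)
})
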