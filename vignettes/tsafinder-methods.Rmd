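---
title: "Methods: database construction, filtration cascade, and RT validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: database construction, filtration cascade, and RT validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsafinder)
```

`tsafinder` identifies tumor-specific antigen (TSA) candidate peptides by
searching tumor mass-spectrometry data against a personalized protein
database built from the tumor's own genomic events, then subtracting
everything attributable to the normal proteome or to events present in
normal tissue. This vignette documents the models, the tunable parameters,
the numerical choices made where the design was genuinely open, and what
the synthetic fixtures do and do not establish.

## Coordinate and sequence conventions

All internal coordinates are 0-based, half-open. GTF input (1-based,
closed) is converted at parse time; BED input is native. One internal
convention eliminates an entire class of off-by-one errors when junction
coordinates from BED are compared to exon boundaries from GTF. Minus-strand
transcripts store exons and CDS in transcription order so translation
always proceeds 5'→3' of the transcript. Codons containing `N` translate
to `X`, which can never match a peptide downstream — toy and real genomes
contain assembly gaps and this keeps them inert rather than fatal.

## Database construction

**Variant proteins.** Each PASS, CDS-overlapping variant is substituted
into the spliced coding sequence of every transcript containing it (allele
reverse-complemented for minus-strand transcripts) and the edited CDS is
translated from the annotated start. SNVs yield the full variant protein
truncated at the first stop; frameshift indels continue in the shifted
frame to the first downstream stop. Synonymous edits are dropped. The full
protein is emitted rather than a peptide window: windowing into observable
peptides is the search engine's job, not the database builder's. Indels
are handled by the same machinery as SNVs; they are a small extension of
the variant pathway and are labeled `indel` so they can be excluded
downstream if desired. Transcripts without an annotated CDS participate in
junction classification (they have exons) but are skipped for variant
translation, where a reading frame would have to be invented.

**Junction translation.** The splice-aware sequence is the left block
(ending at the donor) joined to the right block (starting at the
acceptor), using the block sizes carried by the BED record (the longest
spliced read). It is translated in frames 0–2 on the junction strand; when
the strand is unknown (`.` in the BED, common for unstranded libraries)
both strands are translated, which is the conservative superset — several
of the six junction classes involve intergenic ends with no inferable
strand. Translations are split at stop codons, and a stop-free segment is
emitted only if it spans the splice boundary (draws at least one
nucleotide from each block) and has at least `min_orf_aa = 7` residues.
The spanning requirement is a correctness condition: a segment confined to
one block is plain reference genome sequence and cannot witness the
junction. The 7-residue floor mirrors the fusion rule below so the two
event classes are treated consistently; both are configurable.

**Junction classification.** Each junction end is labeled against the
annotated exons of its contig — `boundary` (coincides with the matching
exon edge: donor with an exon end, acceptor with an exon start), `overlap`
(strictly inside an exon), or `none` — and the label pair maps to the six
types, with type 1 split into `1a` (matched exons share a gene:
alternative splicing) and `1b` (different genes: fusion-like). The pairing
is exhaustive, so every junction is classifiable. Fusion-like `1b`
junctions are handled once, by the junction pathway; they are not also fed
to the fusion translator. Identity against the annotated-intron set (and
against the normal junction catalog) is exact `(contig, donor, acceptor)`
equality; strand is deliberately ignored because unstranded callers emit
`.`.

**Fusion ORFs.** The fused sequence joins `flank_nt` strand-oriented
nucleotides upstream of the 5' breakpoint to `flank_nt` downstream of the
3' breakpoint and is translated in all six frames. Maximal stop-to-stop
runs of **more than six residues** whose codons draw from both arms are
emitted. The default `flank_nt = 999` (333 codons per arm) comfortably
contains any plausible LysC/tryptic peptide context while keeping the
database desk-sized; the breakpoint-spanning requirement can be switched
off (`require_spanning = FALSE`) for strict emulation of pipelines that
keep all ORFs.

**Assembly.** Novel entries are deduplicated by exact sequence with merged
provenance; I and L are distinct at build time (the database records
genomic truth; the I/L mass ambiguity is a detection-time concern and is
available as a filter-time option instead). Reference proteome records are
appended unmodified. FASTA headers carry entry id, event kind, 0-based
event coordinates, strand, frame, junction class and sample — enough to
reconstruct the generating event, which the event-catalog filtration stage
depends on.

## The filtration cascade

Stages run in a fixed canonical order; each is a pure set subtraction
except the quality stage, so the survivor set is order-invariant while the
per-stage attribution is not. A peptide qualifying for several removals is
attributed to the earliest stage — published cohort bookkeeping of this
kind can therefore show per-stage counts that do not sum naively when
removal sets overlap, which is expected, not an error. The ledger enforces
`n_in = n_removed + n_out` per stage and chaining across stages.

Parameter defaults, with rationale:

| parameter | default | meaning |
|---|---|---|
| `fdr_threshold` | 0.01 | q-value gate applied at PSM load (1 % target FDR) |
| `min_len` | 8 | peptides shorter than 8-mers are culled |
| `min_xcorr` | 1 | retention requires Xcorr **strictly** greater than 1 |
| `il_equivalence` | off | collapse I/L during proteome matching |
| `slop_nt` | 0 | coordinate tolerance for normal event catalogs |

The Xcorr boundary is genuinely ambiguous in common usage ("culled below
1" vs "kept above 1" differ at exactly 1); the strict rule is used and the
threshold is configurable. Reference matching is by exact substring against
the proteome sequences rather than by trusting search-engine accession
columns, whose dialects vary by export tool; substring matching is
dialect-free and strictly stronger. The exact-substring scan (stage 4) is
the deterministic equivalent of keeping only 100 %-identity,
100 %-coverage BLASTP hits, with optional I/L equivalence off by default.
The event-catalog stage is scoped to junction- and fusion-derived peptides;
SNV/indel peptides pass unchanged. A peptide with several generating events
is removed only when **all** of them occur in the normal catalogs — one
tumor-only source suffices for tumor specificity. Coordinate matching is
exact by default; `slop_nt` exists because junction callers differ by a few
bases in breakpoint conventions, and it stays off unless the user opts in.

## Retention-time validation

The proprietary hydrophobicity-index tools used with commercial pipelines
are closed; `tsafinder` ships a first-generation additive
retention-coefficient model: per-residue coefficients summed over the
peptide, N-terminal corrections applied to the first three residues with
weights 0.42/0.22/0.05, and a length correction (short peptides, < 10 aa,
and long ones, > 20 aa, retain less than the raw sum predicts). The
coefficient set is versioned package data
(`inst/extdata/hi_coefficients_v1.tsv`, tuned for C18 / formic-acid
reversed-phase systems) and alternative sets drop in as TSV. What matters
for validation is not the absolute HI scale but that HI is proportional to
elution solvent fraction, hence linear in retention time on a fixed
gradient: the validation logic — ordinary least squares of observed mean
RT on predicted HI, R² and the F-test p-value, studentized-residual
flagging at a configurable threshold (default 3) — is the tested
contribution. Validation flags and never filters: RT agreement is
supporting evidence, and a deep-learning RT predictor can be plugged in by
supplying externally predicted values. Degenerate designs (fewer than 3
observations, all-identical HI) are errors; a zero-variance response is
reported as R² = 0 by definition rather than the 0/0 artifact `summary.lm`
can produce.

## What the synthetic fixtures emulate

`fixture_spec()` defaults generate two 9-kb contigs with three 3-exon
protein-coding genes each (alternating strand, valid start/stop, in-frame,
stop-free CDS), one junction per aberrant-junction class constructed
directly from the exon layout, junctions planted below the 5-read support
threshold, two fusions (one reported by two callers to exercise
deduplication), two SNVs and one frameshift deletion chosen by brute force
to change the protein, plus distractor variants (non-PASS; intronic).
About a third of the passing junctions and fusions are copied into the
normal event catalogs. PSM simulation draws peptides by in-silico LysC
digestion (one missed cleavage) from each ground-truth class, with Xcorr
from a truncated normal above the retention threshold, q-values below the
FDR gate, and `RT = 5 + 0.45·HI + N(0, 1)` minutes. Every draw is fixed by
the seed and outputs are byte-deterministic.

The fixtures establish *bookkeeping and logic* correctness: that planted
tumor peptides survive with recall 1.0 and planted reference /
normal-tissue / normal-event peptides all fall, that classification and
ORF extraction agree with brute-force oracles, and that parameter recovery
works. They deliberately do **not** model score overlap between true and
false matches, shared peptides between unrelated proteins, modified
peptides, chimeric spectra, or realistic junction/fusion false-positive
rates — so passing tests say nothing about search-engine FDR behavior on
real spectra, only about what this package does with the PSMs it is given.

Problem sizes in the shipped tests and acceptance script (≥ 1,000
randomized junctions across 20 seeds for classification, 20 end-to-end
fixtures, 10,000 randomized substring pairs, 100–200-protein digestion and
RT simulations) were chosen as the smallest sets that exercise every
branch while keeping runs comfortably reproducible on a laptop.

## Known limitations

* Junction translation relies on the BED block sizes; blocks shorter than
  a read (or clipped flanks at contig ends) bound the ORFs that can be
  recovered.
* Variant translation requires an annotated CDS; variants in non-coding
  transcripts are skipped rather than translated in invented frames.
* The additive HI model ignores positional effects beyond the N-terminal
  window and peptide modifications; it is a validation correlate, not a
  chromatography simulator.
* Per-stage ledger attribution depends on the canonical stage order;
  comparisons with other pipelines should compare survivor sets, not
  per-stage counts.
* No decoy generation, FDR estimation, spectral scoring, or HLA-binding
  prediction: q-values and Xcorr are consumed as given, and
  immunogenicity is out of scope.
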