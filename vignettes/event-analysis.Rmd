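---
title: "Transcript events: catalog construction, coverage and reference filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript events: catalog construction, coverage and reference filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txevents)
```

## The problem and the model

Short-read isoform quantification is unstable when the reference
transcriptome contains many transcripts that are not expressed in the
sample: reads from shared exons get redistributed over non-expressed
isoforms, and replicate-to-replicate concordance suffers. `txevents`
addresses this by decomposing the annotated transcriptome into discrete,
quantifiable *events*, measuring each event directly, and filtering the
reference to the probably-expressed transcript set before any isoform
quantifier runs.

The events are:

* **Exonic regions** — maximal genomic intervals covered by overlapping
  exons of a gene (merged with `GenomicRanges::reduce`).
* **Exon fragments** — the partition of a multi-exon region at every
  distinct exon start/end inside it. Each fragment has a constant set of
  covering exons, and inherits the union of their transcripts. A region
  formed by a single distinct exon has no fragments and is carried as one
  *single-exon* event.
* **Distinct introns** — the gaps between consecutive exonic regions of a
  gene.
* **Junctions** — every annotated splice junction, plus every *logical*
  junction obtainable by pairing a donor (exon 3' end) with any acceptor
  (exon 5' start) strictly downstream of it in transcription orientation
  within the same gene. Junctions with identical coordinates collapse to
  one event. This exhaustive catalog lets reads from unannotated exon
  combinations map to an existing sequence instead of being lost.
* **Border junctions** — for each annotated intron, sequences spanning the
  exon–intron boundary on both sides, probing intron retention, novel
  donor/acceptor sites, and unprocessed transcript.

Junctions are classified by three non-exclusive flags: *exon skipping*
(at least one annotated exon lies wholly inside the open interval between
donor end and acceptor start; partially contained exons do not count —
the only reading consistent with the worked-example tables), *alternative
donor* (the donor's exonic region contains more than one distinct exon
3' end; all sites in such a region are flagged, with no
reference/alternative asymmetry) and *alternative acceptor* (mirror).
Every event also carries a transcript-frequency class: **unique** (one
transcript), **common** (several but not all), **constitutive** (all),
**unannotated** (none), with **multigene** overriding all of them.
Multi-gene status comes from exonic regions touching exons of more than
one gene and, for junctions, from identical flanking sequence occurring in
more than one gene — precisely the condition that makes reads
unassignable. Multi-gene events are excluded from transcript inference.
Exons of mono-transcript genes are both unique and constitutive; they are
reported as unique with a separate `mono_transcript` tag.

## Coverage: the APN unit

All detection rules operate on **APN** (average reads per nucleotide):
the number of *distinct* reads assigned to an event divided by the event
length. Duplicate reads (exact sequence identity) are collapsed first;
no trimming or other processing is applied.

Reads are counted in two stages. First they are matched against the
junction catalog: a read counts toward a junction only if it maps
uniquely (multi-mapping records are discarded) and spans the junction
midpoint with at least `min_overhang` nucleotides on each side. The
junction APN length is the full junction sequence length (both flanks).
Everything else falls through to the genome stage, where a read counts
toward every exon fragment, single-exon event or intron it overlaps by at
least one nucleotide (configurable); no fractional assignment is
attempted, because APN is defined per region independently. Paired-end
data are treated as single-end reads throughout.

Aligner execution is out of scope: the package consumes SAM/BAM (or
in-memory alignment tables) produced against its exported junction FASTA
and the genome, and enforces the mapping conventions as validation and
counting rules instead.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `read_len` | 56 nt | expected read length; sizes the junction flanks |
| `min_overhang` | 8 nt | minimum read extension past the junction midpoint, per side |
| `flank_len` | `read_len - min_overhang` = 48 nt | exon sequence kept per junction side |
| `min_fragment_len` | 10 nt | fragments below this stay in the catalog but are excluded from detection statistics |
| `novel_ratio` | 0.90 | border APN / exon APN calling a possible novel donor/acceptor |
| `ir_ratio` | 0.10 | border APN / exon APN (with intron detected) calling possible intron retention |

The flank default guarantees that any read short enough to fit the
junction sequence necessarily overhangs both sides by at least
`min_overhang`; the original flank length used with real data is not
derivable from first principles, so it is exposed as configuration.
Detection rules make the comparison operator explicit (`APN > 0`
detection versus `APN >= 5` filtering are both in routine use) and
require either a minimum sample count ("at least three of six samples")
or a sample fraction ("at least 50% of subjects").

## Transcript summaries and filtering

A transcript's events are its annotated junctions plus the exon fragments
and single-exon events it contains (whole exonic regions are not
double-counted; multi-gene events and sub-minimum fragments are excluded
from both numerator and denominator). Per transcript the package reports
the number and proportion of events detected, the same for unique events
(`NA` when the transcript has none — such transcripts are intrinsically
non-resolvable from short reads), and combined coverage. Combined
coverage is length-weighted — total reads over total event length, not
the mean of per-event APNs — because events vary greatly in length;
`total_reads` is the per-sample mean so that `mean_apn` remains exactly
recomputable from the reported fields.

Filtering retains transcripts with at least `min_prop_events` of their
events detected at the rule's APN threshold; a summary computed under a
different APN threshold than the filter rule is refused rather than
silently reinterpreted. The three standard configurations — (APN > 0,
100%), (APN > 0, >= 75%), (APN >= 5, >= 75%) — are all expressible
verbatim. The retained set is written as a spliced-sequence FASTA plus a
two-column gene-to-transcript index, the inputs downstream quantifier
reference builders expect.

Border junctions are classified only when detected and when their
adjacent exon (the fragment or single-exon event touching the exon-intron
boundary) is detected: border APN at least `novel_ratio` of the exon APN
calls a possible novel donor/acceptor; at least `ir_ratio` with the
intron detected calls possible intron retention; both together are
ambiguous intron retention; the remainder are possible unprocessed
transcript. Mean APNs are taken over the samples in which the event meets
the detection rule (configurable to the all-samples mean). Whether border
analysis should be restricted to APN >= 5 events globally is left to the
caller's detection rule rather than hard-coded.

## Evaluation statistics

For replicate-concordance evaluation of quantifier output the package
provides: detection disagreement (percent of reference transcripts
detected in exactly one of two replicates), TPM binning on the minimum
across replicates of log2(TPM) with boundaries 0, 0.5, 2 and 4 (base 2 is
the only base under which an RPKM of 5 corresponds to a log-TPM of about
2; the base is configurable), the coefficient of variation on the percent
scale (values near 100 are only plausible as percents), an exact
two-sided paired sign test on per-transcript CVs with ties dropped (the
standard convention; tie handling is not otherwise prescribed), a
Bland-Altman table with bias and 1.96-sd limits of agreement, and the
conversion of a splice-aware aligner's junction read count to the APN
scale by dividing by twice the maximum allowable junction overhang. Bin
CVs are computed on TPM by default with log-TPM available as a switch.

## The synthetic-data generator

Because every pipeline stage must be testable without downloads, the
package ships a first-class generator:

* `toy_gene_model()` emits the canonical worked-example gene: 12 exons
  A–L on a fixed 2,000 nt chromosome, three isoforms, exercising shared
  acceptors (F, G), shared ends with alternative acceptors (J, K, L),
  three alternative donors (A, B, C) and four isolated exons. Its
  junction catalog (54 distinct coordinate junctions, 11 annotated) and
  every published classification cell are frozen in the test suite.
* `random_gene_model()` builds reproducible multi-gene annotations with
  alternative-boundary exon variants at a configurable overlap
  probability; the same seed yields byte-identical GFF3.
* `simulate_reads()` is a deliberately minimal simulator: uniform
  fragment starts along each spliced transcript, expected read count
  `level * coverage * length / read_len`, independent substitution errors
  (default 0.005/base), no positional or fragment-size bias model. For
  every read it records the origin transcript and position, the junctions
  spanned (with overhangs) and the genomic footprint, and can emit FASTQ
  plus truth SAM against both the junction catalog and the genome. Truth
  alignment mirrors the catalog geometry: a read is junction-mappable
  exactly when it covers two exons with both overhangs at least
  `min_overhang`; reads crossing three or more exons (microexon-style
  alignments) fall to the genome stage, as they would with a real
  aligner.

Defaults mirror a 56 nt, 100x-coverage study design at desk scale. What
passing tests show is therefore structural correctness — partition
exactness, catalog completeness, counting-rule fidelity, filter
monotonicity, end-to-end agreement with simulator truth — not read-level
realism: real libraries have positional bias, indels, quality-dependent
errors and fragment-size structure that the generator deliberately omits.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 conversion
  happens at the parse boundary, BED output is native, and junction IDs
  print 1-based genomic positions
  (`chromosome:donor:acceptor:strand`).
* Junction enumeration is strand-aware ("5' to 3'" is transcription
  order); IDs always report plus-strand genomic positions, so the same
  physical junction has one name regardless of strand.
* Exons shorter than the flank contribute their whole length and the
  realized flank lengths are recorded on the event; border flanks are
  additionally clipped to the region and intron lengths.
* Degenerate inputs are defined, not special-cased: single-exon genes
  yield empty junction and intron sets; a region formed by one distinct
  exon refuses fragmentation and directs the caller to the single-exon
  path; an empty retained set writes valid empty reference files with a
  warning.
* Ties and boundaries: detection operators are explicit per rule; bin
  edges are half-open upward (a value exactly at a boundary joins the
  upper bin); the sign test drops ties.

Problem sizes in the shipped tests were chosen for a desk workstation:
the property suites run 100 single-gene random models for the
fragment-partition oracle and the junction-catalog checks, and the
simulation analog uses 20 multi-isoform genes with six replicate samples
at 100x coverage.

## Known limitations

* Completely novel donor or acceptor sites (coordinates absent from the
  annotation) are invisible by construction; border junctions probe only
  annotated intron boundaries.
* Reads spanning more than one junction (microexons shorter than the read
  length) never map to the junction catalog and are only partially
  captured at the genome stage.
* With APN defined as distinct reads per nucleotide, junction APN has a
  hard ceiling after duplicate removal: at most
  `(read_len - 2 * min_overhang + 1) / (2 * flank_len)` (about 0.43 at the
  defaults), because distinct spanning sequences are capped by the number
  of possible start positions. Fragment APN at 100x depth sits around
  2–3. Consequently an `APN >= 5` event-detection threshold is
  unreachable at desk-scale uniform coverage — the strict
  (APN >= 5, >= 75%) reference reduction retains nothing in the shipped
  simulation analog, while the (APN > 0, 100%) configuration recovers
  the full truth set. Very deep or highly diverse real libraries (errors,
  varying read lengths, paired mates) soften the ceiling but the
  structural limit on distinct spanning reads remains.
* GTF input, annotation liftover, trans-spliced and multi-chromosome
  transcripts are out of scope (GFF3 only); orphan transcripts without
  gene parentage are an error rather than a guess.
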