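# txevents

Event-level decomposition of an annotated transcriptome for RNA-seq:
build a catalog of quantifiable transcriptional events — exonic regions,
exon fragments, single-exon events, distinct introns, every annotated
splice junction, **all logical donor/acceptor combinations** within each
gene, and exon–intron border junctions — quantify each event from read
alignments, and filter the reference transcriptome to the
probably-expressed transcript set before isoform quantification.

It is aimed at RNA-seq analysts who want stable isoform estimates (or
direct event-level tests of splicing) without de-novo assembly,
probabilistic transcript models, or ancillary data: only short reads and
a GFF3 annotation are required.

## The method

Exons of a gene are projected onto the genome. Overlapping exons merge
into **exonic regions**; the distinct exon start/end positions inside a
region partition it into **exon fragments**, each annotated with its
covering exons and transcripts. Every ordered exon pair (donor 3' end
strictly upstream of acceptor 5' start, transcription orientation) yields
a junction `chromosome:donor:acceptor:strand`; coordinate-identical pairs
collapse. Junctions are flagged for exon skipping, alternative donor and
alternative acceptor use, and every event gets a transcript-frequency
class (unique / common / constitutive / unannotated, with multi-gene
events excluded from transcript inference).

Coverage of an event is reported as **APN** — average reads per
nucleotide:

    APN = distinct reads assigned to the event / event length

Reads map first to the junction catalog (counted only if uniquely mapped
and spanning the midpoint with >= 8 nt overhang per side), the remainder
to the genome (counted toward every overlapped event). An event is
*detected* under a rule such as "APN > 0 in at least 3 of 6 samples".
Each transcript is then summarized by the proportion of its events
detected, the proportion of its unique events detected, and
length-weighted combined coverage, and the reference is filtered, e.g.
keep transcripts with >= 75% of events detected at APN >= 5. The retained
set is written as a spliced-transcript FASTA plus a gene-to-transcript
index for downstream quantifiers. Replicate-concordance statistics
(detection disagreement, TPM-binned CV, Bland–Altman, exact paired sign
test) evaluate the effect of the reduction on quantifier output.

## Worked example

The package ships the canonical worked-example gene: 12 exons A–L, three
isoforms, on a fixed 2,000 nt chromosome.

```r
library(txevents)

toy <- toy_gene_model()
catalog <- build_event_catalog(toy$annotation)
catalog
#> event_catalog: 86 events
#>   border: 12
#>   fragment: 10
#>   intron: 6
#>   junction: 54
#>   single_exon: 4
#>   junctions annotated/logical: 11/43
```

The 12 exons admit 54 distinct coordinate junctions, 11 of them annotated
to an isoform (two annotated exon pairs share coordinates and collapse
into one common junction). Classification of an exon-skipping junction:

```r
subset(catalog$junctions, event_id == "chrT:600:1101:+",
       c(status, freq_class, exon_skipping, alt_donor, alt_acceptor))
#>      status freq_class exon_skipping alt_donor alt_acceptor
#>   annotated     unique          TRUE     FALSE        FALSE
```

Simulate six replicate samples, count both stages, and filter:

```r
per <- list()
for (s in 1:3) {
  sim <- simulate_reads(toy$annotation, coverage = 100, seed = 100 + s,
                        sample_id = paste0("s", s))
  per[[paste0("s", s)]] <- count_simulated_sample(sim, catalog)
}
cov  <- coverage_matrix(per, catalog)
rule <- detection_rule(0, ">", min_samples = 2)
summ <- summarize_transcripts(catalog, cov, rule)
summ[, c("transcript_id", "n_events", "prop_detected", "n_unique", "mean_apn")]
#>   transcript_id n_events prop_detected n_unique  mean_apn
#> 1          iso1       16             1        7 0.7693939
#> 2          iso2       13             1        3 0.7508091
#> 3          iso3       12             1        4 0.8001580

filter_transcripts(summ, filter_rule(min_prop_events = 1, min_apn = 0, op = ">"))$retained
#> [1] "iso1" "iso2" "iso3"
```

`prop_detected = 1` means every event of each isoform was seen
(`APN > 0` in at least two of three samples); at 100x all three truth
isoforms survive the strictest proportion filter. Dropping a transcript's
reads removes it: its unique events receive no coverage and its
`prop_detected` falls below any threshold.

`export_catalog()` writes the junction FASTA and BED/TSV annotation files
for use with an external aligner, and `inst/cli/txevents.R` exposes the
pipeline (`build-annotations`, `count`, `detect`, `classify-borders`,
`filter`, `reduce-reference`) as a thin command-line wrapper.

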