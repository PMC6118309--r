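Package: txevents
Title: Transcript Event Catalogs, Coverage and Reference Filtering for RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes an annotated transcriptome into quantifiable transcriptional
    events: exonic regions, exon fragments, single-exon events, distinct introns,
    every annotated splice junction, all logical donor/acceptor combinations within
    a gene, and exon-intron border junctions. Events are annotated by transcript
    specificity (unique, common, constitutive) and splicing type (exon skipping,
    alternative donor, alternative acceptor). Read alignments to the junction
    catalog and to the genome are converted into per-event coverage (average reads
    per nucleotide, APN), detection flags are applied across samples, border
    junctions are classified (novel donor/acceptor, intron retention, unprocessed
    transcript), and transcripts are filtered by the proportion of their events
    detected to emit a reduced reference transcriptome for downstream isoform
    quantifiers. Includes replicate-concordance evaluation statistics
    (detection disagreement, TPM-binned coefficient of variation, Bland-Altman,
    paired sign test) and a synthetic genome/annotation/read simulator with
    per-read truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
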