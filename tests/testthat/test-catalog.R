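test_that("toy gene yields the expected exonic regions", {
  cl <- toy_catalog()
  regions <- cl$regions
  expect_equal(nrow(regions), 7L)
  expect_equal(regions$start, c(100L, 300L, 500L, 700L, 900L, 1100L, 1300L))
  expect_equal(regions$end, c(220L, 400L, 600L, 820L, 1000L, 1200L, 1400L))
  expect_equal(regions$n_exons, c(3L, 1L, 1L, 2L, 1L, 1L, 3L))
  expect_equal(regions$is_single_exon, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_false(any(regions$is_multigene))
})

test_that("fragment partition matches the per-base membership oracle", {
  cl <- toy_catalog()
  ann <- toy_fixture()$annotation
  for (i in which(!cl$regions$is_single_exon)) {
    region <- cl$regions[i, ]
    got <- fragment_region(region, ann)
    want <- oracle_fragments(region, ann)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    got_members <- vapply(got$exon_keys, function(k) paste(sort(k), collapse = "|"),
                          character(1))
    expect_equal(got_members, want$members)
  }
  # region {A,B,C} = [100,220) cuts into the five documented pieces
  abc <- fragment_region(cl$regions[1, ], ann)
  expect_equal(abc$start, c(100L, 120L, 140L, 200L, 210L))
  expect_equal(abc$end, c(120L, 140L, 200L, 210L, 220L))
  expect_equal(lengths(abc$exon_keys), c(1L, 2L, 3L, 2L, 1L))
  # region {F,G} = [700,820): shared piece then G-only piece
  fg <- fragment_region(cl$regions[4, ], ann)
  expect_equal(fg$start, c(700L, 800L))
  expect_equal(fg$end, c(800L, 820L))
})

test_that("single-exon regions refuse fragmentation and become single-exon events", {
  cl <- toy_catalog()
  expect_error(fragment_region(cl$regions[2, ], toy_fixture()$annotation), "single-exon")
  expect_equal(nrow(cl$single_exons), 4L)
  expect_setequal(cl$single_exons$start, c(300L, 500L, 900L, 1100L))
})

test_that("two identical exons from different genes give one shared fragment", {
  ann <- mini_annotation(data.frame(
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    start1 = c(101, 101), end1 = c(200, 200), stringsAsFactors = FALSE))
  regions <- build_exonic_regions(ann)
  expect_equal(nrow(regions), 1L)
  expect_true(regions$is_multigene)
  fr <- fragment_region(regions[1, ], ann)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 100L)
  expect_equal(fr$end, 200L)
})

test_that("junction enumeration is exhaustive, deduplicated and annotated", {
  cl <- toy_catalog()
  jt <- cl$junctions[cl$junctions$border_side == "none", ]
  expect_equal(nrow(jt), 54L)
  expect_equal(sum(jt$status == "annotated"), 11L)
  # dedup soundness: coordinates unique
  expect_false(any(duplicated(jt[, c("chrom", "left_end", "right_start", "strand")])))
  # matches the brute-force distinct-coordinate oracle
  expect_equal(nrow(jt), length(oracle_junction_coords(toy_fixture()$annotation, "toygene")))
  # E:F and E:G collapse into one common junction
  efg <- jt[jt$left_end == 600 & jt$right_start == 700, ]
  expect_equal(nrow(efg), 1L)
  expect_setequal(efg$transcript_ids[[1]], c("iso1", "iso2"))
  expect_equal(efg$freq_class, "common")
})

test_that("degenerate genes produce the expected junction sets", {
  single <- mini_annotation(data.frame(transcript_id = "t1", gene_id = "g1",
                                       start1 = 1, end1 = 100))
  expect_equal(nrow(enumerate_junctions(single, "g1")), 0L)

  two <- mini_annotation(data.frame(transcript_id = "t1", gene_id = "g1",
                                    start1 = c(1, 201), end1 = c(100, 300)))
  j <- enumerate_junctions(two, "g1")
  expect_equal(nrow(j), 1L)
  expect_equal(j$status, "annotated")
  cl2 <- build_event_catalog(two)
  j2 <- cl2$junctions[cl2$junctions$border_side == "none", ]
  expect_equal(j2$freq_class, "unique")  # mono-transcript: unique and constitutive
  expect_true(j2$mono_transcript)
})

test_that("junction classification matches the worked-example tables cell for cell", {
  cl <- toy_catalog()
  jt <- cl$junctions
  cell <- function(id) jt[jt$event_id == id,
                          c("exon_skipping", "alt_donor", "alt_acceptor", "freq_class")]
  # annotated junctions (splice table rows, by genomic coordinates)
  expect_equal(unname(unlist(cell("chrT:600:1101:+")[1:3])), c(TRUE, FALSE, FALSE))  # E:I
  expect_equal(unname(unlist(cell("chrT:1000:1301:+")[1:3])), c(TRUE, FALSE, TRUE))  # H:J
  expect_equal(unname(unlist(cell("chrT:1200:1321:+")[1:3])), c(FALSE, FALSE, TRUE)) # I:K
  # logical junctions
  expect_equal(unname(unlist(cell("chrT:400:1301:+")[1:3])), c(TRUE, FALSE, TRUE))   # D:J
  expect_equal(unname(unlist(cell("chrT:200:701:+")[1:3])), c(TRUE, TRUE, FALSE))    # A:F|A:G
  # endpoints not on exon boundaries are rejected
  fake <- data.frame(event_id = "chrT:205:301:+", gene_id = "toygene", chrom = "chrT",
                     strand = "+", left_end = 205L, right_start = 300L,
                     status = "unannotated_logical", transcript_ids = I(list(character(0))),
                     stringsAsFactors = FALSE)
  expect_error(classify_junctions(fake, toy_fixture()$annotation, cl$regions), "boundaries")
})

test_that("border junctions probe every exon-intron boundary and only those", {
  cl <- toy_catalog()
  b <- cl$junctions[cl$junctions$border_side != "none", ]
  expect_equal(nrow(b), 12L)  # 6 introns x 2 sides
  expect_equal(sum(b$border_side == "donor"), 6L)
  # all border extents stay within annotated gene territory (no terminal borders)
  expect_true(all(b$gstart >= 100 & b$gend <= 1400))
  # the donor border of region {A,B,C} is at the region outer edge and is an
  # alternative donor site; the isolated-exon borders are not
  abc_donor <- b[b$border_side == "donor" & b$region_id == "er:chrT:101:220:+", ]
  expect_true(abc_donor$alt_donor)
  e_donor <- b[b$border_side == "donor" & b$region_id == "er:chrT:501:600:+", ]
  expect_false(e_donor$alt_donor)
  # flanks: exon side and intron side both bounded by the configured flank
  expect_true(all(b$exon_flank <= cl$config$flank_len))
  expect_true(all(b$intron_flank <= cl$config$flank_len))
  expect_equal(b$length, b$exon_flank + b$intron_flank)
})

test_that("frequency classes follow transcript membership", {
  expect_equal(assign_frequency_class(0, 3), "unannotated")
  expect_equal(assign_frequency_class(1, 3), "unique")
  expect_equal(assign_frequency_class(2, 3), "common")
  expect_equal(assign_frequency_class(3, 3), "constitutive")
  expect_equal(assign_frequency_class(1, 1), "unique")  # mono-transcript gene
  expect_equal(assign_frequency_class(3, 3, multigene = TRUE), "multigene")
  cl <- toy_catalog()
  de <- cl$junctions[cl$junctions$event_id == "chrT:400:501:+", ]
  expect_equal(de$freq_class, "constitutive")
})

test_that("junction sequences concatenate flanks in transcription orientation", {
  seq <- paste(rep("ACGT", 50), collapse = "")
  ex <- data.frame(transcript_id = "t1", gene_id = "g1",
                   start1 = c(11, 101), end1 = c(40, 130), stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    ann <- mini_annotation(ex, strand = strand, chrom_seq = seq)
    cl <- build_event_catalog(ann, catalog_config(read_len = 10, min_overhang = 5))
    j <- cl$junctions[cl$junctions$border_side == "none", ]
    expect_equal(j$donor_flank, 5L)
    expect_equal(j$acceptor_flank, 5L)
    plus_seq <- paste0(substr(seq, 36, 40), substr(seq, 101, 105))
    want <- if (strand == "+") plus_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
    expect_equal(j$seq, want)
  }
})

test_that("exons shorter than the flank contribute their whole length", {
  ex <- data.frame(transcript_id = "t1", gene_id = "g1",
                   start1 = c(11, 101), end1 = c(13, 130), stringsAsFactors = FALSE)
  ann <- mini_annotation(ex)
  cl <- build_event_catalog(ann, catalog_config(read_len = 10, min_overhang = 5))
  j <- cl$junctions[cl$junctions$border_side == "none", ]
  expect_equal(j$donor_flank, 3L)  # donor exon is 3 nt < flank 5
  expect_equal(j$acceptor_flank, 5L)
  expect_equal(nchar(j$seq), 8L)
  expect_equal(j$length, 8L)
})

test_that("identical junction flanks in two genes are flagged multi-gene", {
  # two genes with the same local sequence context: repeat the chromosome text
  block <- paste(c(rep("A", 60), rep("C", 60), rep("G", 380)), collapse = "")
  seq <- paste0(block, block)
  ex <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2"),
    gene_id = c("g1", "g1", "g2", "g2"),
    start1 = c(1, 101, 501, 601), end1 = c(60, 160, 560, 660),
    stringsAsFactors = FALSE)
  ann <- mini_annotation(ex, chrom_seq = seq)
  cl <- build_event_catalog(ann, catalog_config(read_len = 20, min_overhang = 8))
  jt <- cl$junctions[cl$junctions$border_side == "none", ]
  expect_true(all(jt$freq_class == "multigene"))
  # multi-gene events are excluded from the transcript-event map
  expect_false(any(jt$event_id %in% cl$tx_events$event_id))
})

test_that("catalog export round-trips through standard formats", {
  cl <- toy_catalog()
  dir <- tempfile("exp")
  paths <- export_catalog(cl, dir)
  fa <- Biostrings::readDNAStringSet(paths$junction_fasta)
  expect_equal(length(fa), 54L + 12L)
  expect_setequal(names(fa), cl$junctions$event_id)
  # headers parse back to coordinates
  parsed <- parse_junction_id("chrT:200:301:+")
  expect_equal(parsed$pos1, 200L)
  expect_equal(parsed$pos2, 301L)
  expect_equal(parsed$strand, "+")
  expect_equal(parsed$border_side, "none")
  # annotation table has the documented fixed column order
  tab <- utils::read.table(paths$events_tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(names(tab),
               c("event_id", "gene_id", "event_type", "status", "exon_skipping",
                 "alt_donor", "alt_acceptor", "freq_class", "transcript_ids", "length"))
  beds <- read_bed(paths$fragments_bed)
  expect_equal(nrow(beds), nrow(cl$fragments))
})

test_that("junction counts respect the pre-dedup upper bound on random models", {
  for (seed in 1:10) {
    mod <- random_gene_model(n_genes = 1, seed = 2000 + seed)
    ann <- mod$annotation
    for (g in ann$genes$gene_id) {
      j <- enumerate_junctions(ann, g)
      n <- sum(ann$exons$gene_id == g)
      expect_lte(nrow(j), n * (n - 1) / 2)
      expect_equal(nrow(j), length(oracle_junction_coords(ann, g)))
      expect_false(any(duplicated(j$event_id)))
    }
  }
})

test_that("every consecutive transcript exon pair is an annotated junction", {
  mods <- c(lapply(1:8, function(s) random_gene_model(n_genes = 2, seed = 3000 + s)),
            list(toy_fixture()))
  for (mod in mods) {
    ann <- mod$annotation
    cl <- build_event_catalog(ann)
    jt <- cl$junctions[cl$junctions$border_side == "none", ]
    for (tx in ann$transcripts$transcript_id) {
      te <- transcript_exons(ann, tx)
      te <- te[order(te$start), ]
      if (nrow(te) < 2) next
      for (k in seq_len(nrow(te) - 1)) {
        hit <- jt[jt$left_end == te$end[k] & jt$right_start == te$start[k + 1] &
                    jt$chrom == te$chrom[1], ]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$status, "annotated")
        expect_true(tx %in% hit$transcript_ids[[1]])
      }
    }
  }
})
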