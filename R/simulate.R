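# deterministic random DNA
.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.write_gff3 <- function(genes, transcripts, exons, path) {
  # genes/transcripts/exons use internal 0-based half-open; GFF3 is 1-based inclusive
  lines <- c("##gff-version 3")
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    lines <- c(lines, paste(g$chrom, "txevents", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", sprintf("ID=%s", g$gene_id), sep = "\t"))
    gtx <- transcripts[transcripts$gene_id == g$gene_id, ]
    for (ti in seq_len(nrow(gtx))) {
      tx <- gtx[ti, ]
      tex <- exons[exons$transcript_id == tx$transcript_id, ]
      tex <- tex[order(tex$start), ]
      lines <- c(lines, paste(g$chrom, "txevents", "mRNA", min(tex$start) + 1L,
                              max(tex$end), ".", g$strand, ".",
                              sprintf("ID=%s;Parent=%s", tx$transcript_id, g$gene_id),
                              sep = "\t"))
      lines <- c(lines, paste(g$chrom, "txevents", "exon", tex$start + 1L, tex$end,
                              ".", g$strand, ".",
                              sprintf("ID=%s;Parent=%s",
                                      sprintf("%s.e%d", tx$transcript_id, seq_len(nrow(tex))),
                                      tx$transcript_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  path
}

#' The worked-example gene fixture
#'
#' A single plus-strand gene of 12 exons (A-L) on a 2,000 nt synthetic
#' chromosome, with three isoforms (1: A,D,E,G,H,J; 2: B,D,E,F,I,L;
#' 3: C,D,E,I,K). Exons A,B,C overlap with three distinct donor ends; F and
#' G share an acceptor start; J,K,L share an end with three distinct
#' acceptor starts; D,E,H,I are isolated single-exon regions. The
#' chromosome sequence is random but fixed, so the fixture is byte-stable.
#'
#' @param dir directory to write `toy.gff3` and `toy.fa` (created if
#'   absent; default a fresh temporary directory)
#' @return list with `annotation` (parsed `genome_annotation` with genome
#'   loaded), `gff3`, `fasta`
#' @export
toy_gene_model <- function(dir = tempfile("toygene")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # 1-based inclusive coordinates of the 12 exons
  coords <- data.frame(
    exon = LETTERS[1:12],
    start1 = c(101, 121, 141, 301, 501, 701, 701, 901, 1101, 1301, 1321, 1341),
    end1 = c(200, 210, 220, 400, 600, 800, 820, 1000, 1200, 1400, 1400, 1400),
    stringsAsFactors = FALSE
  )
  isoforms <- list(iso1 = c("A", "D", "E", "G", "H", "J"),
                   iso2 = c("B", "D", "E", "F", "I", "L"),
                   iso3 = c("C", "D", "E", "I", "K"))
  exons <- do.call(rbind, lapply(names(isoforms), function(tx) {
    m <- coords[match(isoforms[[tx]], coords$exon), ]
    data.frame(transcript_id = tx, start = m$start1 - 1L, end = m$end1,
               stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = "toygene", chrom = "chrT", strand = "+",
                      start = 100L, end = 1400L, stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = names(isoforms), gene_id = "toygene",
                            stringsAsFactors = FALSE)
  gff3 <- .write_gff3(genes, transcripts, exons, file.path(dir, "toy.gff3"))

  fasta <- file.path(dir, "toy.fa")
  seq <- .with_seed(20180718L, .random_dna(2000L))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seq, "chrT")), fasta)

  list(annotation = parse_gff3(gff3, genome = fasta), gff3 = gff3, fasta = fasta)
}

#' Generate random gene models
#'
#' Reproducible synthetic annotations exercising alternative donors and
#' acceptors, exon skipping and shared exons: each gene gets a set of
#' non-overlapping "core" exons, each core exon may gain an overlapping
#' boundary variant (alternative donor/acceptor) with probability
#' `overlap_prob`, and isoforms are random ordered subsets of the exon
#' pool. The same seed produces byte-identical GFF3 output.
#'
#' @param n_genes number of genes
#' @param exons_per_gene integer range (min, max) of core exons per gene
#' @param isoforms_per_gene integer range of isoforms per gene
#' @param overlap_prob probability a core exon gains a boundary variant
#' @param seed RNG seed (required, for reproducibility)
#' @param dir output directory for `genome.gff3` / `genome.fa`
#' @param exon_len range of exon lengths in nt
#' @param intron_len range of intron lengths in nt
#' @return as [toy_gene_model()]: list with `annotation`, `gff3`, `fasta`
#' @export
random_gene_model <- function(n_genes = 5, exons_per_gene = c(4, 8),
                              isoforms_per_gene = c(2, 4), overlap_prob = 0.3,
                              seed = 1, dir = tempfile("randgene"),
                              exon_len = c(100, 250), intron_len = c(120, 400)) {
  if (exons_per_gene[1] < 2 || isoforms_per_gene[1] < 1 || n_genes < 1) {
    stop("infeasible generator parameters", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .with_seed(seed, {
    gene_list <- list(); tx_list <- list(); ex_list <- list()
    pos <- 200L
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      strand <- sample(c("+", "-"), 1)
      n_core <- sample(exons_per_gene[1]:exons_per_gene[2], 1)
      starts <- ends <- integer(0)
      exon_of <- list()  # per core slot: matrix of (start,end) variants
      p <- pos
      for (k in seq_len(n_core)) {
        len <- sample(exon_len[1]:exon_len[2], 1)
        s <- p; e <- p + len
        variants <- cbind(s, e)
        if (stats::runif(1) < overlap_prob) {
          # boundary variant: shift one edge inward/outward by 15-60 nt
          shift <- sample(15:60, 1)
          if (stats::runif(1) < 0.5) variants <- rbind(variants, c(s + shift, e))
          else variants <- rbind(variants, c(s, e + shift))
        }
        exon_of[[k]] <- variants
        p <- max(variants[, 2]) + sample(intron_len[1]:intron_len[2], 1)
      }
      gene_end <- max(vapply(exon_of, function(v) max(v[, 2]), numeric(1)))
      n_iso <- sample(isoforms_per_gene[1]:isoforms_per_gene[2], 1)
      for (t in seq_len(n_iso)) {
        tid <- sprintf("%s.t%d", gid, t)
        # ordered subset of core slots; keep at least 2 (or all if 2 cores)
        keep <- sort(sample(seq_len(n_core), max(2L, stats::rbinom(1, n_core, 0.8))))
        rows <- lapply(keep, function(k) {
          v <- exon_of[[k]]
          v[sample(nrow(v), 1), , drop = FALSE]
        })
        m <- do.call(rbind, rows)
        ex_list[[length(ex_list) + 1L]] <- data.frame(
          transcript_id = tid, start = as.integer(m[, 1]), end = as.integer(m[, 2]),
          stringsAsFactors = FALSE)
        tx_list[[length(tx_list) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
      }
      gene_list[[g]] <- data.frame(gene_id = gid, chrom = "chrS", strand = strand,
                                   start = pos, end = gene_end, stringsAsFactors = FALSE)
      pos <- gene_end + 500L
    }
    genes <- do.call(rbind, gene_list)
    transcripts <- do.call(rbind, tx_list)
    exons <- do.call(rbind, ex_list)
    gff3 <- .write_gff3(genes, transcripts, exons, file.path(dir, "genome.gff3"))
    fasta <- file.path(dir, "genome.fa")
    chrom_len <- max(genes$end) + 200L
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(.random_dna(chrom_len), "chrS")), fasta)
    list(annotation = parse_gff3(gff3, genome = fasta), gff3 = gff3, fasta = fasta)
  })
}

#' Simulate reads from expressed transcripts with full truth
#'
#' A deliberately minimal simulator: fragment start positions are uniform
#' along each spliced transcript, the expected read count per transcript is
#' `level * coverage * length / read_len`, and sequencing errors are
#' independent substitutions at `error_rate` per base. For every read the
#' truth is recorded: origin transcript and position, the splice junctions
#' the read spans (with overhangs), and the read's genomic footprint.
#'
#' @param annotation a `genome_annotation` with genome loaded
#' @param expressed data frame with `transcript_id` and relative `level`
#'   (default: all transcripts at level 1)
#' @param coverage target per-base depth (default 100)
#' @param read_len read length in nt (default 56)
#' @param error_rate substitution rate per base (default 0.005)
#' @param seed RNG seed (required)
#' @param sample_id label recorded on reads
#' @return a `sim_reads` list: `reads` (read_id, transcript_id, tx_start,
#'   seq), `junctions` (read_id, junction_id, left_overhang,
#'   right_overhang, n_exons spanned by the read), `segments` (read_id,
#'   chrom, start, end genomic blocks), `skipped` (transcripts shorter
#'   than the read length, simulated with a warning elsewhere)
#' @export
simulate_reads <- function(annotation, expressed = NULL, coverage = 100,
                           read_len = 56L, error_rate = 0.005, seed = 1,
                           sample_id = "sample1") {
  if (is.null(annotation$genome)) stop("annotation has no genome loaded", call. = FALSE)
  if (is.null(expressed)) {
    expressed <- data.frame(transcript_id = annotation$transcripts$transcript_id,
                            level = 1, stringsAsFactors = FALSE)
  }
  bad <- setdiff(expressed$transcript_id, annotation$transcripts$transcript_id)
  if (length(bad)) stop("expressed transcript(s) not in annotation: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  .with_seed(seed, {
    reads <- list(); jtruth <- list(); segs <- list(); skipped <- character(0)
    for (i in seq_len(nrow(expressed))) {
      tx <- expressed$transcript_id[i]
      level <- expressed$level[i]
      txseq <- spliced_sequence(annotation, tx)
      L <- nchar(txseq)
      if (L < read_len) {
        skipped <- c(skipped, tx)
        warning("transcript '", tx, "' shorter than read length; skipped")
        next
      }
      n_reads <- stats::rpois(1, level * coverage * L / read_len)
      if (n_reads == 0) next
      starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L
      seqs <- substring(txseq, starts + 1L, starts + read_len)
      # substitution errors
      if (error_rate > 0) {
        n_err <- stats::rbinom(n_reads, read_len, error_rate)
        for (r in which(n_err > 0)) {
          posn <- sample.int(read_len, n_err[r])
          ch <- strsplit(seqs[r], "")[[1]]
          ch[posn] <- vapply(ch[posn], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
          seqs[r] <- paste(ch, collapse = "")
        }
      }
      ids <- sprintf("%s:%s:r%06d", sample_id, tx, seq_len(n_reads))
      reads[[tx]] <- data.frame(read_id = ids, transcript_id = tx,
                                tx_start = starts, seq = seqs,
                                stringsAsFactors = FALSE)

      # transcript -> genome map
      te <- transcript_exons(annotation, tx)
      ex_len <- te$end - te$start
      cum <- cumsum(c(0L, ex_len))  # transcript offsets of exon boundaries
      strand <- te$strand[1]; chrom <- te$chrom[1]

      # junctions spanned (transcription-order consecutive exon pairs)
      if (nrow(te) >= 2) {
        for (k in seq_len(nrow(te) - 1L)) {
          b <- cum[k + 1L]  # transcript coordinate of the boundary
          lo <- b - starts          # nt of read left of boundary
          ro <- starts + read_len - b
          spans <- lo > 0 & ro > 0
          if (!any(spans)) next
          left_ex <- if (strand == "+") te[k, ] else te[k + 1L, ]
          right_ex <- if (strand == "+") te[k + 1L, ] else te[k, ]
          jid <- .junction_id(chrom, left_ex$end, right_ex$start, strand)
          jtruth[[length(jtruth) + 1L]] <- data.frame(
            read_id = ids[spans], junction_id = jid,
            left_overhang = lo[spans], right_overhang = ro[spans],
            stringsAsFactors = FALSE)
        }
      }

      # genomic footprint blocks
      for (k in seq_len(nrow(te))) {
        s_tx <- cum[k]; e_tx <- cum[k + 1L]
        ov_s <- pmax(starts, s_tx); ov_e <- pmin(starts + read_len, e_tx)
        hit <- ov_s < ov_e
        if (!any(hit)) next
        if (strand == "+") {
          gs <- te$start[k] + (ov_s[hit] - s_tx)
          ge <- te$start[k] + (ov_e[hit] - s_tx)
        } else {
          ge <- te$end[k] - (ov_s[hit] - s_tx)
          gs <- te$end[k] - (ov_e[hit] - s_tx)
        }
        segs[[length(segs) + 1L]] <- data.frame(
          read_id = ids[hit], chrom = chrom, start = gs, end = ge,
          stringsAsFactors = FALSE)
      }
    }
    reads <- if (length(reads)) do.call(rbind, reads) else
      data.frame(read_id = character(), transcript_id = character(),
                 tx_start = integer(), seq = character(), stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    jtruth <- if (length(jtruth)) do.call(rbind, jtruth) else
      data.frame(read_id = character(), junction_id = character(),
                 left_overhang = integer(), right_overhang = integer(),
                 stringsAsFactors = FALSE)
    segs <- if (length(segs)) do.call(rbind, segs) else
      data.frame(read_id = character(), chrom = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)
    structure(list(reads = reads, junctions = jtruth, segments = segs,
                   skipped = skipped, sample_id = sample_id,
                   read_len = as.integer(read_len)),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "reads from",
      length(unique(x$reads$transcript_id)), "transcript(s)\n")
  invisible(x)
}

#' Truth-based stage assignment of simulated reads
#'
#' Mirrors how reads align against the exported junction catalog: a read
#' maps to a junction sequence if and only if it covers exactly two exons
#' and overhangs the junction midpoint by at least `min_overhang` on each
#' side (the flank geometry makes shorter overhangs unalignable); all
#' other reads fall through to the genome stage. Returns in-memory
#' alignment tables in the shapes the counting functions accept.
#'
#' @param sim a `sim_reads` object
#' @param catalog the `event_catalog` built from the same annotation
#' @return list with `junction_aln` (read_id, ref, pos, ref_width, seq)
#'   and `genome_reads` (read_id, chrom, start, end)
#' @export
truth_alignments <- function(sim, catalog) {
  h <- catalog$config$min_overhang
  n_seg <- table(sim$segments$read_id)
  jt <- sim$junctions
  two_exon <- names(n_seg)[n_seg == 2]
  ok <- jt$read_id %in% two_exon & jt$left_overhang >= h & jt$right_overhang >= h &
    jt$junction_id %in% catalog$junctions$event_id
  jok <- jt[ok, , drop = FALSE]
  ji <- match(jok$junction_id, catalog$junctions$event_id)
  donor_f <- catalog$junctions$donor_flank[ji]
  junction_aln <- data.frame(
    read_id = jok$read_id, ref = jok$junction_id,
    pos = donor_f - jok$left_overhang,
    ref_width = sim$read_len,
    seq = sim$reads$seq[match(jok$read_id, sim$reads$read_id)],
    stringsAsFactors = FALSE
  )
  genome_ids <- setdiff(sim$reads$read_id, junction_aln$read_id)
  genome_reads <- sim$segments[sim$segments$read_id %in% genome_ids, , drop = FALSE]
  list(junction_aln = junction_aln, genome_reads = genome_reads)
}

#' Write simulated reads as FASTQ
#'
#' @param sim a `sim_reads` object
#' @param path output FASTQ (uncompressed)
#' @return `path`, invisibly
#' @export
write_fastq <- function(sim, path) {
  q <- strrep("I", sim$read_len)
  lines <- as.vector(rbind(paste0("@", sim$reads$read_id), sim$reads$seq, "+", q))
  writeLines(lines, path)
  invisible(path)
}

#' Write truth alignments as SAM
#'
#' Emits two SAM files: reads assigned to the junction stage aligned
#' against the junction catalog sequences, and the remaining reads aligned
#' to the genome (spliced reads use N cigar operations). Together with the
#' truth tables these let the counting stages be tested without running an
#' external aligner.
#'
#' @param sim a `sim_reads` object
#' @param catalog the matching `event_catalog` (with sequences)
#' @param junction_sam,genome_sam output paths
#' @return invisible list of the two paths
#' @export
write_truth_sam <- function(sim, catalog, junction_sam, genome_sam) {
  ta <- truth_alignments(sim, catalog)
  jun <- catalog$junctions
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", jun$event_id, jun$length))
  aln <- ta$junction_aln
  recs <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  aln$read_id, aln$ref, aln$pos + 1L, sim$read_len, aln$seq,
                  strrep("I", sim$read_len))
  writeLines(c(hdr, recs), junction_sam)

  g <- ta$genome_reads
  chroms <- names(catalog$annotation$genome)
  ghdr <- c("@HD\tVN:1.6\tSO:unknown",
            sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                    Biostrings::width(catalog$annotation$genome)))
  by_read <- split(g, g$read_id)
  grecs <- vapply(by_read, function(b) {
    b <- b[order(b$start), ]
    cig <- paste0(b$end[1] - b$start[1], "M")
    if (nrow(b) > 1) {
      for (k in 2:nrow(b)) {
        cig <- paste0(cig, b$start[k] - b$end[k - 1], "N", b$end[k] - b$start[k], "M")
      }
    }
    seq <- sim$reads$seq[match(b$read_id[1], sim$reads$read_id)]
    sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
            b$read_id[1], b$chrom[1], b$start[1] + 1L, cig, seq,
            strrep("I", nchar(seq)))
  }, character(1))
  writeLines(c(ghdr, grecs), genome_sam)
  invisible(list(junction_sam = junction_sam, genome_sam = genome_sam))
}

#' Count one simulated sample through both coverage stages
#'
#' Convenience wrapper: optionally removes duplicate reads, assigns reads
#' to the junction stage via [truth_alignments()], counts both stages and
#' returns the per-sample element expected by [coverage_matrix()]. Reads
#' failing the junction counting rules are routed to the genome stage, so
#' every distinct read is counted in exactly one stage.
#'
#' @param sim a `sim_reads` object
#' @param catalog the matching `event_catalog`
#' @param dedup collapse exact-duplicate reads first (default TRUE)
#' @return list with `junctions` and `genomic` count components
#' @export
count_simulated_sample <- function(sim, catalog, dedup = TRUE) {
  reads <- if (dedup) dedupe_reads(sim$reads) else sim$reads
  ta <- truth_alignments(sim, catalog)
  ja <- ta$junction_aln[ta$junction_aln$read_id %in% reads$read_id, , drop = FALSE]
  jc <- count_junction_alignments(ja, catalog, sim$sample_id)
  genome_ids <- union(
    intersect(ta$genome_reads$read_id, reads$read_id),
    jc$unmapped_reads)
  ga <- sim$segments[sim$segments$read_id %in% genome_ids, , drop = FALSE]
  gc <- count_genomic_events(ga, catalog, sim$sample_id)
  list(junctions = jc, genomic = gc)
}
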