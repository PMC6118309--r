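#' Collapse exact-duplicate reads
#'
#' Identical sequences are collapsed to one representative read (the first
#' seen); no trimming or other processing is performed. Reverse-complement
#' pairs are different sequences and are not collapsed.
#'
#' @param reads data frame with columns `read_id` and `seq`
#' @return the distinct-read subset of `reads`
#' @export
dedupe_reads <- function(reads) {
  .stopifnot_cols(reads, c("read_id", "seq"), "reads")
  reads[!duplicated(reads$seq), , drop = FALSE]
}

#' Average reads per nucleotide
#'
#' APN is the number of distinct reads assigned to an event divided by the
#' event length; an APN of 2 means an average of two reads cover the region.
#'
#' @param read_count non-negative read counts
#' @param length event lengths in nt (must be positive)
#' @return `read_count / length`, exactly
#' @export
compute_apn <- function(read_count, length) {
  if (any(length <= 0)) stop("event length must be positive", call. = FALSE)
  read_count / length
}

# ref-space width of SAM cigars (M/D/N/=/X consume reference)
.cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read alignments from SAM/BAM
#'
#' SAM input is converted to BAM in a temporary directory. Unmapped records
#' are kept (with `rname` NA) so that the full read set can be tracked
#' through the counting stages.
#'
#' @param path SAM or BAM file
#' @return data frame with `read_id`, `ref`, `pos` (0-based leftmost
#'   reference position), `ref_width`, `seq`; one row per alignment record
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             indexDestination = FALSE, overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq")))[[1]]
  mapped <- !is.na(b$pos)
  data.frame(
    read_id = b$qname,
    ref = as.character(b$rname),
    pos = ifelse(mapped, b$pos - 1L, NA_integer_),
    ref_width = ifelse(mapped, .cigar_ref_width(ifelse(mapped, b$cigar, "1M")), NA_integer_),
    seq = as.character(b$seq),
    stringsAsFactors = FALSE
  )
}

#' Genomic footprint of reads in a SAM/BAM genome alignment
#'
#' Spliced alignments (N cigar operations) are split into their aligned
#' blocks, one row per block.
#'
#' @param path SAM or BAM file of genome alignments
#' @return data frame with `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open)
#' @export
read_genomic_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             indexDestination = FALSE, overwrite = TRUE)
  }
  ga <- GenomicAlignments::readGAlignments(path, use.names = TRUE)
  blocks <- GenomicAlignments::grglist(ga)
  ub <- unlist(blocks, use.names = FALSE)
  df <- .from_gr(ub)
  df$read_id <- rep(names(blocks), lengths(blocks))
  df[, c("read_id", "chrom", "start", "end")]
}

#' Count reads aligned to the junction catalog
#'
#' A read counts toward a junction if and only if it aligned uniquely (reads
#' with more than one alignment record are discarded from this stage) and
#' its alignment spans the junction midpoint with at least `min_overhang` nt
#' on each side. The APN length of a junction is its total sequence length
#' (donor flank + acceptor flank). Reads failing these rules are returned
#' for genome-stage mapping.
#'
#' @param alignments SAM/BAM path or data frame from [read_alignments()];
#'   references must be junction IDs of `catalog`
#' @param catalog an `event_catalog`
#' @param sample_id sample label for the output rows
#' @return list with `coverage` (one row per junction event: `event_id`,
#'   `sample_id`, `read_count`, `length`, `apn`), `counted_reads`, and
#'   `unmapped_reads` (read IDs to pass to the genome stage)
#' @export
count_junction_alignments <- function(alignments, catalog, sample_id = "sample1") {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  .stopifnot_cols(alignments, c("read_id", "ref", "pos", "ref_width"), "alignments")
  jun <- catalog$junctions
  aln <- alignments[!is.na(alignments$pos), , drop = FALSE]
  all_ids <- unique(alignments$read_id)

  bad <- setdiff(unique(aln$ref), jun$event_id)
  if (length(bad)) {
    stop("alignment reference(s) not in junction catalog: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }

  multi <- unique(aln$read_id[duplicated(aln$read_id)])
  aln <- aln[!aln$read_id %in% multi, , drop = FALSE]

  ji <- match(aln$ref, jun$event_id)
  mid <- jun$donor_flank[ji]
  h <- catalog$config$min_overhang
  ok <- aln$pos <= mid - h & aln$pos + aln$ref_width >= mid + h
  counted <- aln[ok, , drop = FALSE]
  counted <- counted[!duplicated(paste(counted$read_id, counted$ref)), , drop = FALSE]

  counts <- table(factor(counted$ref, levels = jun$event_id))
  cov <- data.frame(
    event_id = jun$event_id, sample_id = sample_id,
    read_count = as.integer(counts), length = jun$length,
    stringsAsFactors = FALSE
  )
  cov$apn <- compute_apn(cov$read_count, cov$length)
  list(coverage = cov,
       counted_reads = unique(counted$read_id),
       unmapped_reads = setdiff(all_ids, counted$read_id))
}

#' Count reads over genomic event intervals
#'
#' A read counts toward every event interval (exon fragment, single-exon,
#' intron) it overlaps by at least `min_overlap` nt; each distinct read
#' counts at most once per event. APN uses the genomic event length.
#'
#' @param reads SAM/BAM path, or data frame with `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open; one row per aligned block)
#' @param catalog an `event_catalog`
#' @param sample_id sample label
#' @param min_overlap minimum overlap in nt (default 1)
#' @return data frame with one row per genomic event: `event_id`,
#'   `sample_id`, `read_count`, `length`, `apn`
#' @export
count_genomic_events <- function(reads, catalog, sample_id = "sample1", min_overlap = 1L) {
  if (is.character(reads)) reads <- read_genomic_alignments(reads)
  .stopifnot_cols(reads, c("read_id", "chrom", "start", "end"), "reads")
  ev <- .genomic_events(catalog)
  ev$length <- ev$end - ev$start
  if (nrow(reads)) {
    bad <- setdiff(unique(reads$chrom), unique(ev$chrom))
    if (length(bad) && !any(reads$chrom %in% ev$chrom)) {
      stop("alignment chromosome(s) not present in the event catalog: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    rgr <- .gr(reads$chrom, reads$start, reads$end)
    egr <- .gr(ev$chrom, ev$start, ev$end)
    hits <- GenomicRanges::findOverlaps(rgr, egr, minoverlap = min_overlap,
                                        ignore.strand = TRUE)
    pairs <- unique(data.frame(read = reads$read_id[S4Vectors::queryHits(hits)],
                               ev = S4Vectors::subjectHits(hits)))
    counts <- table(factor(pairs$ev, levels = seq_len(nrow(ev))))
  } else {
    counts <- rep(0L, nrow(ev))
  }
  cov <- data.frame(
    event_id = ev$event_id, sample_id = sample_id,
    read_count = as.integer(counts), length = ev$length,
    stringsAsFactors = FALSE
  )
  cov$apn <- compute_apn(cov$read_count, cov$length)
  cov
}

#' Assemble a complete per-sample, per-event coverage table
#'
#' Combines junction-stage and genome-stage counts for one or more samples
#' into one long table covering every event of the catalog; events with no
#' alignments get a zero count, never a missing cell.
#'
#' @param per_sample named list (names = sample IDs); each element a list
#'   with elements `junctions` (output of [count_junction_alignments()]) and
#'   `genomic` (output of [count_genomic_events()]), either optional
#' @param catalog an `event_catalog`
#' @return a `coverage_matrix`: long data frame with `event_id`,
#'   `sample_id`, `read_count`, `length`, `apn`
#' @export
coverage_matrix <- function(per_sample, catalog) {
  stopifnot(length(names(per_sample)) == length(per_sample))
  base <- data.frame(event_id = catalog$events$event_id,
                     length = catalog$events$length, stringsAsFactors = FALSE)
  out <- lapply(names(per_sample), function(s) {
    parts <- per_sample[[s]]
    cov <- rbind(
      if (!is.null(parts$junctions)) parts$junctions$coverage[, c("event_id", "read_count")],
      if (!is.null(parts$genomic)) parts$genomic[, c("event_id", "read_count")]
    )
    m <- base
    m$sample_id <- s
    m$read_count <- 0L
    if (!is.null(cov)) {
      agg <- tapply(cov$read_count, cov$event_id, sum)
      idx <- match(names(agg), m$event_id)
      m$read_count[idx[!is.na(idx)]] <- as.integer(agg[!is.na(idx)])
    }
    m$apn <- compute_apn(m$read_count, m$length)
    m
  })
  res <- do.call(rbind, out)[, c("event_id", "sample_id", "read_count", "length", "apn")]
  rownames(res) <- NULL
  class(res) <- c("coverage_matrix", "data.frame")
  res
}

# wide APN matrix (events x samples) from the long coverage table
.apn_wide <- function(cov) {
  samples <- unique(cov$sample_id)
  events <- unique(cov$event_id)
  m <- matrix(0, nrow = length(events), ncol = length(samples),
              dimnames = list(events, samples))
  m[cbind(match(cov$event_id, events), match(cov$sample_id, samples))] <- cov$apn
  m
}

#' Write a coverage table as TSV
#'
#' One row per (event, sample) cell: sample_id, event_id, read_count,
#' length, apn.
#'
#' @param cov a `coverage_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_coverage_tsv <- function(cov, path) {
  utils::write.table(cov[, c("sample_id", "event_id", "read_count", "length", "apn")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
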