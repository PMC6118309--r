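#' Parse a GFF3 annotation into a validated gene model
#'
#' Reads exon features from a GFF3 file and assembles a gene -> transcript ->
#' exon model with a single internal coordinate convention (0-based,
#' half-open). Exon records with identical coordinates within a gene are
#' treated as the same exon and their transcript memberships are merged.
#' Non-exon features (CDS, UTR, ...) are ignored.
#'
#' @param path path to a GFF3 file. Exon features must carry transcript
#'   parentage, either through the standard `Parent` attribute (pointing at an
#'   mRNA/transcript feature whose own `Parent` is the gene) or through direct
#'   `transcript_id`/`gene_id` attributes.
#' @param dialect attribute-resolution dialect. `"refseq"` and `"ensembl"`
#'   resolve parentage through the `Parent` chain (Ensembl-style
#'   `transcript:`/`gene:` ID prefixes are stripped); `"auto"` (default)
#'   inspects the first 1,000 exon features and prefers direct
#'   `transcript_id`/`gene_id` attributes when present on all of them.
#' @param genome optional genome sequence: a FASTA path or a
#'   [Biostrings::DNAStringSet]. Required later for sequence extraction.
#' @return an object of class `genome_annotation`: a list with data frames
#'   `exons` (one row per distinct exon; columns `exon_key`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`), `exon_tx` (long exon/transcript
#'   mapping), `transcripts`, `genes`, and `genome` (a `DNAStringSet` or
#'   `NULL`). All coordinates are 0-based half-open.
#' @export
parse_gff3 <- function(path, dialect = c("auto", "refseq", "ensembl"), genome = NULL) {
  dialect <- match.arg(dialect)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gff$type))
  mc <- S4Vectors::mcols(gff)

  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features found in ", path, call. = FALSE)
  ex <- gff[is_exon]
  exm <- S4Vectors::mcols(ex)
  ex_idx <- which(is_exon)

  bad_strand <- as.character(GenomicRanges::strand(ex)) == "*"
  if (any(bad_strand)) {
    i <- which(bad_strand)[1]
    stop("exon feature #", ex_idx[i], " (", as.character(GenomicRanges::seqnames(ex))[i],
         ":", GenomicRanges::start(ex)[i], "-", GenomicRanges::end(ex)[i],
         ") has strand '.'", call. = FALSE)
  }

  strip_prefix <- function(x) sub("^(transcript:|gene:|rna-|gene-)", "", x)

  # decide how to resolve transcript parentage
  has_txid <- "transcript_id" %in% names(exm) &&
    all(!is.na(exm$transcript_id[seq_len(min(1000L, length(ex)))]))
  use_attrs <- dialect == "auto" && has_txid && "gene_id" %in% names(exm)

  if (use_attrs) {
    tx_of_exon <- as.list(as.character(exm$transcript_id))
    gene_of_tx <- NULL
    gene_attr <- as.character(exm$gene_id)
  } else {
    if (!"Parent" %in% names(exm)) {
      stop("exon features carry neither Parent nor transcript_id attributes", call. = FALSE)
    }
    parents <- as.list(exm$Parent)
    n_par <- lengths(parents)
    if (any(n_par == 0)) {
      i <- which(n_par == 0)[1]
      stop("exon feature #", ex_idx[i], " (", as.character(GenomicRanges::seqnames(ex))[i],
           ":", GenomicRanges::start(ex)[i], "-", GenomicRanges::end(ex)[i],
           ") has no resolvable transcript parent", call. = FALSE)
    }
    tx_of_exon <- lapply(parents, strip_prefix)

    # map transcript feature ID -> gene ID
    is_tx <- type %in% c("mrna", "transcript", "ncrna", "lnc_rna", "rrna", "trna",
                         "snorna", "snrna", "mirna", "pseudogenic_transcript")
    txf <- gff[is_tx]
    txm <- S4Vectors::mcols(txf)
    tx_ids <- strip_prefix(as.character(txm$ID))
    if ("Parent" %in% names(txm)) {
      tx_parent <- vapply(as.list(txm$Parent), function(p) {
        if (length(p)) strip_prefix(p[[1]]) else NA_character_
      }, character(1))
    } else {
      tx_parent <- rep(NA_character_, length(txf))
    }
    if ("gene_id" %in% names(txm)) {
      tx_parent <- ifelse(is.na(tx_parent), as.character(txm$gene_id), tx_parent)
    }
    gene_of_tx <- stats::setNames(tx_parent, tx_ids)
    gene_attr <- if ("gene_id" %in% names(exm)) as.character(exm$gene_id) else
      rep(NA_character_, length(ex))
  }

  # expand: one row per (exon feature, transcript parent)
  rep_i <- rep(seq_along(ex), lengths(tx_of_exon))
  long <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex))[rep_i],
    start = GenomicRanges::start(ex)[rep_i] - 1L,  # GFF3 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(ex)[rep_i],
    strand = as.character(GenomicRanges::strand(ex))[rep_i],
    transcript_id = unlist(tx_of_exon, use.names = FALSE),
    gene_id = gene_attr[rep_i],
    feature = ex_idx[rep_i],
    stringsAsFactors = FALSE
  )
  if (!use_attrs) {
    need <- is.na(long$gene_id)
    long$gene_id[need] <- unname(gene_of_tx[long$transcript_id[need]])
  }
  if (anyNA(long$gene_id)) {
    i <- which(is.na(long$gene_id))[1]
    stop("transcript '", long$transcript_id[i], "' (exon feature #", long$feature[i],
         ") has no resolvable gene parent", call. = FALSE)
  }

  # overlapping exons within one transcript are malformed input
  by_tx <- split(long, long$transcript_id)
  for (tx in by_tx) {
    if (length(unique(tx$chrom)) > 1 || length(unique(tx$strand)) > 1) {
      stop("transcript '", tx$transcript_id[1], "' spans multiple chromosomes or strands",
           call. = FALSE)
    }
    o <- order(tx$start, tx$end)
    if (nrow(tx) > 1 && any(tx$start[o][-1] < tx$end[o][-nrow(tx)])) {
      stop("overlapping exons within transcript '", tx$transcript_id[1], "'", call. = FALSE)
    }
    if (length(unique(tx$gene_id)) > 1) {
      stop("transcript '", tx$transcript_id[1], "' is assigned to multiple genes", call. = FALSE)
    }
  }

  # deduplicate identical exons within a gene, merging transcript membership
  key <- sprintf("%s:%d-%d:%s:%s", long$chrom, long$start, long$end, long$strand, long$gene_id)
  long$exon_key <- key
  exons <- long[!duplicated(key), c("exon_key", "gene_id", "chrom", "start", "end", "strand")]
  exons <- exons[order(exons$gene_id, exons$start, exons$end), ]
  rownames(exons) <- NULL
  exon_tx <- unique(long[, c("exon_key", "transcript_id")])
  rownames(exon_tx) <- NULL

  transcripts <- unique(long[, c("transcript_id", "gene_id", "chrom", "strand")])
  rownames(transcripts) <- NULL
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  ann <- structure(
    list(exons = exons, exon_tx = exon_tx, transcripts = transcripts,
         genes = genes, genome = NULL, source = path),
    class = "genome_annotation"
  )
  if (!is.null(genome)) ann <- set_genome(ann, genome)
  ann
}

#' Attach a genome sequence to an annotation
#'
#' @param annotation a `genome_annotation`
#' @param genome FASTA path or [Biostrings::DNAStringSet]
#' @return the annotation with `$genome` set; errors if an annotated
#'   chromosome is absent from the sequence set.
#' @export
set_genome <- function(annotation, genome) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  miss <- setdiff(unique(annotation$exons$chrom), names(genome))
  if (length(miss)) {
    stop("annotated chromosome(s) absent from genome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  annotation$genome <- genome
  annotation
}

#' Read a genome FASTA
#'
#' Sequence names are truncated at the first whitespace.
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "gene(s),",
      nrow(x$transcripts), "transcript(s),", nrow(x$exons), "distinct exon(s)\n")
  cat("  genome:", if (is.null(x$genome)) "not loaded" else
    paste(length(x$genome), "sequence(s)"), "\n")
  invisible(x)
}

#' Exons of a transcript in transcription order
#'
#' @param annotation a `genome_annotation`
#' @param transcript_id transcript identifier
#' @return exon data frame ordered 5' to 3' in transcript orientation
#' @export
transcript_exons <- function(annotation, transcript_id) {
  keys <- annotation$exon_tx$exon_key[annotation$exon_tx$transcript_id == transcript_id]
  if (!length(keys)) stop("unknown transcript '", transcript_id, "'", call. = FALSE)
  ex <- annotation$exons[annotation$exons$exon_key %in% keys, ]
  ex[order(ex$start, decreasing = ex$strand[1] == "-"), ]
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcript order; minus-strand transcripts
#' are reverse-complemented. The result length equals the sum of exon lengths.
#'
#' @inheritParams transcript_exons
#' @return nucleotide string
#' @export
spliced_sequence <- function(annotation, transcript_id) {
  if (is.null(annotation$genome)) stop("annotation has no genome loaded", call. = FALSE)
  ex <- transcript_exons(annotation, transcript_id)
  ex <- ex[order(ex$start), ]
  seqs <- vapply(seq_len(nrow(ex)), function(i) {
    .genome_seq(annotation$genome, ex$chrom[i], ex$start[i], ex$end[i])
  }, character(1))
  s <- paste(seqs, collapse = "")
  if (ex$strand[1] == "-") s <- .revcomp(s)
  s
}

#' Spliced sequences for a set of transcripts
#'
#' @param annotation a `genome_annotation`
#' @param transcript_ids transcripts to extract (default: all)
#' @return a named [Biostrings::DNAStringSet]
#' @export
spliced_sequences <- function(annotation, transcript_ids = annotation$transcripts$transcript_id) {
  seqs <- vapply(transcript_ids, function(tx) spliced_sequence(annotation, tx), character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, transcript_ids))
}

#' Derive the distinct introns of each gene
#'
#' Introns are the maximal gaps between consecutive exonic regions
#' (merged overlapping exons) of a gene; a single-region gene has none.
#'
#' @param annotation a `genome_annotation`
#' @param gene_ids genes to process (default: all)
#' @return data frame with columns `intron_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open)
#' @export
derive_introns <- function(annotation, gene_ids = annotation$genes$gene_id) {
  out <- lapply(gene_ids, function(g) {
    ex <- annotation$exons[annotation$exons$gene_id == g, ]
    red <- GenomicRanges::reduce(.gr(ex$chrom, ex$start, ex$end, ex$strand))
    if (length(red) < 2) return(NULL)
    red <- sort(red)
    r <- .from_gr(red)
    data.frame(
      gene_id = g, chrom = r$chrom[1], strand = r$strand[1],
      start = r$end[-nrow(r)], end = r$start[-1],
      stringsAsFactors = FALSE
    )
  })
  introns <- do.call(rbind, out)
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), chrom = character(), strand = character(),
                          start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  introns$intron_id <- sprintf("intron:%s:%d:%d:%s", introns$chrom,
                               introns$start + 1L, introns$end, introns$strand)
  introns[, c("intron_id", "gene_id", "chrom", "strand", "start", "end")]
}

#' Write distinct exons as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' Name column carries the exon key, score is 0.
#'
#' @param annotation a `genome_annotation`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_exon_bed <- function(annotation, path) {
  ex <- annotation$exons
  bed <- data.frame(ex$chrom, ex$start, ex$end, ex$exon_key, 0L, ex$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' @param path BED file (at least 3 columns; name/score/strand optional)
#' @return data frame with `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open)
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  data.frame(
    chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    name = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_,
    strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "*",
    stringsAsFactors = FALSE
  )
}
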