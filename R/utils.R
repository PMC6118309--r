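# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GFF3 I/O converts at the boundary; junction/event IDs print 1-based positions.

# GRanges from internal coordinates
.gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

# internal coordinates from GRanges
.from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence of genome[chrom] over internal [start, end)
.genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' absent from genome", call. = FALSE)
  }
  n <- length(genome[[chrom]])
  if (start < 0 || end > n) {
    stop("coordinates [", start, ",", end, ") outside chromosome '", chrom,
         "' (length ", n, ")", call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.collapse <- function(x) vapply(x, function(v) paste(sort(unique(v)), collapse = ","), character(1))
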