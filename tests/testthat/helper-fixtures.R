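# Shared fixtures and independent brute-force oracles.

# toy worked-example gene, built once per test run
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_gene_model()
    cache
  }
})

toy_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_event_catalog(toy_fixture()$annotation)
    cache
  }
})

# write a small GFF3 + FASTA from a compact exon spec and parse it.
# exons: data.frame(transcript_id, gene_id, start1, end1) (1-based inclusive)
mini_annotation <- function(exons, strand = "+", chrom = "chrM", chrom_seq = NULL,
                            chrom_len = 2000L) {
  dir <- tempfile("mini")
  dir.create(dir)
  gff <- file.path(dir, "mini.gff3")
  lines <- "##gff-version 3"
  for (g in unique(exons$gene_id)) {
    ge <- exons[exons$gene_id == g, ]
    lines <- c(lines, paste(chrom, "t", "gene", min(ge$start1), max(ge$end1), ".",
                            strand, ".", paste0("ID=", g), sep = "\t"))
    for (tx in unique(ge$transcript_id)) {
      te <- ge[ge$transcript_id == tx, ]
      lines <- c(lines, paste(chrom, "t", "mRNA", min(te$start1), max(te$end1), ".",
                              strand, ".", sprintf("ID=%s;Parent=%s", tx, g), sep = "\t"))
      lines <- c(lines, paste(chrom, "t", "exon", te$start1, te$end1, ".", strand, ".",
                              sprintf("ID=%s.e%d;Parent=%s", tx, seq_len(nrow(te)), tx),
                              sep = "\t"))
    }
  }
  writeLines(lines, gff)
  fa <- file.path(dir, "mini.fa")
  if (is.null(chrom_seq)) {
    chrom_seq <- paste(rep(c("A", "C", "G", "T"), length.out = chrom_len), collapse = "")
  }
  writeLines(c(paste0(">", chrom), chrom_seq), fa)
  parse_gff3(gff, genome = fa)
}

# oracle: per-base exon-membership labeling of one region -> fragment partition
oracle_fragments <- function(region, annotation) {
  keys <- region$exon_keys[[1]]
  ex <- annotation$exons[annotation$exons$exon_key %in% keys, ]
  bases <- seq(region$start, region$end - 1L)
  labels <- vapply(bases, function(b) {
    paste(sort(ex$exon_key[ex$start <= b & ex$end > b]), collapse = "|")
  }, character(1))
  runs <- rle(labels)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  data.frame(
    start = bases[starts_idx], end = bases[ends_idx] + 1L,
    members = runs$values, stringsAsFactors = FALSE
  )
}

# oracle: brute-force distinct-coordinate junction count for one gene
oracle_junction_coords <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  strand <- ex$strand[1]
  coords <- character(0)
  for (i in seq_len(nrow(ex))) for (j in seq_len(nrow(ex))) {
    if (i == j) next
    # regardless of strand, a junction joins a genomically-left exon end
    # to a genomically-right exon start
    left <- ex[i, ]; right <- ex[j, ]
    if (left$end <= right$start) {
      coords <- c(coords, paste(left$end, right$start, sep = "_"))
    }
  }
  unique(coords)
}

# oracle: exact two-sided binomial p-value (sum of outcome probabilities
# no larger than the observed one), independent of stats::binom.test
oracle_binom_two_sided <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= stats::dbinom(k, n, 0.5) * (1 + 1e-7)])
}

# assemble a coverage_matrix-shaped long table from a wide APN spec
fake_coverage <- function(apn_by_event, lengths) {
  # apn_by_event: named list event_id -> numeric vector of per-sample APNs
  samples <- paste0("s", seq_along(apn_by_event[[1]]))
  out <- do.call(rbind, lapply(names(apn_by_event), function(ev) {
    apn <- apn_by_event[[ev]]
    data.frame(event_id = ev, sample_id = samples,
               read_count = as.integer(round(apn * lengths[[ev]])),
               length = lengths[[ev]], apn = apn, stringsAsFactors = FALSE)
  }))
  class(out) <- c("coverage_matrix", "data.frame")
  out
}
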