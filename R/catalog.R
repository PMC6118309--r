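#' Catalog construction parameters
#'
#' @param read_len expected read length in nt; junction flanks are sized so
#'   any read counted on a junction overhangs both sides by at least
#'   `min_overhang`.
#' @param min_overhang minimum nt a junction-spanning read must extend past
#'   the junction midpoint on each side (default 8).
#' @param flank_len nt of exon sequence kept on each side of a junction
#'   (default `read_len - min_overhang`).
#' @param min_fragment_len exon fragments shorter than this are kept in the
#'   catalog but excluded from detection statistics (default 10).
#' @return a `catalog_config` list
#' @export
catalog_config <- function(read_len = 56L, min_overhang = 8L,
                           flank_len = read_len - min_overhang,
                           min_fragment_len = 10L) {
  if (!(flank_len >= min_overhang && min_overhang >= 1)) {
    stop("need flank_len >= min_overhang >= 1", call. = FALSE)
  }
  structure(list(read_len = as.integer(read_len),
                 min_overhang = as.integer(min_overhang),
                 flank_len = as.integer(flank_len),
                 min_fragment_len = as.integer(min_fragment_len)),
            class = "catalog_config")
}

#' Build exonic regions from merged overlapping exons
#'
#' An exonic region is the maximal genomic interval covered by (transversely)
#' overlapping exons on one strand. Regions formed by exons of more than one
#' gene are flagged multi-gene and excluded from transcript inference
#' downstream; regions formed by exactly one distinct exon are flagged
#' single-exon (they have no fragments).
#'
#' @param annotation a `genome_annotation`
#' @return data frame with one row per region: `region_id`, `chrom`, `strand`,
#'   `start`, `end`, list-columns `gene_ids` and `exon_keys`, `n_exons`,
#'   `is_single_exon`, `is_multigene`
#' @export
build_exonic_regions <- function(annotation) {
  ex <- annotation$exons
  gr <- .gr(ex$chrom, ex$start, ex$end, ex$strand)
  red <- sort(GenomicRanges::reduce(gr))
  hits <- GenomicRanges::findOverlaps(red, gr)
  ex_by_region <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  r <- .from_gr(red)
  keys <- lapply(seq_len(nrow(r)), function(i) ex$exon_key[ex_by_region[[as.character(i)]]])
  genes <- lapply(seq_len(nrow(r)), function(i) unique(ex$gene_id[ex_by_region[[as.character(i)]]]))
  data.frame(
    region_id = sprintf("er:%s:%d:%d:%s", r$chrom, r$start + 1L, r$end, r$strand),
    chrom = r$chrom, strand = r$strand, start = r$start, end = r$end,
    gene_ids = I(genes), exon_keys = I(keys),
    n_exons = lengths(keys),
    is_single_exon = lengths(keys) == 1L,
    is_multigene = lengths(genes) > 1L,
    stringsAsFactors = FALSE
  )
}

#' Partition one exonic region into exon fragments
#'
#' Cut points are the distinct exon start/end positions inside the region;
#' each fragment carries the exact set of exons covering it and the union of
#' those exons' transcripts. Fragments partition the region with no gaps or
#' overlaps.
#'
#' @param region one row of [build_exonic_regions()] output
#' @param annotation the `genome_annotation` the region was built from
#' @return data frame of fragments (`start`, `end`, list-columns `exon_keys`
#'   and `transcript_ids`)
#' @export
fragment_region <- function(region, annotation) {
  keys <- region$exon_keys[[1]]
  if (length(keys) == 1L) {
    stop("region '", region$region_id,
         "' is formed by a single exon; emit it as a single-exon event instead",
         call. = FALSE)
  }
  ex <- annotation$exons[match(keys, annotation$exons$exon_key), ]
  cuts <- sort(unique(c(ex$start, ex$end)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  cover <- lapply(seq_along(starts), function(i) {
    ex$exon_key[ex$start <= starts[i] & ex$end >= ends[i]]
  })
  tx <- lapply(cover, function(k) {
    unique(annotation$exon_tx$transcript_id[annotation$exon_tx$exon_key %in% k])
  })
  data.frame(
    region_id = region$region_id, chrom = region$chrom, strand = region$strand,
    start = starts, end = ends, exon_keys = I(cover), transcript_ids = I(tx),
    stringsAsFactors = FALSE
  )
}

# genomic junction coordinates for an exon pair in transcription order.
# left_end / right_start are the genomic (plus-strand) boundaries of the
# spanned interval; ids print 1-based positions (AStalavista style).
.junction_id <- function(chrom, left_end, right_start, strand) {
  sprintf("%s:%d:%d:%s", chrom, left_end, right_start + 1L, strand)
}

#' Enumerate all logical splice junctions of a gene
#'
#' Every ordered exon pair (donor strictly 5' of acceptor in transcription
#' orientation, no overlap) yields a junction; pairs sharing donor-end and
#' acceptor-start coordinates collapse to a single junction. Junctions that
#' join consecutive exons of at least one transcript are `annotated`, the
#' rest `unannotated_logical`.
#'
#' @param annotation a `genome_annotation`
#' @param gene_id gene to enumerate
#' @return data frame with one row per distinct junction: `event_id`,
#'   genomic boundaries `left_end`/`right_start` (0-based half-open interval
#'   between the exons), `status`, and list-column `transcript_ids`
#' @export
enumerate_junctions <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  if (nrow(ex) < 2) {
    return(data.frame(event_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      left_end = integer(), right_start = integer(),
                      status = character(), transcript_ids = I(list()),
                      stringsAsFactors = FALSE))
  }
  strand <- ex$strand[1]
  idx <- expand.grid(d = seq_len(nrow(ex)), a = seq_len(nrow(ex)))
  idx <- idx[idx$d != idx$a, ]
  if (strand == "+") {
    ok <- ex$end[idx$d] <= ex$start[idx$a]
    left_end <- ex$end[idx$d][ok]
    right_start <- ex$start[idx$a][ok]
  } else {
    ok <- ex$end[idx$a] <= ex$start[idx$d]
    left_end <- ex$end[idx$a][ok]
    right_start <- ex$start[idx$d][ok]
  }
  jid <- .junction_id(ex$chrom[1], left_end, right_start, strand)
  keep <- !duplicated(jid)
  jun <- data.frame(
    event_id = jid[keep], gene_id = gene_id, chrom = ex$chrom[1], strand = strand,
    left_end = left_end[keep], right_start = right_start[keep],
    stringsAsFactors = FALSE
  )

  # annotated = consecutive in >= 1 transcript
  txs <- annotation$transcripts$transcript_id[annotation$transcripts$gene_id == gene_id]
  ann_map <- vector("list", nrow(jun))
  names(ann_map) <- jun$event_id
  for (tx in txs) {
    te <- transcript_exons(annotation, tx)
    if (nrow(te) < 2) next
    te <- te[order(te$start), ]  # genomic order; consecutive pairs are strand-symmetric
    ids <- .junction_id(te$chrom[1], te$end[-nrow(te)], te$start[-1], strand)
    for (id in ids) ann_map[[id]] <- c(ann_map[[id]], tx)
  }
  jun$transcript_ids <- I(unname(ann_map))
  jun$status <- ifelse(lengths(jun$transcript_ids) > 0, "annotated", "unannotated_logical")
  jun
}

#' Classify junctions as exon-skipping / alternative donor / alternative acceptor
#'
#' A junction skips an exon when at least one annotated exon of the gene lies
#' wholly inside the open interval between donor end and acceptor start
#' (exons only partially inside are not skipped). A donor (acceptor) is
#' alternative when its exonic region contains more than one distinct exon
#' 3'-end (5'-start); where multiple sites exist, all are flagged
#' alternative. The flags are not mutually exclusive.
#'
#' @param junctions output of [enumerate_junctions()]
#' @param annotation the `genome_annotation`
#' @param regions output of [build_exonic_regions()]
#' @return `junctions` with logical columns `exon_skipping`, `alt_donor`,
#'   `alt_acceptor`
#' @export
classify_junctions <- function(junctions, annotation, regions) {
  if (!nrow(junctions)) {
    junctions$exon_skipping <- junctions$alt_donor <- junctions$alt_acceptor <- logical(0)
    return(junctions)
  }
  n <- nrow(junctions)
  skip <- alt_d <- alt_a <- logical(n)
  for (i in seq_len(n)) {
    j <- junctions[i, ]
    gx <- annotation$exons[annotation$exons$gene_id == j$gene_id, ]
    if (j$strand == "+") {
      donor_pos <- j$left_end; acceptor_pos <- j$right_start
      donor_ok <- any(gx$end == donor_pos); acceptor_ok <- any(gx$start == acceptor_pos)
    } else {
      donor_pos <- j$right_start; acceptor_pos <- j$left_end
      donor_ok <- any(gx$start == donor_pos); acceptor_ok <- any(gx$end == acceptor_pos)
    }
    if (!donor_ok || !acceptor_ok) {
      stop("junction '", j$event_id, "' endpoints do not match exon boundaries of gene '",
           j$gene_id, "'", call. = FALSE)
    }
    skip[i] <- any(gx$start >= j$left_end & gx$end <= j$right_start)

    reg_of <- function(pos0) {
      hit <- regions$chrom == j$chrom & regions$strand == j$strand &
        regions$start <= pos0 & regions$end > pos0
      regions[which(hit)[1], ]
    }
    # donor-side region: the region containing the last exonic base of the donor
    donor_reg <- reg_of(if (j$strand == "+") j$left_end - 1L else j$right_start)
    acc_reg <- reg_of(if (j$strand == "+") j$right_start else j$left_end - 1L)
    reg_ex <- function(reg) gx[gx$exon_key %in% reg$exon_keys[[1]], ]
    if (j$strand == "+") {
      alt_d[i] <- length(unique(reg_ex(donor_reg)$end)) > 1
      alt_a[i] <- length(unique(reg_ex(acc_reg)$start)) > 1
    } else {
      alt_d[i] <- length(unique(reg_ex(donor_reg)$start)) > 1
      alt_a[i] <- length(unique(reg_ex(acc_reg)$end)) > 1
    }
  }
  junctions$exon_skipping <- skip
  junctions$alt_donor <- alt_d
  junctions$alt_acceptor <- alt_a
  junctions
}

#' Build exon-intron border junctions for a gene
#'
#' For each annotated intron, two border junctions probe the flanking
#' exon-intron boundaries: a donor-side border extending the 3' edge of the
#' upstream exonic region into the intron, and an acceptor-side border
#' extending the 5' edge of the downstream region. Only annotated intronic
#' sequence is used, so no borders are emitted at the outer gene boundaries.
#' Each border sits at its region's outer boundary and is the region's
#' selected representative for classification.
#'
#' @param annotation a `genome_annotation`
#' @param gene_id gene to process
#' @param regions output of [build_exonic_regions()]
#' @param introns output of [derive_introns()]
#' @param config a [catalog_config()]
#' @return data frame of border junctions with genomic extent
#'   (`gstart`/`gend`), flank lengths, `border_side`, adjacent `region_id`
#'   and `intron_id`, and alternative donor/acceptor flags
#' @export
build_border_junctions <- function(annotation, gene_id, regions, introns,
                                   config = catalog_config()) {
  intr <- introns[introns$gene_id == gene_id, ]
  empty <- data.frame(event_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      gstart = integer(), gend = integer(),
                      exon_flank = integer(), intron_flank = integer(),
                      border_side = character(), region_id = character(),
                      intron_id = character(), alt_donor = logical(),
                      alt_acceptor = logical(), stringsAsFactors = FALSE)
  if (!nrow(intr)) return(empty)
  f <- config$flank_len
  gx <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  out <- list()
  for (i in seq_len(nrow(intr))) {
    s <- intr$start[i]; e <- intr$end[i]
    strand <- intr$strand[i]; chrom <- intr$chrom[i]
    # regions adjacent to this intron (left region ends at s, right starts at e)
    left_reg <- regions[regions$chrom == chrom & regions$strand == strand & regions$end == s, ]
    right_reg <- regions[regions$chrom == chrom & regions$strand == strand & regions$start == e, ]
    if (!nrow(left_reg) || !nrow(right_reg)) next
    fi <- min(f, e - s)
    fl <- min(f, left_reg$end[1] - left_reg$start[1])
    fr <- min(f, right_reg$end[1] - right_reg$start[1])
    alt_ends <- function(reg) {
      ex <- gx[gx$exon_key %in% reg$exon_keys[[1]], ]
      c(n_end = length(unique(ex$end)), n_start = length(unique(ex$start)))
    }
    nl <- alt_ends(left_reg[1, ]); nr <- alt_ends(right_reg[1, ])
    if (strand == "+") {
      donor <- data.frame(gstart = s - fl, gend = s + fi, exon_flank = fl, intron_flank = fi,
                          border_side = "donor", region_id = left_reg$region_id[1],
                          alt_donor = unname(nl["n_end"]) > 1, alt_acceptor = FALSE)
      acceptor <- data.frame(gstart = e - fi, gend = e + fr, exon_flank = fr, intron_flank = fi,
                             border_side = "acceptor", region_id = right_reg$region_id[1],
                             alt_donor = FALSE, alt_acceptor = unname(nr["n_start"]) > 1)
    } else {
      donor <- data.frame(gstart = e - fi, gend = e + fr, exon_flank = fr, intron_flank = fi,
                          border_side = "donor", region_id = right_reg$region_id[1],
                          alt_donor = unname(nr["n_start"]) > 1, alt_acceptor = FALSE)
      acceptor <- data.frame(gstart = s - fl, gend = s + fi, exon_flank = fl, intron_flank = fi,
                             border_side = "acceptor", region_id = left_reg$region_id[1],
                             alt_donor = FALSE, alt_acceptor = unname(nl["n_end"]) > 1)
    }
    b <- rbind(donor, acceptor)
    b$chrom <- chrom; b$strand <- strand; b$gene_id <- gene_id
    b$intron_id <- intr$intron_id[i]
    out[[length(out) + 1L]] <- b
  }
  if (!length(out)) return(empty)
  b <- do.call(rbind, out)
  b$event_id <- sprintf("%s:%d:%d:%s:border_%s", b$chrom, b$gstart + 1L, b$gend,
                        b$strand, b$border_side)
  b[, c("event_id", "gene_id", "chrom", "strand", "gstart", "gend",
        "exon_flank", "intron_flank", "border_side", "region_id", "intron_id",
        "alt_donor", "alt_acceptor")]
}

#' Transcript-frequency class of an event
#'
#' `unique`: annotated to exactly one transcript of a multi-transcript gene
#' (exons of mono-transcript genes are both unique and constitutive and are
#' reported as unique, with a separate mono-transcript tag); `common`: more
#' than one but not all transcripts; `constitutive`: all transcripts;
#' `unannotated`: none; `multigene` overrides all.
#'
#' @param n_tx number of transcripts the event is annotated to (vectorized)
#' @param n_gene_tx number of transcripts of the event's gene
#' @param multigene logical; event shared between genes
#' @return character vector of classes
#' @export
assign_frequency_class <- function(n_tx, n_gene_tx, multigene = FALSE) {
  n <- max(length(n_tx), length(n_gene_tx), length(multigene))
  n_tx <- rep_len(n_tx, n); n_gene_tx <- rep_len(n_gene_tx, n)
  multigene <- rep_len(multigene, n)
  out <- rep("common", n)
  out[n_tx == 0] <- "unannotated"
  out[n_tx == n_gene_tx] <- "constitutive"
  out[n_tx == 1] <- "unique"
  out[multigene] <- "multigene"
  out
}

#' Extract junction sequences
#'
#' Concatenates the last `flank_len` nt of the donor side with the first
#' `flank_len` nt of the acceptor side, in transcription orientation
#' (minus-strand junctions are reverse-complemented). When an exon (or
#' intron, for borders) is shorter than the flank the whole element is used
#' and the realized flank lengths are recorded on the event.
#'
#' @param junctions junction table rows (regular junctions need `left_end`,
#'   `right_start` and flank columns; borders need `gstart`/`gend`)
#' @param annotation a `genome_annotation` with genome loaded
#' @return character vector of sequences, parallel to `junctions`
#' @export
extract_junction_sequence <- function(junctions, annotation) {
  if (is.null(annotation$genome)) stop("annotation has no genome loaded", call. = FALSE)
  vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    if (identical(j$border_side, "donor") || identical(j$border_side, "acceptor")) {
      s <- .genome_seq(annotation$genome, j$chrom, j$gstart, j$gend)
    } else {
      left <- .genome_seq(annotation$genome, j$chrom, j$left_end - j$left_flank, j$left_end)
      right <- .genome_seq(annotation$genome, j$chrom, j$right_start, j$right_start + j$right_flank)
      s <- paste0(left, right)
    }
    if (j$strand == "-") s <- .revcomp(s)
    s
  }, character(1))
}

# realized flank lengths for regular junctions; donor/acceptor exon lengths
# bound the flanks (short exons contribute whole)
.junction_flanks <- function(junctions, annotation, config) {
  f <- config$flank_len
  left_flank <- right_flank <- integer(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    gx <- annotation$exons[annotation$exons$gene_id == j$gene_id, ]
    left_len <- max(gx$end[gx$end == j$left_end] - gx$start[gx$end == j$left_end])
    right_len <- max(gx$end[gx$start == j$right_start] - gx$start[gx$start == j$right_start])
    left_flank[i] <- min(f, left_len)
    right_flank[i] <- min(f, right_len)
  }
  junctions$left_flank <- left_flank
  junctions$right_flank <- right_flank
  # donor/acceptor flank in transcription orientation
  junctions$donor_flank <- ifelse(junctions$strand == "+", left_flank, right_flank)
  junctions$acceptor_flank <- ifelse(junctions$strand == "+", right_flank, left_flank)
  junctions
}

#' Build the complete event catalog
#'
#' Runs the full annotation-side workflow: exonic regions, exon fragments and
#' single-exon events, distinct introns, the exhaustive junction catalog
#' (annotated + logical + border junctions) with splicing classification,
#' transcript-frequency classes, junction sequences (when a genome is
#' loaded), and multi-gene flags. Junctions whose flanking sequence occurs
#' identically in more than one gene, and events in regions overlapping
#' exons of more than one gene, are flagged multi-gene and excluded from
#' transcript inference.
#'
#' @param annotation a `genome_annotation`
#' @param config a [catalog_config()]
#' @return an object of class `event_catalog` with tables `regions`,
#'   `fragments`, `single_exons`, `introns`, `junctions` (including
#'   borders), a unified `events` table, and the transcript-to-event map
#'   `tx_events`
#' @export
build_event_catalog <- function(annotation, config = catalog_config()) {
  regions <- build_exonic_regions(annotation)
  introns <- derive_introns(annotation)
  n_gene_tx <- table(annotation$transcripts$gene_id)

  region_gene_ntx <- vapply(regions$gene_ids, function(g) sum(n_gene_tx[g]), numeric(1))

  # fragments for multi-exon regions
  frag_list <- lapply(which(!regions$is_single_exon), function(i) {
    fragment_region(regions[i, ], annotation)
  })
  fragments <- if (length(frag_list)) do.call(rbind, frag_list) else NULL
  if (!is.null(fragments)) {
    fragments$event_id <- sprintf("ef:%s:%d:%d:%s", fragments$chrom,
                                  fragments$start + 1L, fragments$end, fragments$strand)
    ri <- match(fragments$region_id, regions$region_id)
    fragments$is_multigene <- regions$is_multigene[ri]
    fragments$gene_ids <- regions$gene_ids[ri]
    fragments$length <- fragments$end - fragments$start
    fragments$freq_class <- assign_frequency_class(
      lengths(fragments$transcript_ids), region_gene_ntx[ri], fragments$is_multigene)
    fragments$detectable <- fragments$length >= config$min_fragment_len
  } else {
    fragments <- data.frame(region_id = character(), chrom = character(),
                            strand = character(), start = integer(), end = integer(),
                            exon_keys = I(list()), transcript_ids = I(list()),
                            event_id = character(), is_multigene = logical(),
                            gene_ids = I(list()), length = integer(),
                            freq_class = character(), detectable = logical(),
                            stringsAsFactors = FALSE)
  }

  # single-exon events
  se_idx <- which(regions$is_single_exon)
  single_exons <- regions[se_idx, c("region_id", "chrom", "strand", "start", "end",
                                    "exon_keys", "gene_ids", "is_multigene")]
  single_exons$transcript_ids <- I(lapply(se_idx, function(i) {
    unique(annotation$exon_tx$transcript_id[
      annotation$exon_tx$exon_key %in% regions$exon_keys[[i]]])
  }))
  single_exons$event_id <- sprintf("se:%s:%d:%d:%s", single_exons$chrom,
                                   single_exons$start + 1L, single_exons$end,
                                   single_exons$strand)
  single_exons$length <- single_exons$end - single_exons$start
  single_exons$freq_class <- assign_frequency_class(
    lengths(single_exons$transcript_ids), region_gene_ntx[se_idx],
    single_exons$is_multigene)
  single_exons$mono_transcript <- region_gene_ntx[se_idx] == 1
  rownames(single_exons) <- NULL

  introns$event_id <- introns$intron_id
  introns$length <- introns$end - introns$start

  # junction catalog: logical + annotated, then borders
  jun_list <- lapply(annotation$genes$gene_id, function(g) {
    j <- enumerate_junctions(annotation, g)
    classify_junctions(j, annotation, regions)
  })
  junctions <- do.call(rbind, jun_list)
  if (is.null(junctions) || !nrow(junctions)) {
    junctions <- data.frame(event_id = character(), gene_id = character(),
                            chrom = character(), strand = character(),
                            left_end = integer(), right_start = integer(),
                            status = character(), transcript_ids = I(list()),
                            exon_skipping = logical(), alt_donor = logical(),
                            alt_acceptor = logical(), stringsAsFactors = FALSE)
  }
  junctions$border_side <- "none"
  junctions <- .junction_flanks(junctions, annotation, config)
  junctions$length <- junctions$donor_flank + junctions$acceptor_flank
  junctions$gstart <- NA_integer_; junctions$gend <- NA_integer_
  junctions$exon_flank <- NA_integer_; junctions$intron_flank <- NA_integer_
  junctions$region_id <- NA_character_; junctions$intron_id <- NA_character_
  junctions$freq_class <- assign_frequency_class(
    lengths(junctions$transcript_ids),
    as.integer(n_gene_tx[junctions$gene_id]))
  junctions$mono_transcript <- as.integer(n_gene_tx[junctions$gene_id]) == 1 &
    junctions$status == "annotated"

  borders <- do.call(rbind, lapply(annotation$genes$gene_id, function(g) {
    build_border_junctions(annotation, g, regions, introns, config)
  }))
  if (!is.null(borders) && nrow(borders)) {
    borders$status <- "border"
    borders$transcript_ids <- I(rep(list(character(0)), nrow(borders)))
    borders$exon_skipping <- FALSE
    borders$left_end <- NA_integer_; borders$right_start <- NA_integer_
    borders$left_flank <- NA_integer_; borders$right_flank <- NA_integer_
    borders$donor_flank <- ifelse(borders$border_side == "donor",
                                  borders$exon_flank, borders$intron_flank)
    borders$acceptor_flank <- ifelse(borders$border_side == "acceptor",
                                     borders$exon_flank, borders$intron_flank)
    borders$length <- borders$exon_flank + borders$intron_flank
    borders$freq_class <- "unannotated"
    borders$mono_transcript <- FALSE
    cols <- c("event_id", "gene_id", "chrom", "strand", "left_end", "right_start",
              "status", "transcript_ids", "exon_skipping", "alt_donor", "alt_acceptor",
              "border_side", "left_flank", "right_flank", "donor_flank",
              "acceptor_flank", "exon_flank", "intron_flank", "length",
              "gstart", "gend", "region_id", "intron_id",
              "freq_class", "mono_transcript")
    junctions <- rbind(junctions[, cols], borders[, cols])
  }
  rownames(junctions) <- NULL

  # junction sequences and sequence-identity multi-gene flagging
  junctions$seq <- NA_character_
  if (!is.null(annotation$genome)) {
    junctions$seq <- extract_junction_sequence(junctions, annotation)
    dup <- split(junctions$gene_id, junctions$seq)
    multi_seq <- names(dup)[vapply(dup, function(g) length(unique(g)) > 1, logical(1))]
    is_multi <- junctions$seq %in% multi_seq
    junctions$freq_class[is_multi] <- "multigene"
  }
  # junction flanks overlapping exons of a different gene are also multi-gene
  multi_regions <- regions$region_id[regions$is_multigene]
  if (length(multi_regions)) {
    mr <- regions[regions$is_multigene, ]
    mgr <- .gr(mr$chrom, mr$start, mr$end, mr$strand)
    reg_j <- junctions[junctions$border_side == "none", ]
    lgr <- .gr(reg_j$chrom, reg_j$left_end - reg_j$left_flank, reg_j$left_end, reg_j$strand)
    rgr <- .gr(reg_j$chrom, reg_j$right_start, reg_j$right_start + reg_j$right_flank,
               reg_j$strand)
    hit <- unique(c(S4Vectors::queryHits(GenomicRanges::findOverlaps(lgr, mgr)),
                    S4Vectors::queryHits(GenomicRanges::findOverlaps(rgr, mgr))))
    junctions$freq_class[which(junctions$border_side == "none")[hit]] <- "multigene"
  }
  junctions$is_multigene <- junctions$freq_class == "multigene"

  # transcript -> event map (junctions + fragments + single-exons; multi-gene excluded)
  tx_map <- function(df) {
    ok <- !df$is_multigene
    data.frame(
      transcript_id = unlist(df$transcript_ids[ok], use.names = FALSE),
      event_id = rep(df$event_id[ok], lengths(df$transcript_ids[ok])),
      stringsAsFactors = FALSE
    )
  }
  tx_events <- rbind(tx_map(junctions), tx_map(fragments), tx_map(single_exons))

  events <- rbind(
    data.frame(event_id = fragments$event_id,
               event_type = rep("fragment", nrow(fragments)),
               length = fragments$length, freq_class = fragments$freq_class,
               is_multigene = fragments$is_multigene,
               detectable = fragments$detectable, stringsAsFactors = FALSE),
    data.frame(event_id = single_exons$event_id,
               event_type = rep("single_exon", nrow(single_exons)),
               length = single_exons$length, freq_class = single_exons$freq_class,
               is_multigene = single_exons$is_multigene,
               detectable = rep(TRUE, nrow(single_exons)), stringsAsFactors = FALSE),
    data.frame(event_id = introns$event_id,
               event_type = rep("intron", nrow(introns)),
               length = introns$length,
               freq_class = rep("unannotated", nrow(introns)),
               is_multigene = rep(FALSE, nrow(introns)),
               detectable = rep(TRUE, nrow(introns)), stringsAsFactors = FALSE),
    data.frame(event_id = junctions$event_id,
               event_type = ifelse(junctions$border_side == "none", "junction", "border"),
               length = junctions$length, freq_class = junctions$freq_class,
               is_multigene = junctions$is_multigene, detectable = TRUE,
               stringsAsFactors = FALSE)
  )
  rownames(events) <- NULL

  structure(
    list(annotation = annotation, config = config, regions = regions,
         fragments = fragments, single_exons = single_exons, introns = introns,
         junctions = junctions, events = events, tx_events = tx_events),
    class = "event_catalog"
  )
}

#' @export
print.event_catalog <- function(x, ...) {
  tab <- table(x$events$event_type)
  cat("event_catalog:", nrow(x$events), "events\n")
  for (t in names(tab)) cat("  ", t, ": ", tab[[t]], "\n", sep = "")
  jt <- x$junctions[x$junctions$border_side == "none", ]
  cat("  junctions annotated/logical: ", sum(jt$status == "annotated"), "/",
      sum(jt$status == "unannotated_logical"), "\n", sep = "")
  invisible(x)
}

# genome-stage countable intervals: fragments, single-exons, introns
.genomic_events <- function(catalog) {
  rbind(
    catalog$fragments[, c("event_id", "chrom", "start", "end")],
    catalog$single_exons[, c("event_id", "chrom", "start", "end")],
    catalog$introns[, c("event_id", "chrom", "start", "end")]
  )
}

#' Export the catalog to disk
#'
#' Writes the junction FASTA (headers are junction IDs), BED6 files for
#' exonic regions, exon fragments, single-exon events and introns, and a
#' tab-separated event annotation table with fixed column order: event_id,
#' gene_id, event_type, status, exon_skipping, alt_donor, alt_acceptor,
#' freq_class, transcript_ids, length.
#'
#' @param catalog an `event_catalog`
#' @param dir output directory (created if absent)
#' @return named list of written paths
#' @export
export_catalog <- function(catalog, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- function(df, path, name) {
    utils::write.table(
      data.frame(df$chrom, df$start, df$end, name, 0L, df$strand),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    path
  }
  paths <- list(
    regions_bed = bed(catalog$regions, file.path(dir, "exonic_regions.bed"),
                      catalog$regions$region_id),
    fragments_bed = bed(catalog$fragments, file.path(dir, "exon_fragments.bed"),
                        catalog$fragments$event_id),
    single_exons_bed = bed(catalog$single_exons, file.path(dir, "single_exons.bed"),
                           catalog$single_exons$event_id),
    introns_bed = bed(catalog$introns, file.path(dir, "introns.bed"),
                      catalog$introns$event_id)
  )
  jun <- catalog$junctions
  if (!all(is.na(jun$seq))) {
    fa <- Biostrings::DNAStringSet(stats::setNames(jun$seq, jun$event_id))
    paths$junction_fasta <- file.path(dir, "junctions.fa")
    Biostrings::writeXStringSet(fa, paths$junction_fasta)
  }
  gene_of <- function(df) if ("gene_id" %in% names(df)) df$gene_id else .collapse(df$gene_ids)
  ann <- rbind(
    data.frame(event_id = jun$event_id, gene_id = jun$gene_id, event_type =
                 ifelse(jun$border_side == "none", "junction", "border"),
               status = jun$status, exon_skipping = jun$exon_skipping,
               alt_donor = jun$alt_donor, alt_acceptor = jun$alt_acceptor,
               freq_class = jun$freq_class,
               transcript_ids = .collapse(jun$transcript_ids),
               length = jun$length, stringsAsFactors = FALSE),
    data.frame(event_id = catalog$fragments$event_id,
               gene_id = gene_of(catalog$fragments), event_type = "fragment",
               status = "annotated", exon_skipping = FALSE, alt_donor = FALSE,
               alt_acceptor = FALSE, freq_class = catalog$fragments$freq_class,
               transcript_ids = .collapse(catalog$fragments$transcript_ids),
               length = catalog$fragments$length, stringsAsFactors = FALSE),
    data.frame(event_id = catalog$single_exons$event_id,
               gene_id = gene_of(catalog$single_exons), event_type = "single_exon",
               status = "annotated", exon_skipping = FALSE, alt_donor = FALSE,
               alt_acceptor = FALSE, freq_class = catalog$single_exons$freq_class,
               transcript_ids = .collapse(catalog$single_exons$transcript_ids),
               length = catalog$single_exons$length, stringsAsFactors = FALSE),
    data.frame(event_id = catalog$introns$event_id, gene_id = catalog$introns$gene_id,
               event_type = "intron", status = "unannotated", exon_skipping = FALSE,
               alt_donor = FALSE, alt_acceptor = FALSE, freq_class = "unannotated",
               transcript_ids = "", length = catalog$introns$length,
               stringsAsFactors = FALSE)
  )
  paths$events_tsv <- file.path(dir, "events.tsv")
  utils::write.table(ann, paths$events_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Parse a junction FASTA header back to coordinates
#'
#' @param id junction IDs of the form `chrom:donor:acceptor:strand` (1-based
#'   positions) or border IDs `chrom:start:end:strand:border_side`
#' @return data frame with `chrom`, `pos1`, `pos2`, `strand`, `border_side`
#' @export
parse_junction_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    pos1 = as.integer(vapply(parts, `[`, character(1), 2)),
    pos2 = as.integer(vapply(parts, `[`, character(1), 3)),
    strand = vapply(parts, `[`, character(1), 4),
    border_side = vapply(parts, function(p) {
      if (length(p) >= 5) sub("^border_", "", p[5]) else "none"
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
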