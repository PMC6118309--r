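#' Cross-sample event detection rule
#'
#' Expresses rules like "APN > 0 in at least three of the six samples" or
#' "APN > 5 in at least 50% of subjects". The comparison operator is
#' explicit because both strict and non-strict thresholds are in routine
#' use (APN > 0 detection; APN >= 5 filtering).
#'
#' @param min_apn APN threshold
#' @param op `">"` or `">="`
#' @param min_samples integer: minimum number of samples meeting the
#'   threshold. Exactly one of `min_samples`/`min_sample_fraction` must be
#'   given.
#' @param min_sample_fraction proportion of samples meeting the threshold
#' @return a `detection_rule`
#' @export
detection_rule <- function(min_apn = 0, op = c(">", ">="), min_samples = NULL,
                           min_sample_fraction = NULL) {
  op <- match.arg(op)
  if (is.null(min_samples) == is.null(min_sample_fraction)) {
    stop("set exactly one of min_samples / min_sample_fraction", call. = FALSE)
  }
  structure(list(min_apn = min_apn, op = op, min_samples = min_samples,
                 min_sample_fraction = min_sample_fraction),
            class = "detection_rule")
}

.rule_hits <- function(apn, rule) {
  if (rule$op == ">") apn > rule$min_apn else apn >= rule$min_apn
}

#' Flag detected events across samples
#'
#' @param cov a `coverage_matrix` (long event x sample table)
#' @param rule a [detection_rule()]
#' @param catalog optional `event_catalog`; when given, exon fragments
#'   shorter than the configured minimum are excluded from flagging
#'   (returned as `NA`)
#' @return data frame with `event_id` and logical `detected`
#' @export
flag_detection <- function(cov, rule, catalog = NULL) {
  apn <- .apn_wide(cov)
  n_samples <- ncol(apn)
  needed <- if (!is.null(rule$min_samples)) rule$min_samples else
    ceiling(rule$min_sample_fraction * n_samples)
  if (needed > n_samples) {
    stop("rule requires ", needed, " samples but coverage has ", n_samples, call. = FALSE)
  }
  det <- rowSums(.rule_hits(apn, rule)) >= needed
  out <- data.frame(event_id = rownames(apn), detected = unname(det),
                    stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    skip <- catalog$events$event_id[!catalog$events$detectable]
    out$detected[out$event_id %in% skip] <- NA
  }
  out
}

#' Border junction classification thresholds
#'
#' @param novel_ratio border APN at least this fraction of the adjacent
#'   exon APN calls a possible novel donor/acceptor (default 0.90)
#' @param ir_ratio border APN at least this fraction of the adjacent exon
#'   APN, with the intron also detected, calls possible intron retention
#'   (default 0.10)
#' @return a `border_config`
#' @export
border_config <- function(novel_ratio = 0.90, ir_ratio = 0.10) {
  if (!(ir_ratio > 0 && ir_ratio <= novel_ratio && novel_ratio <= 1)) {
    stop("need 0 < ir_ratio <= novel_ratio <= 1", call. = FALSE)
  }
  structure(list(novel_ratio = novel_ratio, ir_ratio = ir_ratio),
            class = "border_config")
}

#' Classify a detected border junction
#'
#' Border junctions are only classified when their adjacent exon is also
#' detected. A border with mean APN at least `novel_ratio` of the exon APN
#' is a possible novel donor/acceptor; one with at least `ir_ratio` of the
#' exon APN whose adjacent intron is also detected is possible intron
#' retention; a border meeting both is ambiguous intron retention; anything
#' else is a possible unprocessed transcript.
#'
#' @param border_apn mean APN of the border junction (over detected samples)
#' @param exon_apn mean APN of the adjacent exon
#' @param intron_detected logical, adjacent intron detected
#' @param exon_detected logical, adjacent exon detected
#' @param config a [border_config()]
#' @return character vector with values `possible_novel_donor_acceptor`,
#'   `possible_IR`, `ambiguous_IR`, `possible_unprocessed`, or
#'   `unclassified` (adjacent exon not detected)
#' @export
classify_border <- function(border_apn, exon_apn, intron_detected, exon_detected,
                            config = border_config()) {
  if (any(border_apn < 0 | exon_apn < 0)) stop("negative APN", call. = FALSE)
  n <- max(length(border_apn), length(exon_apn), length(intron_detected),
           length(exon_detected))
  border_apn <- rep_len(border_apn, n); exon_apn <- rep_len(exon_apn, n)
  intron_detected <- rep_len(intron_detected, n)
  exon_detected <- rep_len(exon_detected, n)
  novel <- border_apn >= config$novel_ratio * exon_apn
  ir <- border_apn >= config$ir_ratio * exon_apn & intron_detected
  out <- rep("possible_unprocessed", n)
  out[novel & !ir] <- "possible_novel_donor_acceptor"
  out[!novel & ir] <- "possible_IR"
  out[novel & ir] <- "ambiguous_IR"
  out[!exon_detected] <- "unclassified"
  out
}

#' Classify all detected border junctions of a catalog
#'
#' For each border junction, the adjacent exon is the fragment or
#' single-exon event of its exonic region touching the exon-intron
#' boundary; the adjacent intron is the border's intron event. Mean APNs
#' are taken over the samples in which each event meets the detection rule
#' (configurable to the all-samples mean).
#'
#' @param catalog an `event_catalog`
#' @param cov a `coverage_matrix`
#' @param rule a [detection_rule()] used for per-sample detection
#' @param config a [border_config()]
#' @param mean_over `"detected"` (default) or `"all"` samples
#' @return data frame with one row per detected border junction:
#'   `event_id`, `border_side`, `region_id`, `intron_id`, `border_apn`,
#'   `exon_apn`, `intron_detected`, `exon_detected`, `call`
#' @export
classify_borders <- function(catalog, cov, rule, config = border_config(),
                             mean_over = c("detected", "all")) {
  mean_over <- match.arg(mean_over)
  borders <- catalog$junctions[catalog$junctions$border_side != "none", ]
  det <- flag_detection(cov, rule, catalog)
  det_of <- function(id) det$detected[match(id, det$event_id)]
  apn <- .apn_wide(cov)
  mean_apn <- function(id) {
    v <- apn[id, , drop = TRUE]
    use <- if (mean_over == "detected") .rule_hits(v, rule) else rep(TRUE, length(v))
    if (!any(use)) 0 else mean(v[use])
  }
  borders <- borders[det_of(borders$event_id) %in% TRUE, ]
  if (!nrow(borders)) {
    return(data.frame(event_id = character(), border_side = character(),
                      region_id = character(), intron_id = character(),
                      border_apn = numeric(), exon_apn = numeric(),
                      intron_detected = logical(), exon_detected = logical(),
                      call = character(), stringsAsFactors = FALSE))
  }
  # adjacent exon event: region member touching the exon-intron boundary
  adj_event <- vapply(seq_len(nrow(borders)), function(i) {
    b <- borders[i, ]
    reg <- catalog$regions[catalog$regions$region_id == b$region_id, ]
    if (reg$is_single_exon) return(catalog$single_exons$event_id[
      catalog$single_exons$region_id == b$region_id])
    fr <- catalog$fragments[catalog$fragments$region_id == b$region_id, ]
    # boundary = the region edge inside the border's genomic extent
    if (b$gstart < reg$start || reg$end < b$gend) {
      if (b$gstart < reg$start && b$gend > reg$start) {
        return(fr$event_id[fr$start == reg$start])
      }
      return(fr$event_id[fr$end == reg$end])
    }
    fr$event_id[1]
  }, character(1))
  out <- data.frame(
    event_id = borders$event_id, border_side = borders$border_side,
    region_id = borders$region_id, intron_id = borders$intron_id,
    border_apn = vapply(borders$event_id, mean_apn, numeric(1)),
    exon_apn = vapply(adj_event, mean_apn, numeric(1)),
    intron_detected = det_of(borders$intron_id) %in% TRUE,
    exon_detected = det_of(adj_event) %in% TRUE,
    stringsAsFactors = FALSE
  )
  out$call <- classify_border(out$border_apn, out$exon_apn, out$intron_detected,
                              out$exon_detected, config)
  rownames(out) <- NULL
  out
}

#' Summarize detection and coverage per transcript
#'
#' Each transcript is a series of events (its annotated junctions plus the
#' exon fragments and single-exon events it contains; whole exonic regions
#' are not double-counted and multi-gene events are excluded). Coverage is
#' combined over events, length-weighted: `mean_apn` is the per-sample mean
#' of total reads divided by total event length. Exon fragments below the
#' catalog's minimum detectable length are excluded from both numerator and
#' denominator of the detection proportions.
#'
#' @param catalog an `event_catalog`
#' @param cov a `coverage_matrix`
#' @param rule a [detection_rule()]
#' @return data frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `n_events`, `n_detected`, `prop_detected`, `n_unique`,
#'   `n_unique_detected`, `prop_unique_detected` (NA when the transcript
#'   has no unique events), `total_reads` (mean per sample),
#'   `total_length`, `mean_apn`. The detection rule is attached as
#'   attribute `"rule"`.
#' @export
summarize_transcripts <- function(catalog, cov, rule) {
  det <- flag_detection(cov, rule, catalog)
  ev <- catalog$events
  te <- catalog$tx_events
  te <- te[ev$detectable[match(te$event_id, ev$event_id)], ]
  te$detected <- det$detected[match(te$event_id, det$event_id)]
  te$freq_class <- ev$freq_class[match(te$event_id, ev$event_id)]
  te$length <- ev$length[match(te$event_id, ev$event_id)]
  counts <- .apn_wide(cov)  # reuse layout for reads
  reads_wide <- counts
  reads_wide[] <- 0
  reads_wide[cbind(match(cov$event_id, rownames(counts)),
                   match(cov$sample_id, colnames(counts)))] <- cov$read_count
  te$mean_reads <- rowMeans(reads_wide)[te$event_id]

  tx_all <- catalog$annotation$transcripts
  by_tx <- split(te, factor(te$transcript_id, levels = tx_all$transcript_id))
  out <- do.call(rbind, lapply(names(by_tx), function(tx) {
    e <- by_tx[[tx]]
    n <- nrow(e)
    n_u <- sum(e$freq_class == "unique")
    data.frame(
      transcript_id = tx,
      gene_id = tx_all$gene_id[match(tx, tx_all$transcript_id)],
      n_events = n,
      n_detected = sum(e$detected, na.rm = TRUE),
      prop_detected = if (n) sum(e$detected, na.rm = TRUE) / n else NA_real_,
      n_unique = n_u,
      n_unique_detected = sum(e$detected[e$freq_class == "unique"], na.rm = TRUE),
      prop_unique_detected = if (n_u) {
        sum(e$detected[e$freq_class == "unique"], na.rm = TRUE) / n_u
      } else NA_real_,
      total_reads = sum(e$mean_reads),
      total_length = sum(e$length),
      mean_apn = if (n) sum(e$mean_reads) / sum(e$length) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  out
}

#' Transcript filtering rule
#'
#' @param min_prop_events minimum proportion of a transcript's events that
#'   must be detected (default 0.75)
#' @param min_apn APN threshold at which events count as detected
#'   (default 5)
#' @param op `">="` (default) or `">"`
#' @param require_unique_detected if `TRUE`, additionally require at least
#'   one unique event detected (default off)
#' @return a `filter_rule`
#' @export
filter_rule <- function(min_prop_events = 0.75, min_apn = 5, op = c(">=", ">"),
                        require_unique_detected = FALSE) {
  op <- match.arg(op)
  if (min_prop_events < 0 || min_prop_events > 1) {
    stop("min_prop_events must be in [0, 1]", call. = FALSE)
  }
  structure(list(min_prop_events = min_prop_events, min_apn = min_apn, op = op,
                 require_unique_detected = require_unique_detected),
            class = "filter_rule")
}

#' Filter transcripts to the probably-expressed set
#'
#' Retains transcripts whose proportion of detected events meets the rule;
#' summaries must have been computed under the same per-event APN threshold
#' as the filter rule.
#'
#' @param summaries output of [summarize_transcripts()]
#' @param rule a [filter_rule()]
#' @return list with `retained` (transcript IDs) and `summary` (the input
#'   table plus a logical `retained_flag` column)
#' @export
filter_transcripts <- function(summaries, rule = filter_rule()) {
  drule <- attr(summaries, "rule")
  if (is.null(drule) || drule$min_apn != rule$min_apn || drule$op != rule$op) {
    stop("summaries were computed under a different APN threshold than the filter rule",
         call. = FALSE)
  }
  keep <- !is.na(summaries$prop_detected) & summaries$n_events > 0 &
    summaries$prop_detected >= rule$min_prop_events
  if (rule$require_unique_detected) {
    keep <- keep & summaries$n_unique > 0 & summaries$n_unique_detected >= 1
  }
  summaries$retained_flag <- keep
  list(retained = summaries$transcript_id[keep], summary = summaries)
}

#' Write the per-transcript summary table
#'
#' Tab-delimited, fixed column order: transcript_id, gene_id, n_events,
#' n_detected, prop_detected, n_unique, n_unique_detected,
#' prop_unique_detected, total_reads, total_length, mean_apn,
#' retained_flag.
#'
#' @param filtered output of [filter_transcripts()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_transcript_summary <- function(filtered, path) {
  cols <- c("transcript_id", "gene_id", "n_events", "n_detected", "prop_detected",
            "n_unique", "n_unique_detected", "prop_unique_detected", "total_reads",
            "total_length", "mean_apn", "retained_flag")
  utils::write.table(filtered$summary[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the reduced reference transcriptome
#'
#' Emits a FASTA of spliced sequences for the retained transcripts and a
#' two-column tab-delimited gene-to-transcript index, the inputs expected
#' by downstream isoform quantifier reference builders.
#'
#' @param retained transcript IDs to keep
#' @param annotation a `genome_annotation` with genome loaded
#' @param fasta_path output FASTA
#' @param index_path output gene-to-transcript TSV
#' @return invisible list of the two paths and the transcript count
#' @export
write_reduced_reference <- function(retained, annotation, fasta_path, index_path) {
  unknown <- setdiff(retained, annotation$transcripts$transcript_id)
  if (length(unknown)) {
    stop("retained transcript(s) absent from annotation: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  if (!length(retained)) {
    warning("empty retained set; writing empty reference files")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), fasta_path)
    utils::write.table(data.frame(character(), character()), index_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    return(invisible(list(fasta = fasta_path, index = index_path, n = 0L)))
  }
  seqs <- spliced_sequences(annotation, retained)
  Biostrings::writeXStringSet(seqs, fasta_path)
  idx <- data.frame(
    gene_id = annotation$transcripts$gene_id[
      match(retained, annotation$transcripts$transcript_id)],
    transcript_id = retained, stringsAsFactors = FALSE
  )
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  message("reduced reference: ", length(retained), " transcript(s) written")
  invisible(list(fasta = fasta_path, index = index_path, n = length(retained)))
}
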