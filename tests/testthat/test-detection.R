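# minimal catalog stub for arithmetic-level checks of transcript summaries
stub_catalog <- function(events, tx_events, transcripts) {
  list(events = events, tx_events = tx_events,
       annotation = list(transcripts = transcripts))
}

test_that("detection rules count qualifying samples correctly", {
  lens <- list(e1 = 100L)
  rule36 <- detection_rule(0, ">", min_samples = 3)
  cov <- fake_coverage(list(e1 = c(0, 0, 1, 1, 1, 0)), lens)
  expect_true(flag_detection(cov, rule36)$detected)

  cov2 <- fake_coverage(list(e1 = c(0, 0, 0, 0, 1, 1)), lens)
  expect_false(flag_detection(cov2, rule36)$detected)

  # APN > 5 in at least 50% of subjects
  rule_frac <- detection_rule(5, ">", min_sample_fraction = 0.5)
  cov3 <- fake_coverage(list(e1 = c(6, 6, 0, 0)), lens)
  expect_true(flag_detection(cov3, rule_frac)$detected)

  expect_error(flag_detection(cov3, detection_rule(0, ">", min_samples = 9)),
               "9 samples")
  expect_error(detection_rule(0, ">", min_samples = 3, min_sample_fraction = 0.5),
               "exactly one")
})

test_that("short fragments are excluded from detection flagging", {
  cl <- toy_catalog()
  short_ids <- cl$events$event_id[!cl$events$detectable]
  expect_true(all(cl$events$length[match(short_ids, cl$events$event_id)] < 10))
  cov <- coverage_matrix(list(s1 = list()), cl)
  det <- flag_detection(cov, detection_rule(0, ">", min_samples = 1), cl)
  expect_true(all(is.na(det$detected[det$event_id %in% short_ids])))
})

test_that("border calls bracket the two coverage-ratio thresholds", {
  expect_equal(classify_border(9.5, 10, FALSE, TRUE), "possible_novel_donor_acceptor")
  expect_equal(classify_border(2, 10, TRUE, TRUE), "possible_IR")
  expect_equal(classify_border(9.5, 10, TRUE, TRUE), "ambiguous_IR")
  expect_equal(classify_border(0.5, 10, FALSE, TRUE), "possible_unprocessed")
  expect_equal(classify_border(5, 10, TRUE, FALSE), "unclassified")
  expect_error(classify_border(-1, 10, TRUE, TRUE), "negative")
})

test_that("border classification is a total function over its input space", {
  grid <- expand.grid(border = c(0, 0.5, 0.9, 1, 5, 9, 9.5, 10),
                      exon = c(1, 10), intron = c(TRUE, FALSE))
  calls <- classify_border(grid$border, grid$exon, grid$intron, TRUE)
  expect_true(all(calls %in% c("possible_novel_donor_acceptor", "possible_IR",
                               "ambiguous_IR", "possible_unprocessed")))
  expect_length(calls, nrow(grid))
})

test_that("catalog-level border classification finds the adjacent exon and intron", {
  cl <- toy_catalog()
  # donor border of single-exon region E and its intron
  b_id <- "chrT:553:648:+:border_donor"
  e_id <- "se:chrT:501:600:+"
  i_id <- "intron:chrT:601:700:+"
  lens <- sapply(c(b_id, e_id, i_id), function(id)
    cl$events$length[cl$events$event_id == id])
  apns <- stats::setNames(list(c(9.5, 9.5), c(10, 10), c(1, 1)),
                          c(b_id, e_id, i_id))
  cov0 <- coverage_matrix(list(s1 = list(), s2 = list()), cl)
  for (id in names(apns)) {
    cov0$apn[cov0$event_id == id] <- apns[[id]]
    cov0$read_count[cov0$event_id == id] <- round(apns[[id]] * lens[[id]])
  }
  res <- classify_borders(cl, cov0, detection_rule(0, ">", min_samples = 2))
  row <- res[res$event_id == b_id, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$call, "ambiguous_IR")
  expect_equal(row$exon_apn, 10)
  expect_true(row$intron_detected)
})

test_that("transcript summaries combine events length-weighted", {
  events <- data.frame(
    event_id = c("e1", "e2"), event_type = "single_exon",
    length = c(100L, 50L), freq_class = c("unique", "common"),
    is_multigene = FALSE, detectable = TRUE, stringsAsFactors = FALSE)
  txe <- data.frame(transcript_id = "t1", event_id = c("e1", "e2"))
  txs <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c", strand = "+")
  cl <- stub_catalog(events, txe, txs)
  cov <- fake_coverage(list(e1 = c(0.2), e2 = c(0)), list(e1 = 100L, e2 = 50L))
  su <- summarize_transcripts(cl, cov, detection_rule(0, ">", min_samples = 1))
  expect_equal(su$prop_detected, 0.5)
  expect_equal(su$total_reads, 20)
  expect_equal(su$total_length, 150L)
  expect_equal(su$mean_apn, 20 / 150)
  expect_equal(su$n_unique, 1L)
  expect_equal(su$n_unique_detected, 1L)

  # all events without reads: candidate for removal
  cov0 <- fake_coverage(list(e1 = 0, e2 = 0), list(e1 = 100L, e2 = 50L))
  su0 <- summarize_transcripts(cl, cov0, detection_rule(0, ">", min_samples = 1))
  expect_equal(su0$prop_detected, 0)
  expect_equal(su0$mean_apn, 0)

  # transcript with no unique events: proportion undefined
  events$freq_class <- "common"
  cl2 <- stub_catalog(events, txe, txs)
  su2 <- summarize_transcripts(cl2, cov, detection_rule(0, ">", min_samples = 1))
  expect_true(is.na(su2$prop_unique_detected))
})

test_that("transcript filtering applies the proportion threshold exactly", {
  events <- data.frame(event_id = paste0("e", 1:100), event_type = "single_exon",
                       length = 100L, freq_class = "common", is_multigene = FALSE,
                       detectable = TRUE, stringsAsFactors = FALSE)
  mk_summary <- function(prop) {
    txe <- data.frame(transcript_id = "t1", event_id = events$event_id)
    txs <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c", strand = "+")
    apns <- as.list(stats::setNames(c(rep(6, round(prop * 100)), rep(0, 100 - round(prop * 100))),
                                    events$event_id))
    cov <- fake_coverage(apns, as.list(stats::setNames(events$length, events$event_id)))
    summarize_transcripts(stub_catalog(events, txe, txs), cov,
                          detection_rule(5, ">=", min_samples = 1))
  }
  rule <- filter_rule(min_prop_events = 0.75, min_apn = 5, op = ">=")
  expect_equal(filter_transcripts(mk_summary(0.80), rule)$retained, "t1")
  expect_length(filter_transcripts(mk_summary(0.74), rule)$retained, 0L)
  # mismatched thresholds between summary and filter are refused
  expect_error(filter_transcripts(mk_summary(0.80), filter_rule(min_apn = 2)),
               "different APN threshold")
})

test_that("the three standard filter configurations are expressible verbatim", {
  toy <- toy_fixture(); cl <- toy_catalog()
  per <- list()
  for (s in 1:3) {
    sim <- simulate_reads(toy$annotation, coverage = 60, seed = 400 + s,
                          sample_id = paste0("s", s))
    per[[paste0("s", s)]] <- count_simulated_sample(sim, cl)
  }
  cov <- coverage_matrix(per, cl)
  configs <- list(
    list(d = detection_rule(0, ">", min_samples = 2), f = filter_rule(1.00, 0, ">")),
    list(d = detection_rule(0, ">", min_samples = 2), f = filter_rule(0.75, 0, ">")),
    list(d = detection_rule(5, ">=", min_samples = 2), f = filter_rule(0.75, 5, ">="))
  )
  for (cf in configs) {
    su <- summarize_transcripts(cl, cov, cf$d)
    fl <- filter_transcripts(su, cf$f)
    expect_true(is.character(fl$retained))
  }
  # at high coverage all three isoforms are retained at (APN > 0, 100%)
  fl1 <- filter_transcripts(summarize_transcripts(cl, cov, configs[[1]]$d),
                            configs[[1]]$f)
  expect_setequal(fl1$retained, c("iso1", "iso2", "iso3"))
})

test_that("raising either filter threshold never enlarges the retained set", {
  toy <- toy_fixture(); cl <- toy_catalog()
  per <- list()
  for (s in 1:2) {
    sim <- simulate_reads(toy$annotation,
                          expressed = data.frame(transcript_id = c("iso1", "iso2"),
                                                 level = c(1, 0.1)),
                          coverage = 30, seed = 500 + s, sample_id = paste0("s", s))
    per[[paste0("s", s)]] <- count_simulated_sample(sim, cl)
  }
  cov <- coverage_matrix(per, cl)
  apn_grid <- c(0, 0.2, 0.5, 1)
  prop_grid <- c(0.25, 0.5, 0.75, 1)
  retained <- matrix(list(), length(apn_grid), length(prop_grid))
  for (i in seq_along(apn_grid)) {
    su <- summarize_transcripts(cl, cov, detection_rule(apn_grid[i], ">", min_samples = 1))
    for (j in seq_along(prop_grid)) {
      fl <- filter_transcripts(su, filter_rule(prop_grid[j], apn_grid[i], ">"))
      retained[[i, j]] <- fl$retained
    }
  }
  for (i in seq_along(apn_grid)) for (j in seq_along(prop_grid)) {
    if (i > 1) expect_true(all(retained[[i, j]] %in% retained[[i - 1, j]]))
    if (j > 1) expect_true(all(retained[[i, j]] %in% retained[[i, j - 1]]))
  }
})

test_that("the reduced reference writes retained spliced sequences and index", {
  toy <- toy_fixture()
  fa <- tempfile(fileext = ".fa"); idx <- tempfile(fileext = ".tsv")
  suppressMessages(write_reduced_reference(c("iso1", "iso3"), toy$annotation, fa, idx))
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), 2L)
  expect_equal(unname(Biostrings::width(seqs)),
               c(nchar(spliced_sequence(toy$annotation, "iso1")),
                 nchar(spliced_sequence(toy$annotation, "iso3"))))
  tab <- utils::read.table(idx, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab[[1]], c("toygene", "toygene"))

  expect_warning(write_reduced_reference(character(0), toy$annotation, fa, idx), "empty")
  expect_error(write_reduced_reference("nope", toy$annotation, fa, idx), "absent")
})
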