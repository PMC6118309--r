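#' Replicate detection disagreement
#'
#' The percentage of transcripts in a reference detected in exactly one of
#' two replicates: `100 * (only_a + only_b) / total`, reported to two
#' decimals.
#'
#' @param total total transcripts in the reference
#' @param only_a detected only in replicate A
#' @param only_b detected only in replicate B
#' @return disagreement percent, rounded to 2 decimals
#' @export
detection_disagreement <- function(total, only_a, only_b) {
  if (any(c(total, only_a, only_b) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(total == 0)) stop("total must be positive", call. = FALSE)
  if (any(only_a + only_b > total)) stop("only_a + only_b exceeds total", call. = FALSE)
  round(100 * (only_a + only_b) / total, 2)
}

#' Bin transcripts by replicate TPM
#'
#' Bins use the minimum across replicates of log2(TPM): `no_expression`
#' (TPM = 0 in all replicates), `very_low` (min log-TPM 0-0.5), `low`
#' (0.5-2), `moderate` (2-4), `high` (4 or greater). Base-2 logs are the
#' default (an RPKM of 5 corresponds to a log-TPM of about 2 on this
#' scale); the base is configurable.
#'
#' @param tpm numeric matrix or data frame, transcripts x replicates
#'   (needs at least 2 replicate columns), or a numeric vector of one
#'   transcript's replicate TPMs
#' @param log_base logarithm base (default 2)
#' @return character vector of bins, one per transcript
#' @export
bin_by_tpm <- function(tpm, log_base = 2) {
  if (is.vector(tpm)) tpm <- matrix(tpm, nrow = 1)
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2) stop("need TPM from at least 2 replicates", call. = FALSE)
  if (any(tpm < 0)) stop("negative TPM", call. = FALSE)
  min_log <- apply(tpm, 1, function(v) min(log(v, base = log_base)))
  out <- rep("no_expression", nrow(tpm))
  pos <- apply(tpm, 1, function(v) any(v > 0))
  out[pos & min_log < 0.5] <- "very_low"
  out[pos & min_log >= 0.5 & min_log < 2] <- "low"
  out[pos & min_log >= 2 & min_log < 4] <- "moderate"
  out[pos & min_log >= 4] <- "high"
  zero_all <- apply(tpm, 1, function(v) all(v == 0))
  out[zero_all] <- "no_expression"
  out
}

#' Coefficient of variation, percent scale
#'
#' `100 * sd(x) / mean(x)` (sample standard deviation). Undefined (NA) when
#' the mean is zero.
#'
#' @param x numeric values (at least 2)
#' @return CV in percent
#' @export
cv_percent <- function(x) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Paired sign test on per-transcript CVs
#'
#' Scores "+" when the full-reference CV exceeds the reduced-reference CV
#' and "-" when it is smaller; ties are dropped. The p-value is the exact
#' two-sided binomial probability of the observed sign split under a fair
#' null.
#'
#' @param cv_full per-transcript CVs under the full reference
#' @param cv_reduced per-transcript CVs under the reduced reference,
#'   paired with `cv_full`
#' @return list with `n_plus`, `n_minus`, `n_ties`, `p_value`
#' @export
sign_test <- function(cv_full, cv_reduced) {
  if (length(cv_full) != length(cv_reduced)) stop("inputs must be paired", call. = FALSE)
  ok <- !is.na(cv_full) & !is.na(cv_reduced)
  d <- cv_full[ok] - cv_reduced[ok]
  n_plus <- sum(d > 0); n_minus <- sum(d < 0); n_ties <- sum(d == 0)
  if (n_plus + n_minus == 0) stop("all pairs are ties", call. = FALSE)
  p <- stats::binom.test(n_plus, n_plus + n_minus, p = 0.5)$p.value
  list(n_plus = n_plus, n_minus = n_minus, n_ties = n_ties, p_value = p)
}

#' Junction APN from a mapped-read count
#'
#' Converts an aligner's junction read count to the APN scale by dividing
#' by the expected junction size, twice the maximum allowable junction
#' overhang. Used to compare splice-aware aligner output with
#' catalog-mapped junction coverage.
#'
#' @param mapped_reads reads reported on the junction
#' @param max_overhang maximum allowable junction overhang in nt
#' @return APN
#' @export
junction_apn_from_count <- function(mapped_reads, max_overhang) {
  if (any(max_overhang <= 0)) stop("max_overhang must be positive", call. = FALSE)
  mapped_reads / (2 * max_overhang)
}

#' Bland-Altman agreement table for paired log-TPMs
#'
#' @param a,b paired per-transcript values (e.g., log-TPM of two replicates)
#' @return list with `table` (per-transcript `mean` and `difference`
#'   a - b), `bias` (mean difference), and `limits` (bias +/- 1.96 sd of
#'   the differences)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must be paired", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(
    table = data.frame(mean = (a + b) / 2, difference = d),
    bias = bias,
    limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  )
}

#' Read a quantifier abundance table
#'
#' @param path TSV with columns `transcript_id` and `TPM` (a header row is
#'   expected)
#' @return data frame with `transcript_id`, `tpm`
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  .stopifnot_cols(df, c("transcript_id", "tpm"), "abundance table")
  if (any(df$tpm < 0)) stop("negative TPM in ", path, call. = FALSE)
  df[, c("transcript_id", "tpm")]
}
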