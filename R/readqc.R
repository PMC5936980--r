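#' Mean read quality (error-probability averaged)
#'
#' Converts each Phred+33 symbol to an error probability, averages the
#' probabilities, and converts back to the Phred scale — the nanopore
#' pass/fail convention, which weights low-quality bases more heavily than
#' an arithmetic mean of Phred scores would.
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities.
#' @examples
#' mean_read_quality(strrep("0", 10)) # all-Q15 read -> 15
#' @export
mean_read_quality <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) abort("empty quality string")
    ints <- utf8ToInt(q) - 33L
    if (any(ints < 0)) abort("quality symbol below '!' (not Phred+33)")
    -10 * log10(mean(10^(-ints / 10)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads by quality and length
#'
#' A read passes when its error-averaged mean quality is at least `min_q`
#' and its length falls inside `length_window` (by default 80%–125% of the
#' expected amplicon length, generous because amplicon reads cluster tightly
#' around the template size). The returned tibble is the rejection log: each
#' failing read is annotated with the first rule that fired.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param min_q Mean-quality threshold (default 15).
#' @param amplicon_len Expected amplicon length used for the default window.
#' @param length_window Numeric `c(min_len, max_len)`; overrides
#'   `amplicon_len` when given.
#' @return The input tibble plus `mean_q`, `length`, `pass`, `reason`
#'   (`NA`, `"quality"` or `"length"`).
#' @export
filter_reads <- function(reads, min_q = 15, amplicon_len = 943,
                         length_window = NULL) {
  if (is.null(length_window)) length_window <- amplicon_len * c(0.8, 1.25)
  out <- dplyr::mutate(
    reads,
    mean_q = mean_read_quality(.data$qual),
    length = nchar(.data$seq),
    q_ok = .data$mean_q >= min_q,
    len_ok = .data$length >= length_window[1] & .data$length <= length_window[2],
    pass = .data$q_ok & .data$len_ok,
    reason = dplyr::case_when(!q_ok ~ "quality", !len_ok ~ "length",
                              TRUE ~ NA_character_)
  )
  dplyr::select(out, -"q_ok", -"len_ok")
}

#' Read-length N50
#'
#' The smallest length L such that reads of length >= L contain at least
#' half of all sequenced bases.
#'
#' @param lengths Integer vector of read lengths.
#' @return The N50 (integer).
#' @examples
#' compute_n50(c(2, 2, 2, 6)) # 6
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("N50 of an empty length set is undefined")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Run-level read statistics
#'
#' @param reads Read tibble.
#' @param min_q Quality threshold for the passing fraction (default 15).
#' @param assignments Optional demultiplexing assignments (see
#'   [scan_barcode()]) for per-sample read counts.
#' @return A classed list `"run_stats"`: `n_reads`, `mean_length`, `n50`,
#'   `frac_pass_q`, `per_sample` (or `NULL`), plus the length and quality
#'   vectors used (for plotting).
#' @export
run_stats <- function(reads, min_q = 15, assignments = NULL) {
  lens <- nchar(reads$seq)
  mq <- mean_read_quality(reads$qual)
  per_sample <- if (!is.null(assignments)) {
    dplyr::count(assignments, barcode_id = .data$barcode_id, name = "n_reads")
  }
  structure(list(
    n_reads = nrow(reads), mean_length = mean(lens), n50 = compute_n50(lens),
    frac_pass_q = mean(mq >= min_q), min_q = min_q,
    per_sample = per_sample, lengths = lens, mean_q = mq
  ), class = "run_stats")
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf(
    "run_stats: %d reads | mean length %.1f bp | N50 %d bp | %.1f%% >= Q%g\n",
    x$n_reads, x$mean_length, x$n50, 100 * x$frac_pass_q, x$min_q))
  if (!is.null(x$per_sample)) {
    cat(sprintf("  %d demultiplexed bins\n", nrow(x$per_sample)))
  }
  invisible(x)
}

#' @export
glance.run_stats <- function(x, ...) {
  tibble(n_reads = x$n_reads, mean_length = x$mean_length, n50 = x$n50,
         frac_pass_q = x$frac_pass_q)
}
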