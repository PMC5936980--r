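#' Align a read against an allele amplicon
#'
#' Semi-global unit-cost edit-distance alignment with the allele anchored:
#' the allele amplicon is aligned end to end while the read's flanks
#' (adapter/barcode remnants) overhang for free. The traceback is projected
#' onto allele columns, which is the representation the consensus caller
#' consumes. Tie-breaking in the traceback prefers match > substitution >
#' deletion > insertion (read perspective) and is deterministic.
#'
#' @param read Read sequence (string), or a one-row read tibble.
#' @param allele One row of an allele set, or a plain reference string.
#' @return A classed list `"read_alignment"`: `allele`, `distance`, `n_sub`,
#'   `n_del`, `n_ins` (read perspective), `read_start`/`read_end` (0-based
#'   half-open aligned span on the read), `allele_cols` (one char per allele
#'   column: read base or `"-"`), `insertions` (tibble `pos` = 0-based allele
#'   column the inserted read bases precede, `seq`), `sub_pos` (0-based
#'   allele columns with substitutions).
#' @export
align_read <- function(read, allele) {
  if (is.data.frame(read)) read <- read$seq[1]
  allele_name <- NA_character_
  if (is.data.frame(allele)) {
    allele_name <- allele$allele[1]
    allele <- allele$seq[1]
  }
  if (is.na(read) || !nzchar(read)) abort("empty read")
  a <- .sg_align_cpp(allele, read, TRUE)
  structure(list(
    allele = allele_name, distance = a$distance,
    n_sub = a$n_sub, n_del = a$n_gap_ref, n_ins = a$n_gap_query,
    read_start = a$ref_start, read_end = a$ref_end,
    allele_cols = a$q_cols,
    insertions = tibble(pos = a$q_ins_pos, seq = as.character(a$q_ins_seq)),
    sub_pos = a$q_sub_pos
  ), class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("read_alignment vs %s: distance %d (%d sub, %d del, %d ins)\n",
              if (is.na(x$allele)) "<seq>" else x$allele,
              x$distance, x$n_sub, x$n_del, x$n_ins))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distance of each read (rows of the result are alleles) with the allele
# anchored; reads as given, no orientation handling.
.allele_distance_matrix <- function(allele_seqs, read_seqs) {
  .sg_distance_matrix_cpp(allele_seqs, read_seqs, TRUE)
}

#' Trim adapter/barcode tails and orient reads
#'
#' Locates the left affix (adapter + barcode) near the read start and the
#' right affix near the read end by semi-global alignment, trimming through
#' the match when it scores at or below `max_edit_frac` of the affix length.
#' Orientation is decided by whichever of the read and its reverse
#' complement carries the better left-affix match, so minus-strand reads
#' come back plus-oriented.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param left_affix,right_affix Expected flanking sequences (e.g.
#'   `paste0(tails$left, barcode)` and `paste0(revcomp(barcode),
#'   tails$right)`).
#' @param max_edit_frac Maximum edit fraction of the affix length for a
#'   trim (default 0.25).
#' @return The input tibble with `seq`/`qual` oriented and trimmed, plus
#'   `orientation`, `left_trimmed`, `right_trimmed`.
#' @export
trim_tails <- function(reads, left_affix, right_affix, max_edit_frac = 0.25) {
  slack <- 30L
  wl <- nchar(left_affix) + slack
  wr <- nchar(right_affix) + slack
  max_l <- floor(max_edit_frac * nchar(left_affix))
  max_r <- floor(max_edit_frac * nchar(right_affix))
  one <- function(seq, qual) {
    n <- nchar(seq)
    win <- function(s) substr(s, 1, min(wl, nchar(s)))
    rc <- revcomp(seq)
    d_fwd <- .sg_distance_cpp(left_affix, win(seq), TRUE)
    d_rev <- .sg_distance_cpp(left_affix, win(rc), TRUE)
    orientation <- if (d_rev < d_fwd) "-" else "+"
    if (orientation == "-") {
      seq <- rc
      qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
    }
    lt <- FALSE; rt <- FALSE
    al <- .sg_align_cpp(left_affix, substr(seq, 1, min(wl, n)), TRUE)
    if (al$distance <= max_l) {
      seq <- substr(seq, al$ref_end + 1, nchar(seq))
      qual <- substr(qual, al$ref_end + 1, nchar(qual))
      lt <- TRUE
    }
    n <- nchar(seq)
    off <- max(0L, n - wr)
    ar <- .sg_align_cpp(right_affix, substr(seq, off + 1, n), TRUE)
    if (ar$distance <= max_r) {
      seq <- substr(seq, 1, off + ar$ref_start)
      qual <- substr(qual, 1, off + ar$ref_start)
      rt <- TRUE
    }
    list(seq = seq, qual = qual, orientation = orientation,
         left_trimmed = lt, right_trimmed = rt)
  }
  res <- purrr::map2(reads$seq, reads$qual, one)
  dplyr::mutate(
    reads,
    seq = purrr::map_chr(res, "seq"),
    qual = purrr::map_chr(res, "qual"),
    orientation = purrr::map_chr(res, "orientation"),
    left_trimmed = purrr::map_lgl(res, "left_trimmed"),
    right_trimmed = purrr::map_lgl(res, "right_trimmed")
  )
}
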