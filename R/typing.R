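# ---- internal helpers -------------------------------------------------------

# Map 0-based allele columns to exon-local coordinates (exon number and
# 1-based position within the exon); intron/flank columns get NA.
.col_exon_info <- function(allele_row, cols0) {
  exon <- rep(NA_integer_, length(cols0))
  pos <- rep(NA_integer_, length(cols0))
  in2 <- cols0 >= allele_row$exon2_start & cols0 < allele_row$exon2_end
  in3 <- cols0 >= allele_row$exon3_start & cols0 < allele_row$exon3_end
  exon[in2] <- 2L; pos[in2] <- cols0[in2] - allele_row$exon2_start + 1L
  exon[in3] <- 3L; pos[in3] <- cols0[in3] - allele_row$exon3_start + 1L
  list(exon = exon, pos = pos)
}

# Column-wise consensus over the reads assigned to one allele. Every read
# alignment projects onto all L allele columns (the allele is anchored), so
# coverage is uniform; per column the majority among {A,C,G,T,-} wins, ties
# resolved toward the reference base. Insertions are retained only when
# carried by more than half of the reads at that junction.
.consensus <- function(aligns, idx, allele_row) {
  L <- nchar(allele_row$seq)
  ref <- strsplit(allele_row$seq, "")[[1]]
  codes <- c("A", "C", "G", "T", "-")
  n <- length(idx)
  if (n == 0) {
    return(list(cons = ref, second_frac = rep(0, L), second_count = rep(0L, L),
                n = 0L, ins = tibble(pos = integer(), seq = character(),
                                     support = integer())))
  }
  counts <- numeric(5L * L)
  ins_pos_all <- integer(0)
  ins_seq_all <- character(0)
  for (k in seq_len(n)) {
    a <- aligns[[idx[k]]]
    enc <- a$enc %||% .encode_cols(a$q_cols, codes)
    counts <- counts + tabulate(enc, nbins = 5L * L)
    keep <- a$q_ins_pos > 0 & a$q_ins_pos < L
    if (any(keep)) {
      ins_pos_all <- c(ins_pos_all, a$q_ins_pos[keep])
      ins_seq_all <- c(ins_seq_all, as.character(a$q_ins_seq)[keep])
    }
  }
  cm <- matrix(counts, nrow = 5L)
  ref_idx <- match(ref, codes)
  # majority with tie toward reference: a half-count bonus on the reference
  # row wins exact ties without overtaking any strictly larger count
  cmb <- cm
  cmb[cbind(ref_idx, seq_len(L))] <- cmb[cbind(ref_idx, seq_len(L))] + 0.5
  cons_idx <- max.col(t(cmb), ties.method = "first")
  cons <- codes[cons_idx]
  m2 <- cm
  m2[cbind(cons_idx, seq_len(L))] <- -1
  second <- m2[cbind(max.col(t(m2), ties.method = "first"), seq_len(L))]
  ins <- tibble(pos = integer(), seq = character(), support = integer())
  if (length(ins_pos_all)) {
    support <- table(ins_pos_all)
    keep_pos <- as.integer(names(support))[support > n / 2]
    if (length(keep_pos)) {
      ins <- tibble(
        pos = keep_pos,
        seq = vapply(keep_pos, function(p) {
          names(sort(table(ins_seq_all[ins_pos_all == p]),
                     decreasing = TRUE))[1]
        }, character(1)),
        support = as.integer(support[as.character(keep_pos)])
      )
    }
  }
  list(cons = cons, second_frac = second / n, second_count = as.integer(second),
       n = n, ins = ins)
}

# Consensus-vs-reference differences, with exon restriction, optional column
# masking, and the heterozygosity guard: a column whose consensus matches the
# reference but carries a strong minority vote is an unexplained polymorphism
# under the pair hypothesis and counts as a mismatch. Two clauses: the
# moderate one (>= het_min_frac of reads, >= het_min_count reads) for
# well-covered members, and a near-balanced one (>= 0.4 of reads, >= 2 reads)
# so a 50/50 split is caught even at minimal depth.
.member_mismatches <- function(consobj, allele_row, mask_cols = integer(),
                               het_min_frac = 0.3, het_min_count = 5) {
  ref <- strsplit(allele_row$seq, "")[[1]]
  L <- length(ref)
  cons <- consobj$cons
  type <- rep(NA_character_, L)
  type[cons == "-"] <- "del"
  type[cons != "-" & cons != ref] <- "sub"
  sf <- consobj$second_frac; sc <- consobj$second_count
  het <- cons == ref &
    ((sf >= het_min_frac & sc >= het_min_count) |
       (sf >= pmax(0.4, het_min_frac) & sc >= 2))
  type[het] <- "het_signal"
  cols0 <- which(!is.na(type)) - 1L
  rows <- tibble(col = cols0, type = type[cols0 + 1L], edits = 1L)
  if (nrow(consobj$ins)) {
    rows <- dplyr::bind_rows(rows, tibble(
      col = consobj$ins$pos, type = "ins", edits = nchar(consobj$ins$seq)))
  }
  if (nrow(rows)) {
    ei <- .col_exon_info(allele_row, rows$col)
    rows$exon <- ei$exon; rows$pos <- ei$pos
    rows$in_exon <- !is.na(rows$exon)
    rows$masked <- rows$col %in% mask_cols
  } else {
    rows$exon <- integer(); rows$pos <- integer()
    rows$in_exon <- logical(); rows$masked <- logical()
  }
  rows
}

.consensus_seq <- function(consobj) {
  s <- consobj$cons
  s[s == "-"] <- ""
  if (nrow(consobj$ins)) {
    for (k in seq_len(nrow(consobj$ins))) {
      p <- consobj$ins$pos[k] + 1L
      s[p] <- paste0(consobj$ins$seq[k], s[p])
    }
  }
  paste(s, collapse = "")
}

# 0-based columns of `allele` excluded by a repeat mask
# (tibble allele/start/end, 0-based half-open).
.mask_cols <- function(mask, allele) {
  if (is.null(mask)) return(integer())
  m <- mask[mask$allele == allele, , drop = FALSE]
  if (!nrow(m)) return(integer())
  unlist(lapply(seq_len(nrow(m)), function(k) seq.int(m$start[k], m$end[k] - 1L)))
}

# Pair scoring against cached alignments. `aligns` is a named list (by
# allele) of per-read alignment lists; `dists` a matrix alleles x reads.
.score_pair_impl <- function(aligns, dists, alleles, a, b, minor_fraction,
                             het_min_frac, het_min_count, mask = NULL,
                             demoted_from = NULL) {
  ord <- allele_name_order(c(a, b))
  a2 <- c(a, b)[ord][1]; b2 <- c(a, b)[ord][2]
  a <- a2; b <- b2
  row_a <- alleles[alleles$allele == a, ]
  row_b <- alleles[alleles$allele == b, ]
  n <- ncol(dists)
  if (a == b) {
    idx_a <- seq_len(n); idx_b <- idx_a; unas <- 0L
  } else {
    d_a <- dists[a, ]; d_b <- dists[b, ]
    idx_a <- which(d_a < d_b); idx_b <- which(d_b < d_a)
    unas <- n - length(idx_a) - length(idx_b)
    assignable <- length(idx_a) + length(idx_b)
    if (assignable == 0 ||
        min(length(idx_a), length(idx_b)) < minor_fraction * assignable) {
      maj <- if (length(idx_a) >= length(idx_b)) a else b
      return(.score_pair_impl(aligns, dists, alleles, maj, maj,
                              minor_fraction, het_min_frac, het_min_count,
                              mask, demoted_from = c(a, b)))
    }
  }
  cons_a <- .consensus(aligns[[a]], idx_a, row_a)
  mm_a <- .member_mismatches(cons_a, row_a, .mask_cols(mask, a),
                             het_min_frac, het_min_count)
  if (a == b) {
    cons_b <- cons_a; mm_b <- mm_a
  } else {
    cons_b <- .consensus(aligns[[b]], idx_b, row_b)
    mm_b <- .member_mismatches(cons_b, row_b, .mask_cols(mask, b),
                               het_min_frac, het_min_count)
  }
  count <- function(mm) sum(mm$edits[mm$in_exon & !mm$masked])
  positions <- dplyr::bind_rows(
    dplyr::mutate(mm_a, member = "a", allele = a, .before = 1),
    dplyr::mutate(mm_b, member = "b", allele = b, .before = 1)
  )
  structure(list(
    a = a, b = b, n_reads = n,
    n_a = length(idx_a), n_b = length(idx_b), n_unassigned = unas,
    mismatch_a = count(mm_a), mismatch_b = count(mm_b),
    total = count(mm_a) + count(mm_b),
    support = if (a == b) n else min(length(idx_a), length(idx_b)),
    demoted = !is.null(demoted_from), demoted_from = demoted_from,
    positions = positions,
    consensus_a = .consensus_seq(cons_a), consensus_b = .consensus_seq(cons_b)
  ), class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("pair_score (%s, %s): total %d mismatches (%d + %d), reads %d/%d (+%d unassigned)%s\n",
              x$a, x$b, x$total, x$mismatch_a, x$mismatch_b,
              x$n_a, x$n_b, x$n_unassigned,
              if (x$demoted) sprintf(" [demoted from (%s, %s)]",
                                     x$demoted_from[1], x$demoted_from[2]) else ""))
  invisible(x)
}

.read_seqs <- function(reads) if (is.data.frame(reads)) reads$seq else reads

# plus-orient sequences against a probe reference (better-scoring strand wins)
.orient_seqs <- function(seqs, probe) {
  rc <- revcomp(seqs)
  d_fwd <- .sg_distance_matrix_cpp(probe, seqs, TRUE)[1, ]
  d_rev <- .sg_distance_matrix_cpp(probe, rc, TRUE)[1, ]
  ifelse(d_rev < d_fwd, rc, seqs)
}

# flat 5 x L encoding of a projected column string, for fast vote tallying
.encode_cols <- function(q_cols, codes = c("A", "C", "G", "T", "-")) {
  m <- match(strsplit(q_cols, "")[[1]], codes)
  okc <- which(!is.na(m))
  (okc - 1L) * 5L + m[okc]
}

.build_aligns <- function(alleles, allele_names, seqs) {
  setNames(lapply(allele_names, function(a) {
    lapply(.sg_align_to_refs_cpp(alleles$seq[alleles$allele == a], seqs, TRUE),
           function(al) { al$enc <- .encode_cols(al$q_cols); al })
  }), allele_names)
}

# ---- exported operations ----------------------------------------------------

#' Shortlist candidate alleles by read votes
#'
#' Each read votes for its minimum-edit-distance allele(s); alleles are
#' ranked by votes and the top `k` are returned, together with any further
#' allele whose vote count is within 10% of the k-th.
#'
#' @param reads Read tibble or character vector of sequences (oriented,
#'   tails may be present).
#' @param alleles Allele set.
#' @param k Shortlist size (>= 2).
#' @param .dists Precomputed allele-by-read distance matrix (internal reuse).
#' @return Tibble `allele`, `votes`, ranked.
#' @export
shortlist_alleles <- function(reads, alleles, k = 10, .dists = NULL) {
  seqs <- .read_seqs(reads)
  if (length(seqs) == 0) abort("no reads to shortlist from")
  stopifnot(k >= 2)
  d <- .dists %||% {
    m <- .allele_distance_matrix(alleles$seq, seqs)
    rownames(m) <- alleles$allele
    m
  }
  votes <- rowSums(apply(d, 2, function(col) col == min(col)))
  tb <- tibble(allele = rownames(d), votes = as.numeric(votes)) |>
    dplyr::arrange(dplyr::desc(.data$votes), .data$allele)
  if (nrow(tb) <= k) return(tb)
  vk <- tb$votes[k]
  tb[seq_len(nrow(tb)) <= k | tb$votes >= 0.9 * vk, ]
}

#' Build a consensus from reads against one allele
#'
#' Aligns the reads to the allele, projects each alignment onto allele
#' columns, and majority-votes per column over \{A, C, G, T, gap\}; ties go
#' to the reference base, a gap majority deletes the column, and insertions
#' are kept only when supported by more than half of the reads.
#'
#' @param reads Read tibble or sequence vector (>= 1 read).
#' @param allele One row of an allele set.
#' @param auto_orient Flip reads whose reverse complement aligns better.
#' @return List: `seq` (consensus string), `columns` (per-column consensus
#'   char and minority-vote fraction), `insertions`.
#' @export
build_consensus <- function(reads, allele, auto_orient = TRUE) {
  seqs <- .read_seqs(reads)
  stopifnot(length(seqs) >= 1, nrow(allele) == 1)
  if (auto_orient) seqs <- .orient_seqs(seqs, allele$seq)
  aligns <- .sg_align_to_refs_cpp(allele$seq, seqs, TRUE)
  co <- .consensus(aligns, seq_along(seqs), allele)
  list(
    seq = .consensus_seq(co),
    columns = tibble(col = seq_along(co$cons) - 1L, consensus = co$cons,
                     minority_frac = co$second_frac),
    insertions = co$ins
  )
}

#' Score an allele pair against a read set
#'
#' Implements the mismatch-minimisation scoring at the heart of allele-pair
#' genotyping: each read is assigned to the nearer pair member by edit
#' distance (ties are unassignable and excluded from consensus), a consensus
#' is built per member, and the pair's score is the total number of
#' consensus-vs-reference differences restricted to exon 2+3 columns. A pair
#' whose minor member attracts fewer than `minor_fraction` of the assignable
#' reads is demoted to the homozygous pair of the majority member (allele
#' dropout guard); a consensus column matching the reference but carrying a
#' strong minority vote counts as an unexplained polymorphism (heterozygosity
#' guard — see the package vignette).
#'
#' @param reads Read tibble or sequence vector.
#' @param alleles Allele set containing `a` and `b`.
#' @param a,b Allele names (unordered; `score_pair(r, A, a, b)` equals
#'   `score_pair(r, A, b, a)`).
#' @param minor_fraction Dropout-demotion threshold (default 0.2).
#' @param het_min_frac,het_min_count Heterozygosity-guard thresholds.
#' @param mask Optional repeat mask (tibble `allele`, `start`, `end`;
#'   0-based half-open allele coordinates) whose exon columns are excluded
#'   from the mismatch count.
#' @param auto_orient Flip reads whose reverse complement aligns better
#'   (default TRUE).
#' @return A `"pair_score"`: members, read partition, per-member mismatch
#'   counts and positions, total, support.
#' @export
score_pair <- function(reads, alleles, a, b, minor_fraction = 0.2,
                       het_min_frac = 0.3, het_min_count = 5, mask = NULL,
                       auto_orient = TRUE) {
  seqs <- .read_seqs(reads)
  if (length(seqs) == 0) abort("no reads to score")
  stopifnot(all(c(a, b) %in% alleles$allele))
  if (auto_orient) seqs <- .orient_seqs(seqs, alleles$seq[alleles$allele == a])
  names <- unique(c(a, b))
  aligns <- .build_aligns(alleles, names, seqs)
  dists <- matrix(
    vapply(names, function(nm) {
      vapply(aligns[[nm]], function(al) al$distance, numeric(1))
    }, numeric(length(seqs))),
    nrow = length(names), byrow = TRUE, dimnames = list(names, NULL))
  .score_pair_impl(aligns, dists, alleles, a, b, minor_fraction,
                   het_min_frac, het_min_count, mask)
}

#' Re-score an allele pair with repeat columns masked
#'
#' Identical to [score_pair()] but exon columns inside the masked intervals
#' are excluded from the mismatch count — the automated counterpart of
#' manually discounting systematic repeat-tract errors when adjudicating a
#' flagged call. The masked total is never larger than the unmasked one.
#'
#' @inheritParams score_pair
#' @param mask Repeat mask (required here).
#' @return A `"pair_score"`.
#' @export
rescore_masked <- function(reads, alleles, a, b, mask, minor_fraction = 0.2,
                           het_min_frac = 0.3, het_min_count = 5,
                           auto_orient = TRUE) {
  stopifnot(!is.null(mask))
  score_pair(reads, alleles, a, b, minor_fraction, het_min_frac,
             het_min_count, mask = mask, auto_orient = auto_orient)
}

#' Call a diploid genotype from one sample's reads
#'
#' The full engine: orient reads, shortlist candidate alleles by votes,
#' enumerate all unordered allele pairs (self-pairs included) over the
#' shortlist, score each with [score_pair()] semantics, and rank by total
#' mismatches (ascending), then balanced read support (descending), then
#' pair name. The best pair is the call; G-group mapping is applied to the
#' reported names; a call whose minimum total exceeds zero is annotated for
#' manual review and ships its full ranked list, with recurrent mismatch
#' positions summarised as hotspots.
#'
#' @param reads Read tibble or sequence vector for one sample.
#' @param alleles Allele set.
#' @param ggroups Optional G-group map from [build_ggroups()].
#' @param k Shortlist size.
#' @param min_depth Minimum read count (default 20); calls below it are
#'   refused unless `allow_low_depth = TRUE`.
#' @param allow_low_depth Override the depth refusal.
#' @param auto_orient Flip reads whose reverse complement aligns better
#'   (default TRUE).
#' @param repeat_mask Optional STR mask for hotspot annotation (not applied
#'   to scoring; see [rescore_masked()]).
#' @param sample_id Optional label carried into the call.
#' @inheritParams score_pair
#' @return A `"genotype_call"`; see [tidy.genotype_call()] /
#'   [glance.genotype_call()].
#' @export
call_genotype <- function(reads, alleles, ggroups = NULL, k = 10,
                          min_depth = 20, allow_low_depth = FALSE,
                          minor_fraction = 0.2, het_min_frac = 0.3,
                          het_min_count = 5, auto_orient = TRUE,
                          repeat_mask = NULL, sample_id = NULL) {
  seqs <- .read_seqs(reads)
  n <- length(seqs)
  if (n < min_depth && !allow_low_depth) {
    abort(sprintf(
      "only %d reads (< min_depth = %d); pass allow_low_depth = TRUE to override",
      n, min_depth))
  }
  if (n == 0) abort("no reads")
  if (auto_orient) seqs <- .orient_seqs(seqs, alleles$seq[1])
  dists <- .allele_distance_matrix(alleles$seq, seqs)
  rownames(dists) <- alleles$allele
  sl <- shortlist_alleles(seqs, alleles, k = max(2, min(k, nrow(alleles))),
                          .dists = dists)
  cand <- sl$allele
  aligns <- .build_aligns(alleles, cand, seqs)
  combos <- tidyr::expand_grid(i = seq_along(cand), j = seq_along(cand)) |>
    dplyr::filter(.data$i <= .data$j)
  scores <- purrr::map2(combos$i, combos$j, function(i, j) {
    .score_pair_impl(aligns, dists[cand, , drop = FALSE], alleles,
                     cand[i], cand[j], minor_fraction,
                     het_min_frac, het_min_count)
  })
  tb <- tibble(
    a = purrr::map_chr(scores, "a"), b = purrr::map_chr(scores, "b"),
    total = purrr::map_int(scores, "total"),
    support = purrr::map_dbl(scores, "support"),
    mismatch_a = purrr::map_int(scores, "mismatch_a"),
    mismatch_b = purrr::map_int(scores, "mismatch_b"),
    n_a = purrr::map_int(scores, "n_a"), n_b = purrr::map_int(scores, "n_b"),
    n_unassigned = purrr::map_int(scores, "n_unassigned"),
    demoted = purrr::map_lgl(scores, "demoted"),
    detail = scores
  )
  # demotion can create duplicate self-pairs; keep the best-scoring instance,
  # preferring a non-demoted one on ties
  tb <- tb |>
    dplyr::arrange(.data$total, dplyr::desc(.data$support), .data$demoted,
                   .data$a, .data$b) |>
    dplyr::distinct(.data$a, .data$b, .keep_all = TRUE)
  tb <- dplyr::mutate(tb,
                      reported_a = ggroup_of(.data$a, ggroups),
                      reported_b = ggroup_of(.data$b, ggroups),
                      rank = dplyr::row_number())
  best <- tb[1, ]
  cobest <- tb$total == best$total & tb$support == best$support
  call <- structure(list(
    sample_id = sample_id,
    pairs = tb,
    best = list(allele_a = best$a, allele_b = best$b,
                reported_a = best$reported_a, reported_b = best$reported_b,
                total = best$total, support = best$support),
    zygosity = if (best$a == best$b) "homozygous" else "heterozygous",
    ambiguous = sum(cobest) > 1,
    manual_review = best$total > 0,
    depth = n,
    per_allele_depth = c(best$n_a, best$n_b),
    shortlist = sl,
    hotspots = NULL
  ), class = "genotype_call")
  call$hotspots <- find_hotspots(call, repeat_mask = repeat_mask,
                                 alleles = alleles)
  call
}

#' Recurrent mismatch-position (hotspot) report
#'
#' Positions at which mismatches recur across at least `min_share` of the
#' top `top_n` ranked pairs are systematic rather than pair-specific —
#' the signature of a sequencing artifact. Positions falling inside the
#' repeat mask are labelled repeat-associated. Coordinates are 1-based and
#' exon-local.
#'
#' @param x A `"genotype_call"` or a list of `"pair_score"` objects.
#' @param repeat_mask Optional STR mask (tibble `allele`, `start`, `end`).
#' @param alleles Allele set; required when `repeat_mask` is given (for
#'   coordinate conversion).
#' @param top_n Number of top-ranked pairs examined (default 5).
#' @param min_share Recurrence threshold (default 0.5).
#' @return Tibble `exon`, `pos`, `n_pairs`, `share`, `repeat_associated`.
#' @export
find_hotspots <- function(x, repeat_mask = NULL, alleles = NULL, top_n = 5,
                          min_share = 0.5) {
  scores <- if (inherits(x, "genotype_call")) x$pairs$detail else x
  if (length(scores) == 0) abort("no pair scores to analyse")
  scores <- head(scores, top_n)
  per_pair <- purrr::map(scores, function(s) {
    dplyr::distinct(dplyr::filter(s$positions, .data$in_exon),
                    .data$exon, .data$pos)
  })
  tallied <- dplyr::bind_rows(per_pair) |>
    dplyr::count(.data$exon, .data$pos, name = "n_pairs") |>
    dplyr::mutate(share = .data$n_pairs / length(scores)) |>
    dplyr::filter(.data$share >= min_share) |>
    dplyr::arrange(.data$exon, .data$pos)
  tallied$repeat_associated <- rep(FALSE, nrow(tallied))
  if (!is.null(repeat_mask) && nrow(tallied)) {
    if (is.null(alleles)) abort("'alleles' is required to interpret 'repeat_mask'")
    mrows <- dplyr::inner_join(repeat_mask, alleles, by = "allele",
                               suffix = c("", ".allele"))
    covered <- dplyr::bind_rows(lapply(seq_len(nrow(mrows)), function(k) {
      i <- .col_exon_info(mrows[k, ], seq.int(mrows$start[k], mrows$end[k] - 1L))
      tibble(exon = i$exon, pos = i$pos)
    })) |> dplyr::filter(!is.na(.data$exon)) |> dplyr::distinct()
    tallied$repeat_associated <- purrr::map2_lgl(
      tallied$exon, tallied$pos,
      function(e, p) any(covered$exon == e & covered$pos == p))
  }
  tallied
}

#' Re-adjudicate a flagged call with repeat-masked rescoring
#'
#' Rescored totals (masked columns excluded) are computed for the top
#' `top_n` ranked pairs and the list re-ranked, automating the manual
#' least-mismatch adjudication of repeat-artifact calls.
#'
#' @param call A `"genotype_call"`.
#' @param reads,alleles The sample's reads and allele set.
#' @param mask Repeat mask.
#' @param top_n Pairs to rescore.
#' @return Tibble of rescored pairs, ranked by masked total then support.
#' @export
adjudicate_call <- function(call, reads, alleles, mask, top_n = 5) {
  top <- head(call$pairs, top_n)
  rescored <- purrr::map2(top$a, top$b, function(a, b) {
    rescore_masked(reads, alleles, a, b, mask)
  })
  tibble(
    a = purrr::map_chr(rescored, "a"), b = purrr::map_chr(rescored, "b"),
    masked_total = purrr::map_int(rescored, "total"),
    unmasked_total = top$total,
    support = purrr::map_dbl(rescored, "support")
  ) |>
    dplyr::arrange(.data$masked_total, dplyr::desc(.data$support),
                   .data$a, .data$b)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf(
    "genotype_call%s: %s / %s (%s)%s%s\n  depth %d | best total %d mismatches | support %g\n",
    if (!is.null(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
    x$best$reported_a, x$best$reported_b, x$zygosity,
    if (x$ambiguous) " AMBIGUOUS" else "",
    if (x$manual_review) " MANUAL-REVIEW" else "",
    x$depth, x$best$total, x$best$support))
  invisible(x)
}

#' Tidy a genotype call into its ranked pair table
#'
#' @param x A `"genotype_call"`.
#' @param ... Unused.
#' @return Tibble of ranked pairs (one row per scored pair).
#' @export
tidy.genotype_call <- function(x, ...) {
  dplyr::select(x$pairs, "rank", "a", "b", "reported_a", "reported_b",
                "total", "support", "mismatch_a", "mismatch_b",
                "n_a", "n_b", "n_unassigned", "demoted")
}

#' One-row summary of a genotype call
#'
#' @param x A `"genotype_call"`.
#' @param ... Unused.
#' @return One-row tibble: sample, reported alleles, zygosity, flags, depth.
#' @export
glance.genotype_call <- function(x, ...) {
  tibble(
    sample_id = x$sample_id %||% NA_character_,
    allele_a = x$best$reported_a, allele_b = x$best$reported_b,
    zygosity = x$zygosity, total_mismatches = x$best$total,
    ambiguous = x$ambiguous, manual_review = x$manual_review,
    depth = x$depth
  )
}
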