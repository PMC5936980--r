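#' Nanopore-style error model
#'
#' Per-base event rates for the read simulator, defaulting to an R9-era 2D
#' profile: 7.3% total error split as 3.5% deletions (the dominant and most
#' consequential error mode on this platform), 2.8% substitutions and 1.0%
#' insertions. Deletion probability is multiplied by
#' `repeat_del_multiplier` inside annotated short-tandem-repeat intervals,
#' reproducing the elevated indel rate seen in tracts such as (GA)3.
#' Per-read mean basecall quality is drawn from
#' Normal(`read_q_mean`, `read_q_sd`) truncated to \[2, 30\].
#'
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   probabilities.
#' @param repeat_del_multiplier Deletion-rate factor inside STR masks (>= 1).
#' @param read_q_mean,read_q_sd Per-read mean-quality distribution (Phred).
#' @return A classed list `"error_model"`.
#' @export
error_model <- function(p_sub = 0.028, p_ins = 0.010, p_del = 0.035,
                        repeat_del_multiplier = 3, read_q_mean = 12,
                        read_q_sd = 3) {
  stopifnot(
    p_sub >= 0, p_ins >= 0, p_del >= 0, p_sub + p_del <= 1, p_ins <= 1,
    repeat_del_multiplier >= 1, p_del * repeat_del_multiplier <= 1
  )
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 repeat_del_multiplier = repeat_del_multiplier,
                 read_q_mean = read_q_mean, read_q_sd = read_q_sd),
            class = "error_model")
}

# Fixed synthetic adapter tails flanking the barcodes (36 bp each side, so
# that with 24 bp barcodes a 943 bp amplicon becomes a 1,063 bp template).
#' Default synthetic adapter tails
#' @return List with `left` and `right` 36 bp adapter sequences.
#' @export
default_tails <- function() {
  list(left = "AATGTACTTCGTTCAGTTACGTATTGCTAAGGTTAA",
       right = "GCAATACGTAACTGAACGAAGTACATTCCTGGTAAC")
}

#' Synthetic HLA-B-like allele reference set
#'
#' Generates a deterministic fixture of 943 bp amplicon alleles emulating the
#' HLA-B exon 2 + 3 amplicon layout: primer footprints at both ends, a 270 bp
#' exon 2 (amplicon coordinates \[60, 330)), a 276 bp exon 3 (\[560, 836)),
#' and a (GA)3-containing tract at exon 2 nucleotides 128–137 (1-based within
#' the exon) with the deletion-prone heterozygous A/G site at exon 2
#' nucleotide 133. Allele `i` carries three private substitutions in exon 3,
#' so any two alleles differ at >= 6 exon positions; the designated
#' `ga_carrier` allele additionally carries G at the tract site, turning the
#' tract into a deletion-prone G-run. Optional intron twins duplicate an
#' allele with a single intron substitution, giving identical exon 2+3
#' sequences (a G-group pair).
#'
#' @param n Number of primary alleles (2–28).
#' @param seed Seed for the background sequence (fixture is deterministic).
#' @param ga_carrier Index of the allele given G at the tract het site, or
#'   `NULL` for none.
#' @param intron_twins Integer indices of alleles to duplicate with an
#'   intron-only difference (named `B*<g>:01:02`).
#' @return An `allele_set` tibble with attributes `"str_mask"` (tibble
#'   `allele`, `start`, `end`, 0-based half-open amplicon coordinates of the
#'   tract) and `"primers"` (the matching synthetic [primer_pair()]).
#' @export
synthetic_allele_set <- function(n = 6, seed = 42, ga_carrier = 2,
                                 intron_twins = integer(0)) {
  stopifnot(n >= 2, n <= 28, all(intron_twins %in% seq_len(n)))
  e2s <- 60L; e2e <- 330L; e3s <- 560L; e3e <- 836L; amp_len <- 943L
  base <- with_seed_if(seed, paste(sample(c("A", "C", "G", "T"), amp_len,
                                          replace = TRUE), collapse = ""))
  chars <- strsplit(base, "")[[1]]
  # plant the GA tract: exon2-local 1-based 128..137 (A at nt 133)
  tract_start <- e2s + 127L            # 0-based amplicon coord
  substr(base, tract_start + 1, tract_start + 10) <- "GAGAGAGGAG"
  chars <- strsplit(base, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  make_variant <- function(i) {
    v <- chars
    pos <- e3s + 20L + 9L * (i - 1L) + c(0L, 3L, 6L) # 0-based
    v[pos + 1] <- flip[v[pos + 1]]
    if (!is.null(ga_carrier) && i == ga_carrier) v[tract_start + 6L] <- "G"
    paste(v, collapse = "")
  }
  alleles <- tibble(
    allele = sprintf("B*%02d:01:01", 60L + seq_len(n)),
    seq = vapply(seq_len(n), make_variant, character(1)),
    exon2_start = e2s, exon2_end = e2e, exon3_start = e3s, exon3_end = e3e
  )
  if (length(intron_twins)) {
    twins <- alleles[intron_twins, ]
    twins$allele <- sprintf("B*%02d:01:02", 60L + intron_twins)
    intron_pos <- 400L + intron_twins # 0-based, inside the intron
    twins$seq <- vapply(seq_along(intron_twins), function(k) {
      v <- strsplit(twins$seq[k], "")[[1]]
      v[intron_pos[k] + 1] <- flip[v[intron_pos[k] + 1]]
      paste(v, collapse = "")
    }, character(1))
    alleles <- dplyr::bind_rows(alleles, twins)
  }
  alleles <- validate_allele_set(alleles)
  attr(alleles, "str_mask") <- tibble(
    allele = alleles$allele, start = tract_start, end = tract_start + 10L,
    unit = "GA", copies = 3L
  )
  # degenerate codes chosen to contain the realised template base
  degen <- function(b) c(A = "M", C = "M", G = "K", T = "K")[[b]]
  fwd <- substr(base, 1, 22)
  substr(fwd, 8, 8) <- degen(substr(fwd, 8, 8))
  rev <- revcomp(substr(base, amp_len - 21, amp_len))
  substr(rev, 8, 8) <- degen(substr(rev, 8, 8))
  attr(alleles, "primers") <- primer_pair(fwd, rev)
  alleles
}

#' Retrieve the STR mask attached to an allele set
#'
#' @param alleles Allele set (e.g. from [synthetic_allele_set()]).
#' @return Tibble `allele`, `start`, `end` (0-based half-open amplicon
#'   coordinates), or `NULL` when no mask is annotated.
#' @export
str_mask <- function(alleles) attr(alleles, "str_mask")

#' Synthetic barcode set
#'
#' Random barcodes of fixed width with a guaranteed minimum pairwise global
#' edit distance (width/3, rounded down), regenerated until separation holds.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in bp (default 24).
#' @param seed Seed.
#' @return Tibble with `barcode_id` (`BC01`, ...) and `seq`.
#' @export
synthetic_barcodes <- function(n, width = 24, seed = 7) {
  stopifnot(n >= 1)
  min_d <- width %/% 3
  with_seed_if(seed, {
    draw <- function(k) vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- draw(n)
    repeat {
      d <- .sg_distance_matrix_cpp(seqs, seqs, FALSE)
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < min_d)
      if (!length(bad)) break
      seqs[bad[1]] <- draw(1)
    }
    tibble(barcode_id = sprintf("BC%02d", seq_len(n)), seq = seqs)
  })
}

#' Draw a diploid cohort
#'
#' Samples per-individual diploid genotypes from allele frequencies and
#' assigns one barcode per sample, emulating a multiplexed amplicon run.
#' With probability `homozygote_rate` a sample is forced homozygous for a
#' single frequency-weighted draw; otherwise its two alleles are drawn
#' independently.
#'
#' @param alleles Allele set.
#' @param n_samples Number of individuals (must not exceed the barcode set).
#' @param barcodes Barcode tibble (see [synthetic_barcodes()]).
#' @param allele_freqs Named frequency vector over `alleles$allele`
#'   (default uniform); must sum to 1.
#' @param homozygote_rate Forced-homozygote probability (default 0.08,
#'   matching a cohort with 4 homozygotes among 49).
#' @param seed Seed.
#' @return Cohort tibble: `sample_id`, `allele_a`, `allele_b`, `barcode_id`.
#' @export
make_cohort <- function(alleles, n_samples, barcodes, allele_freqs = NULL,
                        homozygote_rate = 0.08, seed = NULL) {
  stopifnot(n_samples >= 1)
  if (n_samples > nrow(barcodes)) {
    abort(sprintf("n_samples (%d) exceeds barcode set size (%d)",
                  n_samples, nrow(barcodes)))
  }
  if (is.null(allele_freqs)) {
    allele_freqs <- setNames(rep(1 / nrow(alleles), nrow(alleles)), alleles$allele)
  }
  stopifnot(all(names(allele_freqs) %in% alleles$allele),
            abs(sum(allele_freqs) - 1) < 1e-8)
  with_seed_if(seed, {
    hom <- runif(n_samples) < homozygote_rate
    a <- sample(names(allele_freqs), n_samples, replace = TRUE, prob = allele_freqs)
    b <- sample(names(allele_freqs), n_samples, replace = TRUE, prob = allele_freqs)
    b[hom] <- a[hom]
    tibble(sample_id = sprintf("S%02d", seq_len(n_samples)),
           allele_a = a, allele_b = b,
           barcode_id = barcodes$barcode_id[seq_len(n_samples)])
  })
}

#' Build a barcoded template
#'
#' Concatenates `left_tail + barcode + amplicon + revcomp(barcode) +
#' right_tail`, the layout produced by two-sided PCR barcoding; with the
#' default 36 bp tails and a 24 bp barcode a 943 bp amplicon yields a
#' 1,063 bp template.
#'
#' @param amplicon Amplicon sequence.
#' @param barcode Barcode sequence (may be `""`).
#' @param tails List with `left` and `right` adapter strings.
#' @return The template string.
#' @export
make_barcoded_template <- function(amplicon, barcode = "", tails = default_tails()) {
  rc_bc <- if (nzchar(barcode)) revcomp(barcode) else ""
  paste0(tails$left, barcode, amplicon, rc_bc, tails$right)
}

# Substitution alternatives: uniform over the three non-identical bases.
.alt_base <- function(base) {
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  vapply(base, function(b) sample(alts[[b]], 1), character(1), USE.NAMES = FALSE)
}

#' Simulate one noisy read from a template
#'
#' Walks the template base by base drawing one event per base: deletion with
#' probability `p_del` (multiplied by the repeat factor inside `str_mask`),
#' substitution with `p_sub` (uniform over the three alternatives), else the
#' correct base; independently, a uniform random base is inserted after each
#' template position with probability `p_ins`. Minus-strand reads are
#' reverse-complemented after simulation. The quality string is flat at the
#' read's drawn mean quality.
#'
#' @param template Template string.
#' @param model An [error_model()].
#' @param strand `"+"` or `"-"`.
#' @param str_mask Optional tibble with `start`, `end` (0-based half-open,
#'   template coordinates) marking STR intervals for the deletion boost.
#' @return List: `seq`, `qual`, `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_read <- function(template, model = error_model(), strand = "+",
                          str_mask = NULL) {
  stopifnot(inherits(model, "error_model"), strand %in% c("+", "-"))
  chars <- strsplit(template, "")[[1]]
  L <- length(chars)
  p_del <- rep(model$p_del, L)
  if (!is.null(str_mask) && nrow(str_mask)) {
    for (k in seq_len(nrow(str_mask))) {
      idx <- seq.int(str_mask$start[k] + 1L, str_mask$end[k])
      p_del[idx] <- pmin(1, p_del[idx] * model$repeat_del_multiplier)
    }
  }
  u <- runif(L)
  del <- u < p_del
  sub <- !del & u < p_del + model$p_sub
  ins <- runif(L) < model$p_ins
  emitted <- chars
  if (any(sub)) emitted[sub] <- .alt_base(chars[sub])
  emitted[del] <- ""
  if (any(ins)) {
    emitted[ins] <- paste0(emitted[ins], sample(c("A", "C", "G", "T"),
                                                sum(ins), replace = TRUE))
  }
  seq <- paste(emitted, collapse = "")
  if (strand == "-" && nzchar(seq)) seq <- revcomp(seq)
  q <- round(min(30, max(2, rnorm(1, model$read_q_mean, model$read_q_sd))))
  qual <- strrep(intToUtf8(q + 33L), nchar(seq))
  list(seq = seq, qual = qual,
       n_sub = sum(sub), n_ins = sum(ins), n_del = sum(del))
}

#' Measure empirical per-base error rates by re-alignment
#'
#' Globally aligns each read back to the template it was simulated from and
#' counts substitutions, deletions and insertions per template base — the
#' standard protocol for estimating a platform's error profile from amplicon
#' data. Minimal-edit alignment can merge adjacent insertion/deletion events
#' into one substitution, so measured rates sit marginally below the
#' generating rates.
#'
#' @param reads Read tibble or character vector of sequences (plus
#'   orientation).
#' @param template The template each read derives from.
#' @return One-row tibble: `n_bases`, `n_sub`, `n_del`, `n_ins`, and the
#'   corresponding per-template-base rates `sub_rate`, `del_rate`,
#'   `ins_rate`, `total_rate`.
#' @export
measure_error_rates <- function(reads, template) {
  seqs <- .read_seqs(reads)
  stopifnot(length(seqs) >= 1, nzchar(template))
  counts <- vapply(seqs, function(s) {
    a <- .sg_align_cpp(template, s, FALSE)
    c(a$n_sub, a$n_gap_ref, a$n_gap_query)
  }, numeric(3), USE.NAMES = FALSE)
  n_bases <- nchar(template) * length(seqs)
  tibble(
    n_bases = n_bases,
    n_sub = sum(counts[1, ]), n_del = sum(counts[2, ]),
    n_ins = sum(counts[3, ]),
    sub_rate = sum(counts[1, ]) / n_bases,
    del_rate = sum(counts[2, ]) / n_bases,
    ins_rate = sum(counts[3, ]) / n_bases,
    total_rate = sum(counts) / n_bases
  )
}

#' Log-normal per-sample depth model
#'
#' Emulates the heavy per-sample depth skew of multiplexed amplicon runs
#' (spanning roughly 80 to above 10,000 reads per sample), floored at `min`.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @param min Depth floor.
#' @return A function mapping a sample count to integer depths.
#' @export
depth_lognormal <- function(meanlog = log(2000), sdlog = 1, min = 80) {
  function(n) pmax(min, round(rlnorm(n, meanlog, sdlog)))
}

#' Simulate a multiplexed sequencing run
#'
#' Generates barcoded templates for each sample's two haplotypes, draws
#' per-sample read counts from the depth model, simulates each read with the
#' error model (haplotype and strand each Bernoulli(0.5)), shuffles reads
#' across samples, and returns the pooled reads together with a per-read
#' truth table. All randomness flows from one RNG stream seeded once.
#'
#' @param cohort Cohort tibble from [make_cohort()].
#' @param alleles Allele set (masks attached via [str_mask()] are honoured
#'   when `use_str_mask = TRUE`).
#' @param barcodes Barcode tibble.
#' @param depth A single number (fixed depth), a vector of per-sample depths,
#'   or a function of the sample count (e.g. [depth_lognormal()]).
#' @param model An [error_model()].
#' @param seed Seed; identical seeds give byte-identical output.
#' @param use_str_mask Apply the allele set's STR deletion boost (default
#'   FALSE: plain uniform error profile).
#' @param tails Adapter tails.
#' @param out_fastq,out_truth Optional output paths (FASTQ / truth TSV).
#' @return List of class `"sim_run"`: `reads` (tibble `read_id`, `seq`,
#'   `qual`), `truth` (tibble `read_id`, `sample_id`, `barcode_id`, `allele`,
#'   `strand`, `n_sub`, `n_ins`, `n_del`), and `cohort`.
#' @export
simulate_run <- function(cohort, alleles, barcodes, depth = 80,
                         model = error_model(), seed = NULL,
                         use_str_mask = FALSE, tails = default_tails(),
                         out_fastq = NULL, out_truth = NULL) {
  with_seed_if(seed, {
    n <- nrow(cohort)
    depths <- if (is.function(depth)) depth(n)
              else if (length(depth) == 1) rep(depth, n)
              else depth
    stopifnot(length(depths) == n)
    mask_tbl <- if (use_str_mask) str_mask(alleles) else NULL
    offset <- nchar(tails$left) +
      nchar(barcodes$seq[match(cohort$barcode_id, barcodes$barcode_id)])
    per_sample <- lapply(seq_len(n), function(s) {
      bc <- barcodes$seq[match(cohort$barcode_id[s], barcodes$barcode_id)]
      haps <- c(cohort$allele_a[s], cohort$allele_b[s])
      tmpl <- vapply(haps, function(a) {
        make_barcoded_template(alleles$seq[match(a, alleles$allele)], bc, tails)
      }, character(1))
      masks <- lapply(haps, function(a) {
        if (is.null(mask_tbl)) return(NULL)
        m <- mask_tbl[mask_tbl$allele == a, ]
        if (!nrow(m)) return(NULL)
        dplyr::mutate(m, start = .data$start + offset[s],
                      end = .data$end + offset[s])
      })
      hap <- sample(1:2, depths[s], replace = TRUE)
      strand <- sample(c("+", "-"), depths[s], replace = TRUE)
      sims <- lapply(seq_len(depths[s]), function(r) {
        simulate_read(tmpl[hap[r]], model, strand[r], masks[[hap[r]]])
      })
      tibble(
        sample_id = cohort$sample_id[s], barcode_id = cohort$barcode_id[s],
        allele = haps[hap], strand = strand,
        seq = vapply(sims, `[[`, character(1), "seq"),
        qual = vapply(sims, `[[`, character(1), "qual"),
        n_sub = vapply(sims, `[[`, numeric(1), "n_sub"),
        n_ins = vapply(sims, `[[`, numeric(1), "n_ins"),
        n_del = vapply(sims, `[[`, numeric(1), "n_del")
      )
    })
    all <- dplyr::bind_rows(per_sample)
    all <- all[sample.int(nrow(all)), ]
    all$read_id <- sprintf("read%06d", seq_len(nrow(all)))
    reads <- all[c("read_id", "seq", "qual")]
    truth <- all[c("read_id", "sample_id", "barcode_id", "allele", "strand",
                   "n_sub", "n_ins", "n_del")]
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    if (!is.null(out_truth)) readr::write_tsv(truth, out_truth)
    structure(list(reads = reads, truth = truth, cohort = cohort),
              class = "sim_run")
  })
}
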