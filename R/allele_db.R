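#' Load an allele reference set
#'
#' Reads allele amplicon sequences from a FASTA file (headers are allele
#' names; free text after the first whitespace is ignored) together with a
#' tab-delimited sidecar table of exon coordinates, columns `allele`,
#' `exon2_start`, `exon2_end`, `exon3_start`, `exon3_end` (0-based,
#' half-open, on the amplicon). Every allele must appear in both files.
#'
#' @param fasta_path Path to the allele FASTA.
#' @param exon_table_path Path to the exon-coordinate TSV.
#' @return An allele set: a tibble with columns `allele`, `seq`,
#'   `exon2_start`, `exon2_end`, `exon3_start`, `exon3_end`.
#' @export
load_allele_set <- function(fasta_path, exon_table_path) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(fa))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate allele name in FASTA: '%s'", nm[duplicated(nm)][1]))
  }
  ex <- readr::read_tsv(exon_table_path, show_col_types = FALSE)
  need <- c("allele", "exon2_start", "exon2_end", "exon3_start", "exon3_end")
  if (!all(need %in% names(ex))) {
    abort(paste0("exon table must have columns: ", paste(need, collapse = ", ")))
  }
  only_fa <- setdiff(nm, ex$allele)
  only_ex <- setdiff(ex$allele, nm)
  if (length(only_fa)) {
    abort(paste0("allele(s) in FASTA missing from exon table: ",
                 paste(only_fa, collapse = ", ")))
  }
  if (length(only_ex)) {
    abort(paste0("allele(s) in exon table missing from FASTA: ",
                 paste(only_ex, collapse = ", ")))
  }
  out <- tibble(allele = nm, seq = unname(toupper(as.character(fa)))) |>
    dplyr::left_join(ex[need], by = "allele")
  validate_allele_set(out)
}

#' Validate an allele set
#'
#' Checks the allele-set invariants: names parse, sequences are A/C/G/T
#' only, exon intervals lie within the sequence, exon 2 precedes and does
#' not overlap exon 3. Returns the (classed) tibble invisibly unchanged on
#' success and aborts with the offending allele otherwise.
#'
#' @param alleles Allele-set tibble (see [load_allele_set()]).
#' @return The validated tibble, classed `"allele_set"`.
#' @export
validate_allele_set <- function(alleles) {
  stopifnot(nrow(alleles) >= 1)
  parse_allele_name(alleles$allele) # aborts on malformed names
  bad <- grepl("[^ACGT]", alleles$seq)
  if (any(bad)) {
    abort(sprintf("allele '%s' contains non-ACGT characters", alleles$allele[bad][1]))
  }
  len <- nchar(alleles$seq)
  ok <- alleles$exon2_start >= 0 & alleles$exon2_start < alleles$exon2_end &
    alleles$exon2_end <= alleles$exon3_start &
    alleles$exon3_start < alleles$exon3_end & alleles$exon3_end <= len
  if (any(!ok)) {
    abort(sprintf("allele '%s' has invalid exon intervals", alleles$allele[!ok][1]))
  }
  class(alleles) <- unique(c("allele_set", class(alleles)))
  alleles
}

#' Write an allele set to FASTA + exon sidecar
#'
#' @param alleles Allele-set tibble.
#' @param fasta_path,exon_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_allele_set <- function(alleles, fasta_path, exon_table_path) {
  dna <- Biostrings::DNAStringSet(setNames(alleles$seq, alleles$allele))
  Biostrings::writeXStringSet(dna, fasta_path)
  readr::write_tsv(alleles[c("allele", "exon2_start", "exon2_end",
                             "exon3_start", "exon3_end")], exon_table_path)
  invisible(c(fasta_path, exon_table_path))
}

# Concatenated exon 2 + exon 3 sequence per allele.
exon_concat <- function(alleles) {
  substr(alleles$seq, alleles$exon2_start + 1, alleles$exon2_end) |>
    paste0(substr(alleles$seq, alleles$exon3_start + 1, alleles$exon3_end))
}

#' Build G-groups from an allele set
#'
#' Partitions alleles by exact identity of their concatenated exon 2 + exon 3
#' sequence (the peptide-binding-domain exons that define class I G-groups).
#' Multi-member groups are named after the field-wise numerically smallest
#' member, truncated to three fields, with `"G"` appended; singleton groups
#' keep the member's own name unchanged.
#'
#' @param alleles Allele-set tibble.
#' @return A tibble with columns `allele`, `group`, plus an attribute
#'   `"groups"`: a named list of member vectors per group.
#' @examples
#' alleles <- synthetic_allele_set(n = 4, intron_twins = 1, seed = 1)
#' build_ggroups(alleles)
#' @export
build_ggroups <- function(alleles) {
  stopifnot(nrow(alleles) >= 1)
  key <- exon_concat(alleles)
  split_members <- split(alleles$allele, factor(key, levels = unique(key)))
  group_name <- vapply(split_members, function(members) {
    if (length(members) == 1L) return(members)
    smallest <- members[allele_name_order(members)][1]
    paste0(truncate_allele(smallest, 3), "G")
  }, character(1))
  groups <- setNames(unname(split_members), unname(group_name))
  map <- tibble(
    allele = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
  map <- map[match(alleles$allele, map$allele), ]
  attr(map, "groups") <- groups
  map
}

# Group name for a vector of alleles under a ggroup map (identity fallback).
ggroup_of <- function(allele, ggroups = NULL) {
  if (is.null(ggroups)) return(allele)
  i <- match(allele, ggroups$allele)
  ifelse(is.na(i), allele, ggroups$group[i])
}

#' IUPAC nucleotide matching
#'
#' Tests whether each concrete base is contained in the set denoted by the
#' corresponding IUPAC degeneracy code (e.g. `M` = A or C, `S` = C or G,
#' `N` = any).
#'
#' @param base Character vector of concrete bases (A/C/G/T).
#' @param code Character vector of IUPAC codes (recycled against `base`).
#' @return Logical vector.
#' @examples
#' iupac_match(c("A", "G"), "M") # TRUE FALSE
#' @export
iupac_match <- function(base, code) {
  n <- max(length(base), length(code))
  base <- toupper(rep_len(base, n)); code <- toupper(rep_len(code, n))
  if (any(!base %in% c("A", "C", "G", "T"))) {
    abort("'base' must be a concrete nucleotide (A/C/G/T)")
  }
  map <- Biostrings::IUPAC_CODE_MAP
  if (any(!code %in% names(map))) {
    abort(sprintf("invalid IUPAC code '%s'", code[!code %in% names(map)][1]))
  }
  stringr::str_detect(map[code], stringr::fixed(base))
}

#' Construct a primer pair
#'
#' @param forward,reverse Primer sequences written 5'→3'; the reverse primer
#'   is given on the opposite strand, as usual. IUPAC degeneracy codes are
#'   allowed.
#' @return A classed list `"primer_pair"`.
#' @export
primer_pair <- function(forward, reverse) {
  ok <- function(x) grepl(sprintf("^[%s]+$", paste(names(Biostrings::IUPAC_CODE_MAP),
                                                   collapse = "")), toupper(x))
  if (!ok(forward) || !ok(reverse)) abort("primers must be IUPAC DNA strings")
  structure(list(forward = toupper(forward), reverse = toupper(reverse)),
            class = "primer_pair")
}

#' The published MinION HLA-B primer pair
#'
#' The degenerate, adapter-tailed primer pair used to amplify the 943 bp
#' fragment spanning HLA-B exons 2 and 3 for nanopore sequencing. The
#' degeneracies (`M`, `R`, `S`) sit at known HLA-B polymorphic sites to
#' prevent allelic dropout during PCR.
#'
#' @return A `"primer_pair"`.
#' @export
hla_b_minion_primers <- function() {
  primer_pair(
    forward = "TTTCTGTTGGTGCTGATATTGCGGGAGGAGMRAGGGGACCSCAG",
    reverse = "ACTTGCCTGTCGCTCTATCTTCGGAGGCCATCCCCGGCGACCTAT"
  )
}

#' In-silico PCR with degenerate primers
#'
#' Finds the forward primer site on the plus strand and the reverse primer
#' site on the minus strand, each with at most `max_mismatch` IUPAC-aware
#' mismatches, and returns the inclusive primer-to-primer product. When
#' several products are possible the shortest is returned with a warning
#' (degenerate primers can pick up spurious distal sites).
#'
#' @param template DNA string (A/C/G/T).
#' @param primers A [primer_pair()].
#' @param max_mismatch Maximum mismatches per primer site (default 0;
#'   degeneracy matches are not mismatches).
#' @return A one-row tibble: `start`, `end` (1-based inclusive on the
#'   template), `length`, `seq`.
#' @export
in_silico_pcr <- function(template, primers, max_mismatch = 0) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- toupper(template)
  if (nchar(template) < nchar(primers$forward) + nchar(primers$reverse)) {
    abort("template shorter than combined primer length")
  }
  subj <- Biostrings::DNAString(template)
  fixedness <- c(pattern = FALSE, subject = TRUE)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(primers$forward), subj,
                                    max.mismatch = max_mismatch, fixed = fixedness)
  rpat <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  rhits <- Biostrings::matchPattern(rpat, subj,
                                    max.mismatch = max_mismatch, fixed = fixedness)
  if (length(fhits) == 0) abort("no amplification: forward primer site not found")
  if (length(rhits) == 0) abort("no amplification: reverse primer site not found")
  combos <- tidyr::expand_grid(
    start = Biostrings::start(fhits),
    end = Biostrings::end(rhits)
  ) |>
    dplyr::filter(.data$end - .data$start + 1 >=
                    nchar(primers$forward) + nchar(primers$reverse)) |>
    dplyr::mutate(length = .data$end - .data$start + 1) |>
    dplyr::arrange(.data$length)
  if (nrow(combos) == 0) abort("no amplification: primer sites do not face each other")
  if (nrow(combos) > 1) {
    warn(sprintf("in_silico_pcr: %d possible products; returning the shortest",
                 nrow(combos)))
  }
  best <- combos[1, ]
  dplyr::mutate(best, seq = substr(template, .data$start, .data$end))
}
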