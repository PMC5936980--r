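#' Read a genotype table
#'
#' Loads a per-sample diploid genotype TSV (columns `sample`, `ethnicity`,
#' `allele1`, `allele2`, optionally SBT confirmation columns), validates
#' sample uniqueness, and canonicalises both allele columns through the
#' nomenclature parser, reporting the offending row on failure. The
#' `ethnicity` column carries free-text ancestry-fraction annotations (e.g.
#' `"0.5 NM 0.5 C"`), kept verbatim.
#'
#' @param path TSV path.
#' @return A `"genotype_table"` tibble.
#' @export
read_genotype_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c")) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("sbt_validated",
                                                "manual_assignment")),
                                as.logical))
  need <- c("sample", "ethnicity", "allele1", "allele2")
  if (!all(need %in% names(tb))) {
    abort(paste0("genotype table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tb$sample)) {
    abort(sprintf("duplicate sample id '%s'", tb$sample[duplicated(tb$sample)][1]))
  }
  for (colnm in c("allele1", "allele2")) {
    canon <- tryCatch(parse_allele_name(tb[[colnm]])$allele, error = function(e) e)
    if (inherits(canon, "error")) {
      # locate the offending row for the error message
      bad <- which(vapply(tb[[colnm]], function(x) {
        inherits(tryCatch(parse_allele_name(x), error = function(e) e), "error")
      }, logical(1)))[1]
      abort(sprintf("row %d (%s): %s", bad, tb$sample[bad],
                    conditionMessage(canon)))
    }
    tb[[colnm]] <- canon
  }
  class(tb) <- unique(c("genotype_table", class(tb)))
  tb
}

#' The transcribed cohort genotype fixture
#'
#' The published 49-sample HLA-B genotype table (40 Māori / Pacific Island
#' individuals with `PI_`-prefixed ids, 4 Coriell references, 5 UDRUGS
#' samples), shipped as a plain-text fixture.
#'
#' @return A `"genotype_table"` tibble (49 rows).
#' @export
table3_genotypes <- function() {
  read_genotype_table(system.file("extdata", "table3_hla_b_genotypes.tsv",
                                  package = "amplitype", mustWork = TRUE))
}

#' Restrict a genotype table to the Māori / Pacific Island subset
#'
#' Membership is defined by the `PI_` sample-id prefix (the cohort rows, as
#' opposed to the Coriell/UDRUGS reference rows); the ancestry-fraction
#' strings are informational only.
#'
#' @param table A `"genotype_table"`.
#' @return The filtered table.
#' @export
maori_pacific <- function(table) {
  dplyr::filter(table, startsWith(.data$sample, "PI_"))
}

#' Zygosity counts
#'
#' @param table A `"genotype_table"`.
#' @return One-row tibble: `homozygotes`, `heterozygotes`.
#' @export
zygosity_counts <- function(table) {
  hom <- sum(table$allele1 == table$allele2)
  tibble(homozygotes = hom, heterozygotes = nrow(table) - hom)
}

#' Distinct alleles in a genotype table
#'
#' @param table A `"genotype_table"` (or subset).
#' @return Tibble with one column `allele`, sorted; the count is its row
#'   count.
#' @export
distinct_alleles <- function(table) {
  al <- sort(unique(c(table$allele1, table$allele2)))
  tibble(allele = al)
}

#' Allele occurrence counts and frequencies
#'
#' Counts allele occurrences over both genotype columns and converts to
#' frequencies under a declared denominator: `"chromosomes"` (2 x samples;
#' the conventional gene-frequency denominator, sums to 1) or
#' `"distinct_alleles"` (occurrences over the number of distinct alleles
#' observed — the denominator under which the published cohort percentages,
#' e.g. 28.95% for the top allele, were reported).
#'
#' @param table A `"genotype_table"` (or subset); must be non-empty.
#' @param denominator `"chromosomes"` (default) or `"distinct_alleles"`.
#' @return A `"frequency_report"` tibble: `allele`, `count`, `frequency`,
#'   `percent`, sorted by descending count; attribute `"denominator"`.
#' @export
allele_frequencies <- function(table,
                               denominator = c("chromosomes",
                                               "distinct_alleles")) {
  denominator <- match.arg(denominator)
  if (nrow(table) == 0) abort("empty genotype table")
  occ <- c(table$allele1, table$allele2)
  denom <- switch(denominator,
                  chromosomes = 2 * nrow(table),
                  distinct_alleles = dplyr::n_distinct(occ))
  out <- tibble(allele = occ) |>
    dplyr::count(.data$allele, name = "count") |>
    dplyr::mutate(frequency = .data$count / denom,
                  percent = 100 * .data$frequency) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$allele)
  stopifnot(sum(out$count) == 2 * nrow(table))
  attr(out, "denominator") <- denom
  attr(out, "denominator_mode") <- denominator
  class(out) <- unique(c("frequency_report", class(out)))
  out
}

#' Screen for pharmacogenetic risk alleles
#'
#' Matches carriers of each risk allele at the risk entry's own field
#' resolution (two-field entries such as `B*57:01` match any deeper-typed
#' allele, G flags and suffixes ignored — the usual pharmacogenetic
#' convention, e.g. abacavir hypersensitivity screening for B*57:01).
#'
#' @param table A `"genotype_table"` (or subset).
#' @param risk Character vector of risk allele names (any field depth).
#' @return Tibble `risk_allele`, `n_carriers`, `carriers` (list-column of
#'   sample ids).
#' @export
screen_risk_alleles <- function(table, risk) {
  if (length(risk) == 0) {
    return(tibble(risk_allele = character(), n_carriers = integer(),
                  carriers = list()))
  }
  rp <- parse_allele_name(risk)
  purrr::map2_dfr(rp$allele, rp$n_fields, function(r, nf) {
    r_trunc <- truncate_allele(r, nf)
    hit <- truncate_allele(table$allele1, nf) == r_trunc |
      truncate_allele(table$allele2, nf) == r_trunc
    tibble(risk_allele = r, n_carriers = sum(hit),
           carriers = list(table$sample[hit]))
  })
}
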