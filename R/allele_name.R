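#' Parse HLA allele names
#'
#' Parses allele names in standard colon-delimited HLA nomenclature, e.g.
#' `"B*40:01:01G"`: a locus, one to four numeric fields (allele group,
#' protein, synonymous coding, non-coding), an optional expression suffix
#' (`N`, `L`, `S`, `C`, `A`, `Q`), and an optional trailing `G` marking a
#' G-group name (alleles identical across the exons encoding the
#' peptide-binding domains, exons 2 and 3 for class I). G-group names are
#' by convention three-field, which is enforced.
#'
#' @param x Character vector of allele names.
#' @return A tibble with one row per name: `allele` (canonical re-formatted
#'   name), `locus`, `f1`–`f4` (integer fields, `NA` when absent),
#'   `n_fields`, `suffix` (`NA` or one of N/L/S/C/A/Q), `g_flag` (logical).
#' @examples
#' parse_allele_name(c("B*40:01:01G", "B*27:09"))
#' @export
parse_allele_name <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  if (any(is.na(x) | !nzchar(x))) {
    abort("allele names must be non-empty strings")
  }
  rx <- "^([A-Za-z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+){0,3})([NLSCAQ]?)(G?)$"
  m <- stringr::str_match(x, rx)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    tok <- x[bad][1]
    hint <- if (!grepl("\\*", tok)) "missing '*' separator" else "malformed fields"
    abort(sprintf("cannot parse allele name '%s' (%s)", tok, hint))
  }
  fields <- stringr::str_split(m[, 3], ":")
  nf <- lengths(fields)
  fmat <- t(vapply(fields, function(f) {
    as.integer(c(f, rep(NA_character_, 4 - length(f))))
  }, integer(4)))
  g_flag <- m[, 5] == "G"
  if (any(g_flag & nf != 3L)) {
    abort(sprintf("G-group name '%s' must have exactly three fields",
                  x[g_flag & nf != 3L][1]))
  }
  out <- tibble(
    locus = m[, 2],
    f1 = fmat[, 1], f2 = fmat[, 2], f3 = fmat[, 3], f4 = fmat[, 4],
    n_fields = as.integer(nf),
    suffix = ifelse(nzchar(m[, 4]), m[, 4], NA_character_),
    g_flag = g_flag
  )
  dplyr::mutate(out, allele = format_allele_name(out), .before = 1)
}

#' Format parsed allele names canonically
#'
#' Inverse of [parse_allele_name()]: renders each field zero-padded to at
#' least two digits, colon-separated, with suffix and `G` flag appended.
#' Round-trips with the parser.
#'
#' @param parsed A tibble as returned by [parse_allele_name()] (the `allele`
#'   column is ignored if present).
#' @return Character vector of canonical names.
#' @export
format_allele_name <- function(parsed) {
  fmat <- cbind(parsed$f1, parsed$f2, parsed$f3, parsed$f4)
  fields <- apply(fmat, 1, function(f) {
    f <- f[!is.na(f)]
    paste(sprintf("%02d", f), collapse = ":")
  })
  paste0(parsed$locus, "*", fields,
         ifelse(is.na(parsed$suffix), "", parsed$suffix),
         ifelse(parsed$g_flag, "G", ""))
}

#' Truncate allele names to a lower field resolution
#'
#' Drops fields beyond `fields` together with any expression suffix and
#' G flag; used for two-field pharmacogenetic risk matching and for
#' G-group naming.
#'
#' @param x Character vector of allele names.
#' @param fields Number of fields to keep (1--4).
#' @return Character vector of truncated canonical names.
#' @examples
#' truncate_allele("B*57:01:01G", 2) # "B*57:01"
#' @export
truncate_allele <- function(x, fields = 2) {
  p <- parse_allele_name(x)
  keep <- seq_len(min(fields, 4L))
  fmat <- cbind(p$f1, p$f2, p$f3, p$f4)
  fmat[, setdiff(1:4, keep)] <- NA_integer_
  p$f1 <- fmat[, 1]; p$f2 <- fmat[, 2]; p$f3 <- fmat[, 3]; p$f4 <- fmat[, 4]
  p$suffix <- NA_character_
  p$g_flag <- FALSE
  format_allele_name(p)
}

# Field-wise numeric ordering of allele names; a shorter name that is a
# prefix of a longer one sorts first. Returns an ordering permutation.
allele_name_order <- function(x) {
  p <- parse_allele_name(x)
  order(p$locus, p$f1,
        ifelse(is.na(p$f2), -1L, p$f2),
        ifelse(is.na(p$f3), -1L, p$f3),
        ifelse(is.na(p$f4), -1L, p$f4),
        x)
}
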