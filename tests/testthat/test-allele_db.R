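test_that("allele sets round-trip through FASTA + exon sidecar", {
  al <- synthetic_allele_set(n = 3, seed = 1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_allele_set(al, fa, tsv)
  back <- load_allele_set(fa, tsv)
  expect_equal(nrow(back), 3)
  expect_equal(back$seq, al$seq)
  expect_equal(back$exon2_start, al$exon2_start)
})

test_that("loading rejects mismatched, duplicated and out-of-bounds input", {
  al <- synthetic_allele_set(n = 3, seed = 1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_allele_set(al, fa, tsv)

  # sidecar missing one allele
  ex <- readr::read_tsv(tsv, show_col_types = FALSE)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ex[-2, ], tsv2)
  expect_error(load_allele_set(fa, tsv2), al$allele[2], fixed = TRUE)

  # exon interval beyond the sequence
  ex2 <- ex; ex2$exon3_end[1] <- nchar(al$seq[1]) + 50
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ex2, tsv3)
  expect_error(load_allele_set(fa, tsv3), "invalid exon")

  # duplicate FASTA header
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", al$allele[1]), al$seq[1],
               paste0(">", al$allele[1]), al$seq[2]), fa2)
  expect_error(load_allele_set(fa2, tsv), "duplicate")
})

test_that("G-group partition matches brute-force exon comparison", {
  withr::local_seed(5)
  for (rep in 1:3) {
    al <- synthetic_allele_set(n = 5, seed = sample.int(1000, 1),
                               intron_twins = sample(1:5, 2))
    gg <- build_ggroups(al)
    ex <- amplitype:::exon_concat(al)
    # brute force: same group iff identical exon2+3 concatenation
    for (i in seq_len(nrow(al))) {
      for (j in seq_len(nrow(al))) {
        expect_equal(gg$group[i] == gg$group[j], ex[i] == ex[j])
      }
    }
  }
})

test_that("G-group naming follows the smallest-member three-field+G rule", {
  al <- synthetic_allele_set(n = 5, seed = 42, intron_twins = c(2, 4))
  gg <- build_ggroups(al)
  # 7 alleles, 2 twin pairs -> 5 groups
  expect_equal(length(attr(gg, "groups")), 5)
  # multi-member group named after the numerically smallest member + G
  expect_equal(gg$group[gg$allele == "B*62:01:01"], "B*62:01:01G")
  expect_equal(gg$group[gg$allele == "B*62:01:02"], "B*62:01:01G")
  # singleton keeps its own name, no G appended
  expect_equal(gg$group[gg$allele == "B*61:01:01"], "B*61:01:01")
})

test_that("IUPAC matching follows the code sets", {
  expect_true(iupac_match("A", "M"))
  expect_false(iupac_match("G", "M"))
  expect_true(iupac_match("A", "N"))
  expect_true(iupac_match("C", "S"))
  expect_false(iupac_match("A", "S"))
  expect_error(iupac_match("M", "A"), "concrete")
  expect_error(iupac_match("A", "Z"), "invalid IUPAC")
})

test_that("in-silico PCR recovers each allele's own amplicon exactly", {
  al <- synthetic_allele_set(n = 4, seed = 42)
  pp <- attr(al, "primers")
  for (i in seq_len(nrow(al))) {
    p <- in_silico_pcr(al$seq[i], pp)
    expect_equal(p$length, 943)
    expect_identical(p$seq, al$seq[i])
  }
  # embedded in flanking sequence: the 943 bp product is located
  tpl <- paste0(strrep("T", 120), al$seq[1], strrep("C", 80))
  p <- in_silico_pcr(tpl, pp)
  expect_equal(p$start, 121)
  expect_equal(p$length, 943)
})

test_that("in-silico PCR errors and tie-breaks are reported", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  pp <- attr(al, "primers")
  # template lacking the reverse site
  expect_error(in_silico_pcr(substr(al$seq[1], 1, 600), pp), "reverse primer")
  # two forward sites -> multiple products, shortest returned with a warning
  tpl <- paste0(substr(al$seq[1], 1, 120), al$seq[1])
  expect_warning(p <- in_silico_pcr(tpl, pp), "shortest")
  expect_equal(p$length, 943)
})

test_that("primer degeneracy is not a mismatch at zero tolerance", {
  # the fixture primers carry degenerate codes over concrete template bases
  # and still amplify with max_mismatch = 0 (covered above); a truly
  # mismatched base is not tolerated at 0 but is at 1
  al <- synthetic_allele_set(n = 2, seed = 42)
  pp <- attr(al, "primers")
  tpl <- al$seq[1]
  substr(tpl, 2, 2) <- chartr("ACGT", "GTAC", substr(tpl, 2, 2))
  substr(tpl, 3, 3) <- chartr("ACGT", "GTAC", substr(tpl, 3, 3))
  expect_error(in_silico_pcr(tpl, pp, max_mismatch = 0), "forward")
  expect_equal(in_silico_pcr(tpl, pp, max_mismatch = 2)$length, 943)
})
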