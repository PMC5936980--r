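# error-free reads for a genotype: `depth` per haplotype, plus strand
perfect_reads <- function(alleles, a, b, depth = 5) {
  c(rep(alleles$seq[alleles$allele == a], depth),
    rep(alleles$seq[alleles$allele == b], depth))
}

test_that("error-free reads shortlist the true pair; large k returns all", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  rd <- perfect_reads(al, "B*61:01:01", "B*64:01:01")
  sl <- shortlist_alleles(rd, al, k = 3)
  expect_true(all(c("B*61:01:01", "B*64:01:01") %in% sl$allele))
  expect_equal(nrow(shortlist_alleles(rd, al, k = 10)), nrow(al))
  expect_error(shortlist_alleles(character(0), al), "no reads")
})

test_that("consensus reproduces the template and resists lone errors", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  cons <- build_consensus(rep(al$seq[1], 4), al[1, ])
  expect_identical(cons$seq, al$seq[1])
  # 3 reads, one substitution at column 10 in one read: majority keeps ref
  mut <- al$seq[1]
  substr(mut, 10, 10) <- chartr("ACGT", "GTAC", substr(mut, 10, 10))
  cons2 <- build_consensus(c(al$seq[1], al$seq[1], mut), al[1, ])
  expect_identical(cons2$seq, al$seq[1])
})

test_that("noisy consensus stays within a few edits of the template", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  withr::local_seed(71)
  rd <- vapply(1:50, function(i) simulate_read(al$seq[1], error_model())$seq, "")
  cons <- build_consensus(rd, al[1, ])
  expect_lte(amplitype:::.sg_distance_cpp(cons$seq, al$seq[1], FALSE), 2)
})

test_that("pair scoring is symmetric and zero for the true pair", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  rd <- perfect_reads(al, "B*61:01:01", "B*64:01:01", depth = 6)
  s <- score_pair(rd, al, "B*61:01:01", "B*64:01:01")
  expect_equal(s$total, 0)
  expect_equal(s$n_a, 6)
  expect_equal(s$n_b, 6)
  s_rev <- score_pair(rd, al, "B*64:01:01", "B*61:01:01")
  expect_equal(s$total, s_rev$total)
  expect_equal(s$a, s_rev$a)
  # wrong pair member differing at >= 3 exon sites scores >= 3
  s_wrong <- score_pair(rd, al, "B*61:01:01", "B*65:01:01")
  expect_gte(s_wrong$total, 3)
})

test_that("allele dropout demotes a pair to the majority homozygote", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  rd <- c(rep(al$seq[1], 19), al$seq[2]) # 5% minor member
  s <- score_pair(rd, al, al$allele[1], al$allele[2])
  expect_true(s$demoted)
  expect_equal(s$a, al$allele[1])
  expect_equal(s$b, al$allele[1])
})

test_that("zero-error completeness: true pair called with no ambiguity", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  combos <- utils::combn(al$allele, 2)
  withr::local_seed(81)
  for (k in sample(ncol(combos), 4)) {
    rd <- perfect_reads(al, combos[1, k], combos[2, k], depth = 2)
    cl <- call_genotype(rd, al, allow_low_depth = TRUE)
    expect_equal(sort(c(cl$best$allele_a, cl$best$allele_b)),
                 sort(combos[, k]))
    expect_equal(cl$best$total, 0)
    expect_false(cl$ambiguous)
    expect_false(cl$manual_review)
  }
})

test_that("homozygous samples are called as self-pairs", {
  fx <- tiny_fixture()
  co <- tibble::tibble(sample_id = "S1", allele_a = "B*63:01:01",
                       allele_b = "B*63:01:01", barcode_id = "BC01")
  run <- simulate_run(co, fx$alleles, fx$barcodes, depth = 60, seed = 5)
  cl <- call_genotype(run$reads, fx$alleles)
  expect_equal(cl$zygosity, "homozygous")
  expect_equal(cl$best$allele_a, "B*63:01:01")
  expect_equal(cl$best$allele_b, "B*63:01:01")
})

test_that("depth refusal triggers below min_depth and can be overridden", {
  al <- synthetic_allele_set(n = 4, seed = 42)
  rd <- perfect_reads(al, al$allele[1], al$allele[2], depth = 3)
  expect_error(call_genotype(rd, al, min_depth = 20), "min_depth")
  expect_s3_class(call_genotype(rd, al, min_depth = 20,
                                allow_low_depth = TRUE), "genotype_call")
})

test_that("exon-identical intron variants tie into one reported G-group", {
  al <- synthetic_allele_set(n = 6, seed = 42, intron_twins = 3)
  gg <- build_ggroups(al)
  fx_bc <- synthetic_barcodes(2, seed = 7)
  co <- tibble::tibble(sample_id = "S1", allele_a = "B*61:01:01",
                       allele_b = "B*63:01:01", barcode_id = "BC01")
  run <- simulate_run(co, al, fx_bc, depth = 60, seed = 9)
  cl <- call_genotype(run$reads, al, gg)
  expect_true(cl$ambiguous)
  top <- dplyr::filter(tidy(cl), .data$total == cl$best$total,
                       .data$support == cl$best$support)
  expect_gte(nrow(top), 2)
  # all co-best pairs report the same single G-group name for the twin
  expect_equal(unique(top$reported_b), "B*63:01:01G")
  expect_equal(cl$best$reported_b, "B*63:01:01G")
})

test_that("masked rescoring never increases the total and identity holds", {
  fx <- tiny_fixture(ga_carrier = 2)
  co <- tibble::tibble(sample_id = "S1", allele_a = "B*61:01:01",
                       allele_b = "B*62:01:01", barcode_id = "BC01")
  run <- simulate_run(co, fx$alleles, fx$barcodes, depth = 50, seed = 13,
                      use_str_mask = TRUE)
  msk <- str_mask(fx$alleles)
  for (pair in list(c("B*61:01:01", "B*62:01:01"),
                    c("B*62:01:01", "B*62:01:01"),
                    c("B*62:01:01", "B*63:01:01"))) {
    plain <- score_pair(run$reads, fx$alleles, pair[1], pair[2])
    masked <- rescore_masked(run$reads, fx$alleles, pair[1], pair[2], msk)
    expect_lte(masked$total, plain$total)
  }
  # empty mask: identical to plain scoring
  empty <- rescore_masked(run$reads, fx$alleles, "B*61:01:01", "B*62:01:01",
                          msk[0, ])
  plain <- score_pair(run$reads, fx$alleles, "B*61:01:01", "B*62:01:01")
  expect_equal(empty$total, plain$total)
  expect_equal(empty$positions, plain$positions)
})

test_that("hotspot reports are empty for clean calls and stay in bounds", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  rd <- perfect_reads(al, "B*61:01:01", "B*64:01:01", depth = 3)
  cl <- call_genotype(rd, al, allow_low_depth = TRUE)
  expect_equal(nrow(dplyr::filter(cl$hotspots, .data$share >= 1)), 0)
  exon_len <- c(`2` = 270L, `3` = 276L)
  if (nrow(cl$hotspots)) {
    expect_true(all(cl$hotspots$pos >= 1 &
                      cl$hotspots$pos <= exon_len[as.character(cl$hotspots$exon)]))
  }
})

test_that("tidy and glance expose the ranked pairs and the call summary", {
  al <- synthetic_allele_set(n = 4, seed = 42)
  rd <- perfect_reads(al, al$allele[1], al$allele[3], depth = 3)
  cl <- call_genotype(rd, al, allow_low_depth = TRUE, sample_id = "S9")
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$rank, seq_len(nrow(td)))
  expect_true(all(td$total == sort(td$total)))
  g <- glance(cl)
  expect_equal(g$sample_id, "S9")
  expect_equal(g$zygosity, "heterozygous")
  expect_equal(g$total_mismatches, 0)
})
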