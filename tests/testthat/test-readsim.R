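test_that("error model invariants are enforced", {
  expect_s3_class(error_model(), "error_model")
  expect_error(error_model(p_sub = 0.6, p_del = 0.5))
  expect_error(error_model(repeat_del_multiplier = 0.5))
  expect_error(error_model(p_del = 0.5, repeat_del_multiplier = 3))
})

test_that("barcoded templates have the expected layout and length", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  bc <- synthetic_barcodes(2, seed = 7)
  tmpl <- make_barcoded_template(al$seq[1], bc$seq[1])
  expect_equal(nchar(tmpl), 1063) # 943 bp amplicon + 120 bp barcoded tails
  expect_equal(nchar(tmpl) - nchar(al$seq[1]),
               2 * 36 + 2 * nchar(bc$seq[1]))
  # empty barcode and tails: template is the amplicon
  expect_identical(
    make_barcoded_template(al$seq[1], "", list(left = "", right = "")),
    al$seq[1])
})

test_that("simulated reads honour limit cases and length bookkeeping", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  tpl <- al$seq[1]
  r0 <- simulate_read(tpl, error_model(p_sub = 0, p_ins = 0, p_del = 0))
  expect_identical(r0$seq, tpl)
  expect_equal(nchar(r0$qual), nchar(tpl))
  r1 <- simulate_read(tpl, error_model(p_sub = 0, p_ins = 0, p_del = 1,
                                       repeat_del_multiplier = 1))
  expect_identical(r1$seq, "")
  withr::local_seed(3)
  for (k in 1:10) {
    r <- simulate_read(tpl, error_model())
    expect_equal(nchar(r$seq), nchar(tpl) - r$n_del + r$n_ins)
  }
  # minus strand reverse-complements
  withr::with_seed(5, rp <- simulate_read(tpl, error_model(), strand = "+"))
  withr::with_seed(5, rm <- simulate_read(tpl, error_model(), strand = "-"))
  expect_identical(rm$seq, amplitype:::revcomp(rp$seq))
})

test_that("event rates match the configured error model", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  tpl <- al$seq[1]
  m <- error_model()
  n <- 64
  withr::local_seed(11)
  sims <- replicate(n, simulate_read(tpl, m), simplify = FALSE)
  bases <- n * nchar(tpl)
  for (comp in c("n_sub", "n_ins", "n_del")) {
    p <- switch(comp, n_sub = m$p_sub, n_ins = m$p_ins, n_del = m$p_del)
    rate <- sum(vapply(sims, `[[`, numeric(1), comp)) / bases
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / bases))
  }
})

test_that("STR-masked intervals take the boosted deletion rate", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  tpl <- al$seq[1]
  m <- error_model()
  mask <- tibble::tibble(start = 0, end = nchar(tpl)) # boost everywhere
  withr::local_seed(13)
  sims <- replicate(48, simulate_read(tpl, m, str_mask = mask),
                    simplify = FALSE)
  bases <- 48 * nchar(tpl)
  p <- m$p_del * m$repeat_del_multiplier
  rate <- sum(vapply(sims, `[[`, numeric(1), "n_del")) / bases
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / bases))
})

test_that("cohorts draw valid genotypes reproducibly", {
  al <- synthetic_allele_set(n = 6, seed = 42)
  bc <- synthetic_barcodes(49, seed = 7)
  co <- make_cohort(al, 49, bc, seed = 1)
  expect_equal(nrow(co), 49)
  expect_true(all(c(co$allele_a, co$allele_b) %in% al$allele))
  expect_identical(co, make_cohort(al, 49, bc, seed = 1))
  hom <- make_cohort(al, 20, bc, homozygote_rate = 1, seed = 2)
  expect_true(all(hom$allele_a == hom$allele_b))
  expect_error(make_cohort(al, 60, bc), "exceeds barcode")
})

test_that("simulated runs conserve reads and are seed-deterministic", {
  al <- synthetic_allele_set(n = 4, seed = 42)
  bc <- synthetic_barcodes(2, seed = 7)
  co <- make_cohort(al, 2, bc, seed = 1)
  run <- simulate_run(co, al, bc, depth = 100, seed = 4)
  expect_equal(nrow(run$reads), 200)
  expect_equal(nrow(run$truth), 200)
  expect_setequal(run$reads$read_id, run$truth$read_id)
  expect_equal(as.integer(table(run$truth$sample_id)[co$sample_id]),
               c(100L, 100L))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_run(co, al, bc, depth = 15, seed = 9, out_fastq = f1)
  simulate_run(co, al, bc, depth = 15, seed = 9, out_fastq = f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical under a seed
  back <- read_fastq(f1)
  expect_equal(nrow(back), 30)
})

test_that("re-alignment measures a zero error rate on perfect reads", {
  al <- synthetic_allele_set(n = 2, seed = 42)
  m <- measure_error_rates(rep(al$seq[1], 3), al$seq[1])
  expect_equal(m$total_rate, 0)
  expect_equal(m$n_bases, 3 * 943)
})
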