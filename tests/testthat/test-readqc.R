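test_that("mean quality averages error probabilities, not Phred scores", {
  expect_equal(mean_read_quality(strrep("0", 12)), 15) # '0' is Q15
  # half Q10, half Q20: closed form -10 log10((1e-1 + 1e-2)/2)
  q <- paste0(strrep("+", 5), strrep("5", 5))
  expect_equal(mean_read_quality(q), -10 * log10((1e-1 + 1e-2) / 2),
               tolerance = 1e-12)
  expect_equal(round(mean_read_quality(q), 2), 12.6)
  expect_error(mean_read_quality(""), "empty")
  expect_error(mean_read_quality("AB"), "Phred")
})

test_that("quality/length filtering partitions reads with reasons", {
  rd <- tibble::tibble(
    read_id = c("good", "lowq", "short", "long"),
    seq = c(strrep("A", 1029), strrep("A", 1000), strrep("A", 200),
            strrep("A", 1500)),
    qual = c(strrep("5", 1029), strrep("+", 1000), strrep("5", 200),
             strrep("5", 1500)))
  out <- filter_reads(rd, min_q = 15)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$reason, c(NA, "quality", "length", "length"))
  # boundary: mean Q just below threshold fails on quality
  expect_false(filter_reads(tibble::tibble(
    read_id = "b", seq = strrep("A", 943),
    qual = paste0(strrep(".", 9), "+")), min_q = 15)$pass) # mean Q ~ 12.8
  # partition: pass + fail = input, disjoint
  expect_equal(sum(out$pass) + sum(!out$pass), nrow(rd))
})

test_that("filtering is idempotent and monotone in the threshold", {
  withr::local_seed(31)
  rd <- tibble::tibble(
    read_id = sprintf("r%d", 1:40),
    seq = vapply(1:40, function(i) random_dna(sample(700:1300, 1)), ""),
    qual = vapply(1:40, function(i) {
      strrep(intToUtf8(33 + sample(5:25, 1)), 0)
    }, ""))
  rd$qual <- vapply(seq_len(40), function(i) {
    strrep(intToUtf8(33 + sample(5:25, 1)), nchar(rd$seq[i]))
  }, "")
  once <- filter_reads(rd)
  passed <- once[once$pass, names(rd)]
  twice <- filter_reads(passed)
  expect_true(all(twice$pass))
  counts <- vapply(c(5, 10, 15, 20), function(q) {
    sum(filter_reads(rd, min_q = q)$pass)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("N50 satisfies its defining property", {
  expect_equal(compute_n50(1000), 1000)
  expect_equal(compute_n50(c(2, 2, 2, 6)), 6)
  expect_error(compute_n50(integer(0)), "empty")
  withr::local_seed(41)
  for (k in 1:20) {
    lens <- sample(50:2000, sample(3:60, 1), replace = TRUE)
    n50 <- compute_n50(lens)
    expect_equal(n50, compute_n50(sample(lens))) # permutation invariance
    # smallest L among observed lengths with sum(lengths >= L) >= total/2
    expect_gte(sum(lens[lens >= n50]), sum(lens) / 2)
    # minimality: any strictly larger threshold covers less than half
    larger <- lens[lens > n50]
    if (length(larger)) expect_lt(sum(larger), sum(lens) / 2)
  }
})

test_that("run statistics summarise a simulated run", {
  fx <- tiny_fixture()
  co <- make_cohort(fx$alleles, 2, fx$barcodes, seed = 2)
  run <- simulate_run(co, fx$alleles, fx$barcodes, depth = 30, seed = 3)
  st <- run_stats(run$reads)
  expect_equal(st$n_reads, 60)
  expect_gt(st$mean_length, 900)
  expect_lt(st$mean_length, 1100)
  expect_equal(st$n50, compute_n50(nchar(run$reads$seq)))
  g <- glance(st)
  expect_equal(g$n_reads, 60)
  expect_true(g$frac_pass_q >= 0 && g$frac_pass_q <= 1)
})
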