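# Independent quadratic DP edit-distance oracle (row-vectorised formulation,
# distinct from the package's C++ implementation). The query is aligned end
# to end; free_ref_ends = TRUE leaves reference overhangs uncharged.
oracle_sg_distance <- function(query, ref, free_ref_ends = TRUE) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  prev <- if (free_ref_ends) rep(0, m + 1) else 0:m
  for (i in seq_len(n)) {
    cost <- as.integer(q[i] != r)
    tmp <- pmin(prev[1:m] + cost, prev[2:(m + 1)] + 1) # diag / up into cols 1..m
    tmp <- c(prev[1] + 1, tmp)                         # col 0: up only
    # left-gap chain: cur[j] = j + cummin(tmp[j] - j) over 0..m
    js <- 0:m
    prev <- js + cummin(tmp - js)
    prev[1] <- i
  }
  if (free_ref_ends) min(prev) else prev[m + 1]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a standard two-sample test fixture: alleles, barcodes, cohort
tiny_fixture <- function(n_alleles = 6, seed = 42, ...) {
  al <- synthetic_allele_set(n = n_alleles, seed = seed, ...)
  bc <- synthetic_barcodes(max(4, n_alleles), seed = 7)
  list(alleles = al, barcodes = bc)
}
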