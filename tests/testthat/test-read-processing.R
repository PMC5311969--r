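test_that("quality trim follows the windowed 3' rule", {
  # high quality throughout: untouched
  tr <- quality_trim("ACGTACGT", rep(40L, 8), threshold_q = 20)
  expect_equal(tr$seq, "ACGTACGT")
  # uniformly bad: trimmed away entirely
  tr <- quality_trim("ACGTACGT", rep(2L, 8), threshold_q = 20)
  expect_equal(tr$seq, "")
  # the canonical mixed case: the failing terminal window of 4 is removed
  tr <- quality_trim("ACGTACGT", c(40L, 40L, 40L, 40L, 10L, 10L, 10L, 10L),
                     threshold_q = 20, window = 4)
  expect_equal(tr$seq, "ACGT")
  expect_equal(tr$qual, c(40L, 40L, 40L, 40L))
  # string qualities stay strings
  tr <- quality_trim("ACGTACGT", int_to_phred(c(40, 40, 40, 40, 10, 10, 10, 10)))
  expect_equal(tr$seq, "ACGT")
  expect_equal(tr$qual, int_to_phred(rep(40, 4)))
  # windows anchor at the 3' end; the 5'-most window may be shorter
  tr <- quality_trim("ACGTACG", c(40L, 40L, 40L, 40L, 2L, 2L, 2L))
  expect_equal(nchar(tr$seq), 3)
  tr2 <- quality_trim("ACG", c(2L, 2L, 2L))
  expect_equal(tr2$seq, "")
})

test_that("merge recovers amplicon geometry and resolves conflicts by quality", {
  set.seed(101)
  amp <- random_dna_str(550)
  s1 <- substr(amp, 1, 300)
  s2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 251, 550))))
  q <- strrep("I", 300)
  m <- merge_pair(s1, q, s2, q)
  expect_equal(nchar(m$sequence), 550)
  expect_equal(m$overlap_length, 50)
  expect_equal(m$mismatches_in_overlap, 0)
  expect_equal(m$sequence, amp)

  # identical reads: full overlap, merged length equals read length
  m2 <- merge_pair(s1, q, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s1))), q)
  expect_equal(nchar(m2$sequence), 300)
  expect_equal(m2$overlap_length, 300)

  # disagreement in the overlap: higher-quality base wins
  s1_err <- s1
  substr(s1_err, 260, 260) <- if (substr(s1, 260, 260) == "A") "C" else "A"
  q1 <- paste0(strrep("I", 259), "#", strrep("I", 40))   # low qual at error
  m3 <- merge_pair(s1_err, q1, s2, q)
  expect_equal(m3$mismatches_in_overlap, 1)
  expect_equal(m3$sequence, amp)  # mate 2's high-quality base restored it
  # reversed quality ordering keeps mate 1's erroneous base
  m4 <- merge_pair(s1_err, q, s2, gsub("I", "#", q))
  expect_equal(substr(m4$sequence, 260, 260), substr(s1_err, 260, 260))
  # quality tie keeps the mate-1 base with the min quality
  m5 <- merge_pair(s1_err, q, s2, q)
  expect_equal(substr(m5$sequence, 260, 260), substr(s1_err, 260, 260))

  # too-short reads reject with a reason
  short <- merge_pair("ACGTACGT", strrep("I", 8), "ACGTACGT", strrep("I", 8),
                      min_overlap = 20)
  expect_true(short$rejected)
  expect_equal(short$reason, "no_overlap")

  # heavy disagreement rejects on mismatch fraction
  noisy <- merge_pair(random_dna_str(100), strrep("I", 100),
                      random_dna_str(100), strrep("I", 100),
                      min_overlap = 90, max_mismatch_fraction = 0.1)
  expect_true(noisy$rejected)
  expect_equal(noisy$reason, "mismatch")
})

test_that("merge agrees with an exhaustive overlap-scan oracle", {
  set.seed(202)
  for (rep in 1:25) {
    n1 <- sample(40:80, 1)
    n2 <- sample(40:80, 1)
    s1 <- random_dna_str(n1)
    s2rc <- paste0(substr(s1, max(1, n1 - 29), n1), random_dna_str(n2 - 30))
    # a couple of substitutions inside the copied region
    for (p in sample(1:20, 2)) {
      substr(s2rc, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    oracle <- merge_oracle(s1, s2rc, min_overlap = 10)
    m <- merge_pair(s1, strrep("I", n1),
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(s2rc))),
                    strrep("I", n2), min_overlap = 10,
                    max_mismatch_fraction = 1)
    expect_equal(m$overlap_length, oracle$o)
    expect_equal(m$mismatches_in_overlap, oracle$mm)
    expect_equal(nchar(m$sequence), n1 + n2 - oracle$o)
  }
})

test_that("length filter is a strict boundary and monotone", {
  expect_false(length_filter(450))
  expect_true(length_filter(451))
  expect_true(length_filter(550))
  lens <- sort(sample(440:460, 15, replace = TRUE))
  keep <- length_filter(lens)
  # monotone: once kept, longer reads stay kept
  expect_true(all(diff(as.integer(keep)) >= 0))
})

test_that("read accounting balances at every stage", {
  lib <- simulate_reference(sim_config(n_families = 3, genera_per_family = 2,
                                       species_per_genus = 1, seed = 44))
  taxa <- lib$species[1:3]
  mx <- truth_mixture("s", geometric_mixture(taxa), n_read_pairs = 200,
                      error_rate = 0.02, seed = 6)
  sim <- simulate_reads(lib, mx)
  proc <- process_reads(sim$pairs)
  acc <- proc$accounting
  expect_equal(acc$pairs_in, acc$merged + acc$rejected)
  expect_equal(acc$merged, acc$kept + acc$length_filtered)
  expect_equal(nrow(proc$merged), acc$kept)
  expect_equal(nrow(proc$rejected), acc$rejected)
  expect_true(all(nchar(proc$merged$sequence) > 450))
})

test_that("short-amplicon libraries are removed by the length filter", {
  lib <- simulate_reference(sim_config(n_families = 2, genera_per_family = 1,
                                       species_per_genus = 1,
                                       amplicon_length = 440, seed = 3))
  mx <- truth_mixture("s", setNames(1, lib$species[1]), n_read_pairs = 25,
                      error_rate = 0, seed = 2)
  sim <- simulate_reads(lib, mx)
  proc <- process_reads(sim$pairs)
  expect_equal(proc$accounting$kept, 0)
  expect_equal(proc$accounting$length_filtered, 25)
})
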