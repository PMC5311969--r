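test_that("FASTA reading preserves order, uppercases, and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqB some description", "acgtacgt",
               ">seqA", "GGGTTTNC"), path)
  fa <- read_fasta(path)
  expect_equal(fa$seq_id, c("seqB", "seqA"))
  expect_equal(fa$sequence, c("ACGTACGT", "GGGTTTNC"))

  writeLines(c(">s1", "ACGT", ">s2", ""), path)
  expect_error(read_fasta(path), "empty sequence")

  writeLines(c(">s1", "ACXT"), path)
  expect_error(read_fasta(path), "illegal character")

  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("FASTA round-trips exactly", {
  lib <- tiny_library()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(lib, path)
  back <- read_fasta(path)
  expect_equal(back$seq_id, lib$seq_id)
  expect_equal(back$sequence, lib$sequence)
})

test_that("paired FASTQ reading pairs by position and validates ids", {
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@p1/1", "ACGT", "+", "IIII",
               "@p2/1", "GGCC", "+", "!!!!",
               "@p3/1", "TTAA", "+", "IJKL"), r1)
  writeLines(c("@p1/2", "TTTT", "+", "IIII",
               "@p2/2", "CCGG", "+", "####",
               "@p3/2", "AATT", "+", "LKJI"), r2)
  batch <- read_fastq_pairs(r1, r2)
  expect_equal(nrow(batch), 3)
  expect_equal(batch$read_id, c("p1", "p2", "p3"))
  # Phred+33: 'I' is 40, '!' is 0
  expect_equal(phred_to_int(batch$qual1[1])[[1]], rep(40, 4))
  expect_equal(phred_to_int(batch$qual1[2])[[1]], rep(0, 4))

  writeLines(c("@p1/2", "TTTT", "+", "IIII"), r2)
  expect_error(read_fastq_pairs(r1, r2), "record-count mismatch")

  writeLines(c("@p1/2", "TTTT", "+", "IIII",
               "@px/2", "CCGG", "+", "####",
               "@p3/2", "AATT", "+", "LKJI"), r2)
  expect_error(read_fastq_pairs(r1, r2), "id mismatch")
})

test_that("paired FASTQ round-trips exactly", {
  lib <- tiny_library()
  mx <- truth_mixture("s1", geometric_mixture(unique(lib$genus)[1:2]),
                      n_read_pairs = 20, error_rate = 0.01, seed = 3)
  sim <- simulate_reads(lib, mx, read_length = 50)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(sim$pairs, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_equal(as.data.frame(back), as.data.frame(sim$pairs))
})

test_that("taxonomy table validates keys and required ranks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lib <- tiny_library()
  write_taxonomy_table(lib, path)
  tax <- read_taxonomy_table(path)
  expect_equal(tax$seq_id, lib$seq_id)
  expect_equal(tax$family, lib$family)

  writeLines(c("seq_id\tspecies\tgenus\tfamily",
               "a\tX y\tX\tF", "a\tX z\tX\tF"), path)
  expect_error(read_taxonomy_table(path), "duplicate")

  writeLines(c("seq_id\tspecies\tgenus\tfamily",
               "a\tX y\tX\t"), path)
  expect_error(read_taxonomy_table(path), "missing genus or family")

  writeLines(c("seq_id\tspecies\tgenus", "a\tX y\tX"), path)
  expect_error(read_taxonomy_table(path), "missing required column")
})

test_that("reference_library rejects sequences without taxonomy rows", {
  lib <- tiny_library()
  expect_error(reference_library(lib[, c("seq_id", "sequence")],
                                 lib[-1, c("seq_id", "species", "genus", "family")]),
               lib$seq_id[1])
  ok <- reference_library(lib[, c("seq_id", "sequence")],
                          lib[, c("seq_id", "species", "genus", "family")])
  expect_equal(ok$seq_id, lib$seq_id)
})

test_that("checklist codes are validated and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cl <- tibble::tibble(taxon = c("Salix", "Taraxacum officinale"),
                       status = c("native", "both"),
                       habitat = c("W", "G"),
                       growth_form = c("W", "H"),
                       use = c("NP", "N"))
  write_checklist(cl, path)
  expect_equal(as.data.frame(read_checklist(path)), as.data.frame(cl))

  bad <- cl; bad$status[1] <- "alien"
  write_checklist(bad, path)
  expect_error(read_checklist(path), "invalid status")

  bad <- cl; bad$use[1] <- "NX"
  write_checklist(bad, path)
  expect_error(read_checklist(path), "invalid use")

  bad <- cl; bad$taxon <- c("Salix", "Salix")
  write_checklist(bad, path)
  expect_error(read_checklist(path), "duplicate")
})

test_that("survey tables group zones and months, enforce area consistency", {
  path <- withr::local_tempfile(fileext = ".tsv")
  sv <- tibble::tibble(zone_id = c("Z1", "Z1", "Z2", "Z2", "Z1"),
                       area_m2 = c(100, 100, 250, 250, 100),
                       habitat_class = c("G", "G", "W", "W", "G"),
                       month = c("April", "May", "April", "May", "April"),
                       taxon = c("Salix", "Salix", "Quercus", "Acer", "Salix"))
  write_survey_table(sv, path)
  survey <- read_survey_tables(path)
  # duplicate Z1/April/Salix row collapses: set semantics
  expect_equal(nrow(survey), 4)
  expect_equal(nrow(survey_zones(survey)), 2)

  bad <- sv; bad$area_m2[2] <- 120
  write_survey_table(bad, path)
  expect_error(read_survey_tables(path), "conflicting areas")

  bad <- sv; bad$month[1] <- "January"
  write_survey_table(bad, path)
  expect_error(read_survey_tables(path), "unknown month")
})
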