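test_that("sim_config validates divergence ordering and ranges", {
  expect_error(sim_config(d_family = 0.02, d_genus = 0.06), "d_family > d_genus")
  expect_error(sim_config(d_family = 0.6), "0, 0.5")
  expect_error(sim_config(d_species = -0.1), "0, 0.5")
  expect_silent(sim_config(d_species = 0))
})

test_that("simulated reference has the configured shape and hierarchy", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2,
                    species_per_genus = 2, amplicon_length = 400, seed = 7)
  lib <- simulate_reference(cfg)
  expect_equal(nrow(lib), 8)
  expect_equal(length(unique(lib$family)), 2)
  expect_equal(length(unique(lib$genus)), 4)
  expect_false(anyDuplicated(lib$seq_id) > 0)

  # d_species = 0 limit: congeneric species are identical
  lib0 <- simulate_reference(sim_config(n_families = 1, genera_per_family = 2,
                                        species_per_genus = 3,
                                        amplicon_length = 200,
                                        d_species = 0, seed = 5))
  for (g in unique(lib0$genus)) {
    expect_equal(length(unique(lib0$sequence[lib0$genus == g])), 1)
  }
})

test_that("pairwise identity is graded congeneric > confamilial > cross-family", {
  lib <- simulate_reference(sim_config(seed = 11))
  n <- nrow(lib)
  idg <- c(); idf <- c(); idx <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      id <- pairwise_identity(lib$sequence[i], lib$sequence[j])
      if (lib$genus[i] == lib$genus[j]) idg <- c(idg, id)
      else if (lib$family[i] == lib$family[j]) idf <- c(idf, id)
      else idx <- c(idx, id)
    }
  }
  expect_gt(mean(idg), mean(idf))
  expect_gt(mean(idf), mean(idx))
  expect_lt(mean(idx), 0.5)  # cross-family at the random baseline
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 9)
  expect_identical(simulate_reference(cfg), simulate_reference(cfg))
  lib <- tiny_library()
  mx <- truth_mixture("s", geometric_mixture(unique(lib$genus)),
                      n_read_pairs = 50, error_rate = 0.01, seed = 13)
  a <- simulate_reads(lib, mx, read_length = 60)
  b <- simulate_reads(lib, mx, read_length = 60)
  expect_identical(as.data.frame(a$pairs), as.data.frame(b$pairs))

  zones <- default_zones(seed = 2)
  wins <- list(Salix = c("April", "May"), Acer = "May")
  expect_identical(simulate_survey(zones, wins, seed = 4),
                   simulate_survey(zones, wins, seed = 4))
})

test_that("truth_mixture enforces its invariants", {
  expect_error(truth_mixture("s", c(A = 0.7, B = 0.2)), "sum to 1")
  expect_error(truth_mixture("s", c(A = 1.2, B = -0.2)), "non-negative")
  expect_error(truth_mixture("s", c(A = 1), n_read_pairs = 0), "n_read_pairs")
})

test_that("error-free reads from one taxon merge back to the exact amplicons", {
  lib <- simulate_reference(sim_config(n_families = 2, genera_per_family = 1,
                                       species_per_genus = 1, seed = 21))
  taxon <- lib$species[1]
  mx <- truth_mixture("s", setNames(1, taxon), n_read_pairs = 30,
                      error_rate = 0, seed = 8)
  sim <- simulate_reads(lib, mx)
  proc <- process_reads(sim$pairs)
  expect_equal(nrow(proc$merged), 30)
  expect_true(all(proc$merged$sequence == lib$sequence[1]))
  expect_true(all(proc$merged$overlap_length == 50))
  expect_true(all(proc$merged$mismatches_in_overlap == 0))
})

test_that("realized taxon draws replay from the sample seed", {
  lib <- tiny_library()
  taxa <- unique(lib$genus)[1:2]
  mx <- truth_mixture("s", setNames(c(0.6, 0.4), taxa),
                      n_read_pairs = 1000, error_rate = 0, seed = 77)
  sim <- simulate_reads(lib, mx, read_length = 50)
  replay <- withr::with_seed(77L, sample(taxa, 1000, replace = TRUE,
                                         prob = c(0.6, 0.4)))
  expect_identical(sim$source_taxon, replay)
})

test_that("mixture taxa must resolve against the reference", {
  lib <- tiny_library()
  mx <- truth_mixture("s", c(Ranunculus = 1), seed = 1)
  expect_error(simulate_reads(lib, mx, read_length = 50), "absent from reference")
  mx2 <- truth_mixture("s", setNames(1, lib$species[1]), seed = 1)
  expect_error(simulate_reads(lib, mx2, read_length = 100),
               "amplicon shorter")
})

test_that("realized proportions converge to truth at 10,000 pairs", {
  lib <- simulate_reference(sim_config(seed = 31))
  taxa <- vapply(unique(lib$genus)[1:10],
                 function(g) lib$species[lib$genus == g][1], "")
  mx <- truth_mixture("s", geometric_mixture(taxa), n_read_pairs = 10000,
                      error_rate = 0, seed = 19)
  sim <- simulate_reads(lib, mx)
  realized <- table(factor(sim$source_taxon, levels = taxa)) / 10000
  expect_lt(max(abs(100 * (as.numeric(realized) - unname(mx$proportions)))), 2)
})

test_that("simulated survey respects windows, zones and areas", {
  zones <- tibble::tibble(zone_id = c("Z1", "Z2", "Z3"),
                          area_m2 = c(100, 250, 500),
                          habitat_class = c("G", "W", "H"))
  wins <- list("Salix" = c("April", "May"), "Acer" = "April",
               "Hedera helix" = character(0))
  assign <- list("Salix" = c("Z1", "Z2", "Z3"), "Acer" = "Z2",
                 "Hedera helix" = c("Z1"))
  sv <- simulate_survey(zones, wins, assign)
  # April-only taxon absent from May records
  expect_false(any(sv$taxon == "Acer" & sv$month == "May"))
  # empty window: never recorded
  expect_false(any(sv$taxon == "Hedera helix"))
  # all-zone taxon occupies the full surveyed area
  expect_equal(area_of_occurrence(sv, "Salix", "April"), 850)
  expect_equal(area_of_occurrence(sv, "Acer", "April"), 250)

  # genera-per-m2 equals an independent recount
  dens <- density_per_area(sv, "April")
  for (i in seq_len(nrow(dens))) {
    z <- dens$zone_id[i]
    hand <- length(unique(sv$taxon[sv$zone_id == z & sv$month == "April"]))
    expect_equal(dens$n_genera[i], hand)
    expect_equal(dens$genera_per_m2[i], hand / dens$area_m2[i])
  }
})

test_that("a full simulated study is internally consistent", {
  study <- simulate_study(seed = 5, n_read_pairs = 40, error_rate = 0.002)
  expect_equal(nrow(study$samples), 6)
  expect_equal(sort(names(study$reads)), sort(study$samples$sample_id))
  expect_equal(sum(study$zones$area_m2), 342000)
  # every mixture taxon flowers in both months
  av <- availability(study$survey, study$library)
  for (sid in study$samples$sample_id) {
    tr <- study$truth[study$truth$sample_id == sid, ]
    expect_equal(sum(tr$true_proportion), 1, tolerance = 1e-9)
    genera <- genus_token(tolower(tr$taxon))
    for (m in c("April", "May")) {
      pool <- av$taxa[av$month == m & av$rank == "genus"][[1]]
      expect_true(all(genera %in% pool))
    }
  }
})
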