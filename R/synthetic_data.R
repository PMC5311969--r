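#' Simulation configuration for a hierarchical reference library
#'
#' The generator emulates the hierarchical structure of a plant barcode
#' reference library: one ancestral amplicon per family (uniform over
#' {A,C,G,T}), genus ancestors derived from their family ancestor by
#' independent per-site substitution with probability `d_genus`, and species
#' sequences derived from their genus ancestor with probability `d_species`.
#' Congeneric sequences are therefore more similar than confamilial ones,
#' and cross-family identity is at the random-sequence baseline.
#'
#' @param n_families,genera_per_family,species_per_genus library shape.
#' @param amplicon_length amplicon length in bp. The default (550) exceeds
#'   the 450 bp downstream length filter so that perfect merges pass; pass a
#'   value of 450 or less to exercise filter rejection.
#' @param read_length sequencing read length in bp (2 x 300 dialect).
#' @param d_family,d_genus,d_species per-site divergence probabilities; must
#'   lie in (0, 0.5), satisfy `d_family > d_genus > d_species`, and
#'   `d_species` may be exactly 0 (identical congeneric species).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 6, genera_per_family = 3,
                       species_per_genus = 2, amplicon_length = 550,
                       read_length = 300,
                       d_family = 0.25, d_genus = 0.06, d_species = 0.02,
                       seed = 1) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            amplicon_length >= 1, read_length >= 1)
  d <- c(d_family = d_family, d_genus = d_genus, d_species = d_species)
  if (any(d < 0) || any(d >= 0.5) || d_genus == 0) {
    stop_fmt("divergence probabilities must lie in (0, 0.5); d_species may be 0 (identical congeneric species)")
  }
  if (!(d_family > d_genus && d_genus > d_species)) {
    stop_fmt("divergence probabilities must satisfy d_family > d_genus > d_species")
  }
  structure(list(n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 amplicon_length = amplicon_length,
                 read_length = read_length,
                 d_family = d_family, d_genus = d_genus,
                 d_species = d_species, seed = as.integer(seed)),
            class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Independent per-site substitution with probability p, uniform over the
# three alternative bases. d_species = 0 would return the input unchanged.
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit) > 0) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((match(chars[hit], DNA_BASES) - 1 + shift) %% 4) + 1]
  }
  paste(chars, collapse = "")
}

#' Simulate a hierarchical reference library
#'
#' @param config a [sim_config()].
#' @return a `reference_library` tibble (`seq_id`, `sequence`, `species`,
#'   `genus`, `family`); deterministic given `config$seed`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rows <- list()
    idx <- 0L
    for (f in seq_len(config$n_families)) {
      family <- sprintf("Family%02d", f)
      fam_anc <- random_dna(config$amplicon_length)
      for (g in seq_len(config$genera_per_family)) {
        genus <- sprintf("Genus%02d%02d", f, g)
        gen_anc <- mutate_sequence(fam_anc, config$d_genus)
        for (s in seq_len(config$species_per_genus)) {
          idx <- idx + 1L
          species <- sprintf("%s species%02d", genus, s)
          rows[[idx]] <- tibble(
            seq_id = sprintf("ref%04d", idx),
            sequence = mutate_sequence(gen_anc, config$d_species),
            species = species, genus = genus, family = family)
        }
      }
    }
    lib <- bind_rows(rows)
    class(lib) <- c("reference_library", class(tibble()))
    lib
  })
}

#' Define a known mixture for one simulated honey sample
#'
#' @param sample_id sample label (e.g. "hiveA_April").
#' @param proportions named numeric vector of true taxon proportions
#'   (fractions summing to 1); names are species or genus labels resolvable
#'   against the reference library.
#' @param n_read_pairs number of read pairs to simulate.
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed for this sample.
#' @return a `truth_mixture` list.
#' @export
truth_mixture <- function(sample_id, proportions, n_read_pairs = 10000,
                          error_rate = 0.005, seed = 1) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)),
            n_read_pairs >= 1, error_rate >= 0, error_rate < 0.75)
  if (any(proportions < 0)) stop_fmt("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop_fmt("proportions must sum to 1 (got %.12f)", sum(proportions))
  }
  structure(list(sample_id = sample_id, proportions = proportions,
                 n_read_pairs = as.integer(n_read_pairs),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "truth_mixture")
}

#' Geometric mixture proportions
#'
#' Few-dominant-taxa profile: p_i proportional to `r^i`, normalized. With the
#' default ratio 0.5 and ten taxa, the leading taxon holds about half of the
#' reads and the tail taxa fall below the 1 percent major/minor threshold.
#'
#' @param taxa character vector of taxon labels, most abundant first.
#' @param r geometric ratio in (0, 1).
#' @return named numeric vector summing to 1.
#' @export
geometric_mixture <- function(taxa, r = 0.5) {
  stopifnot(r > 0, r < 1, length(taxa) >= 1)
  p <- r^seq_along(taxa)
  setNames(p / sum(p), taxa)
}

# Quality scores drawn from a two-point mix {q0-4, q0+4} around the Phred
# equivalent of error_rate, with the mixing weight chosen so the expected
# per-base error probability equals error_rate exactly.
quality_scheme <- function(error_rate) {
  if (error_rate <= 0) {
    return(list(q = c(40L, 40L), w = 1))
  }
  q0 <- round(-10 * log10(error_rate))
  q_lo <- max(2L, q0 - 4L)
  q_hi <- min(41L, q0 + 4L)
  p_lo <- 10^(-q_lo / 10)
  p_hi <- 10^(-q_hi / 10)
  w <- if (q_lo == q_hi) 1 else (error_rate - p_hi) / (p_lo - p_hi)
  w <- min(1, max(0, w))
  list(q = c(q_lo, q_hi), w = w)
}

#' Simulate paired reads from a reference library and a known mixture
#'
#' Per pair: the taxon is drawn by its true proportion, one of its reference
#' sequences is picked uniformly, mate 1 is the first `read_length` bases of
#' the amplicon and mate 2 the reverse complement of the last `read_length`
#' bases. Each sequenced base carries a quality score drawn so that its
#' implied error probability averages `error_rate`, and is substituted
#' (uniformly over the three alternatives) with exactly that probability.
#' Deterministic given `truth$seed`; the taxon draw is the first use of the
#' RNG stream.
#'
#' @param library a `reference_library`.
#' @param truth a [truth_mixture()].
#' @param read_length read length in bp; every amplicon must be at least this
#'   long.
#' @return list with `pairs` (a read-pair batch tibble) and `truth` (a tibble
#'   `sample_id`, `taxon`, `true_proportion`).
#' @export
simulate_reads <- function(library, truth, read_length = 300) {
  stopifnot(inherits(truth, "truth_mixture"))
  taxa <- names(truth$proportions)
  lib_species <- normalize_label(library$species)
  lib_genus <- normalize_label(library$genus)
  refs_for <- lapply(normalize_label(taxa), function(t) {
    hits <- which(lib_species == t)
    if (length(hits) == 0) hits <- which(lib_genus == t)
    hits
  })
  unresolved <- taxa[vapply(refs_for, length, 1L) == 0]
  if (length(unresolved) > 0) {
    stop_fmt("mixture taxa absent from reference library: %s",
             paste(unresolved, collapse = ", "))
  }
  if (any(nchar(library$sequence) < read_length)) {
    stop_fmt("amplicon shorter than read_length (%d bp)", read_length)
  }

  n <- truth$n_read_pairs
  with_seed(truth$seed, {
    taxon_draw <- sample(taxa, n, replace = TRUE, prob = truth$proportions)
    ref_idx <- vapply(match(taxon_draw, taxa), function(i) {
      cand <- refs_for[[i]]
      if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    }, 1L)
    amplicon <- library$sequence[ref_idx]
    amp_len <- nchar(amplicon)
    seq1 <- substr(amplicon, 1L, read_length)
    seq2 <- revcomp(substr(amplicon, amp_len - read_length + 1L, amp_len))

    scheme <- quality_scheme(truth$error_rate)
    seq1_q <- sequencing_errors(seq1, scheme, read_length)
    seq2_q <- sequencing_errors(seq2, scheme, read_length)

    pairs <- tibble(
      read_id = sprintf("%s_read%06d", truth$sample_id, seq_len(n)),
      seq1 = seq1_q$seq, qual1 = seq1_q$qual,
      seq2 = seq2_q$seq, qual2 = seq2_q$qual)
    attr(pairs, "quality_offset") <- 33L
    truth_tab <- tibble(sample_id = truth$sample_id, taxon = taxa,
                        true_proportion = unname(truth$proportions))
    list(pairs = pairs, truth = truth_tab,
         source_taxon = taxon_draw, source_ref = library$seq_id[ref_idx])
  })
}

# Draw per-base qualities and apply quality-implied substitution errors.
sequencing_errors <- function(seqs, scheme, read_length) {
  n <- length(seqs)
  total <- n * read_length
  q <- ifelse(runif(total) < scheme$w, scheme$q[1], scheme$q[2])
  err <- which(runif(total) < 10^(-q / 10))
  if (length(err) > 0) {
    ri <- ((err - 1L) %/% read_length) + 1L
    pos <- ((err - 1L) %% read_length) + 1L
    shift <- sample.int(3, length(err), replace = TRUE)
    for (j in seq_along(err)) {
      base <- substr(seqs[ri[j]], pos[j], pos[j])
      alt <- DNA_BASES[((match(base, DNA_BASES) - 1 + shift[j]) %% 4) + 1]
      substr(seqs[ri[j]], pos[j], pos[j]) <- alt
    }
  }
  qm <- matrix(as.integer(q), nrow = n, byrow = TRUE)
  qual <- vapply(seq_len(n), function(i) int_to_phred(qm[i, ]), "")
  list(seq = seqs, qual = qual)
}

#' Default survey-zone layout
#'
#' Twenty zones whose areas sum to 342,000 m2 (34.2 ha), with habitat classes
#' drawn to approximate a garden dominated by grassland with woodland and
#' horticultural plantings.
#'
#' @param n_zones number of zones.
#' @param total_area_m2 total surveyed area.
#' @param seed integer RNG seed.
#' @return tibble `zone_id`, `area_m2`, `habitat_class`.
#' @export
default_zones <- function(n_zones = 20, total_area_m2 = 342000, seed = 1) {
  with_seed(seed, {
    raw <- exp(rnorm(n_zones, 0, 0.6))
    area <- round(raw / sum(raw) * total_area_m2)
    area[n_zones] <- total_area_m2 - sum(area[-n_zones])
    tibble(zone_id = sprintf("Z%02d", seq_len(n_zones)),
           area_m2 = area,
           habitat_class = sample(c("W", "G", "H"), n_zones, replace = TRUE,
                                  prob = c(0.15, 0.72, 0.13)))
  })
}

#' Simulate a floral survey
#'
#' A taxon appears in a zone-month record iff the month is in its flowering
#' window and the zone is in its assigned zone set.
#'
#' @param zones tibble `zone_id`, `area_m2`, `habitat_class`.
#' @param flowering_windows named list: taxon -> character vector of months
#'   in flower.
#' @param zone_assignments named list: taxon -> zone ids where it grows; if
#'   `NULL`, each taxon is assigned a seeded random non-empty zone subset.
#' @param months survey months.
#' @param seed RNG seed (used only when `zone_assignments` is `NULL`).
#' @return a survey tibble as from [read_survey_tables()].
#' @export
simulate_survey <- function(zones, flowering_windows, zone_assignments = NULL,
                            months = c("April", "May"), seed = 1) {
  taxa <- names(flowering_windows)
  stopifnot(length(taxa) > 0)
  bad <- taxa[!vapply(flowering_windows, function(w) all(w %in% months), TRUE)]
  if (length(bad) > 0) {
    stop_fmt("flowering window outside survey months for: %s",
             paste(bad, collapse = ", "))
  }
  if (is.null(zone_assignments)) {
    zone_assignments <- with_seed(seed, {
      setNames(lapply(taxa, function(t) {
        k <- sample.int(nrow(zones), 1)
        sort(sample(zones$zone_id, k))
      }), taxa)
    })
  }
  rows <- lapply(taxa, function(t) {
    w <- flowering_windows[[t]]
    z <- zone_assignments[[t]]
    if (length(w) == 0 || length(z) == 0) return(NULL)
    tidyr::expand_grid(zone_id = z, month = w, taxon = t)
  })
  out <- bind_rows(rows)
  out <- left_join(out, zones, by = "zone_id")
  out <- arrange(out, zone_id, month, taxon)
  out <- out[, c("zone_id", "area_m2", "habitat_class", "month", "taxon")]
  attr(out, "months") <- months
  distinct(out)
}

#' Simulate a complete multi-hive, two-month study
#'
#' Builds the full set of pipeline inputs with known ground truth: a
#' hierarchical reference library, a regional checklist covering every
#' library taxon, a 20-zone floral survey, and per hive x month read sets.
#' Each sample is a ten-taxon geometric mixture (ratio `mixture_r`) over
#' species from distinct genera; all hives share the month's mixture, and the
#' May ranking is a rotation of April's so both months remain geometric. All
#' mixture taxa flower in both survey months, so detections are concordant
#' with phenology by construction; the remaining library taxa receive random
#' windows and mostly horticultural checklist statuses, while mixture taxa
#' are native or near-native, emulating the major/minor status contrast.
#'
#' @param seed master RNG seed; all sample seeds derive from it.
#' @param config a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param n_truth_taxa number of taxa in each sample's mixture.
#' @param mixture_r geometric ratio of the mixture.
#' @param n_read_pairs read pairs per sample.
#' @param error_rate per-base substitution probability.
#' @param hives hive labels.
#' @param months month labels (first is treated as the earlier month).
#' @return list with elements `config`, `library`, `checklist`, `zones`,
#'   `survey`, `samples` (tibble sample_id/hive/month/seed), `mixtures`,
#'   `reads` (named list of read-pair batches), `truth` (combined tibble).
#' @export
simulate_study <- function(seed = 1, config = NULL, n_truth_taxa = 10,
                           mixture_r = 0.5, n_read_pairs = 10000,
                           error_rate = 0.005, hives = c("A", "B", "C"),
                           months = c("April", "May")) {
  if (is.null(config)) config <- sim_config(seed = seed)
  library <- simulate_reference(config)
  genera <- unique(library$genus)
  if (length(genera) < n_truth_taxa) {
    stop_fmt("library has %d genera; %d mixture taxa requested",
             length(genera), n_truth_taxa)
  }

  with_seed(seed + 1L, {
    truth_genera <- sample(genera, n_truth_taxa)
    truth_taxa <- vapply(truth_genera, function(g) {
      library$species[library$genus == g][1]
    }, "")
    other_taxa <- setdiff(library$species, truth_taxa)

    status <- c(
      setNames(rep(c("native", "both"), length.out = n_truth_taxa), truth_taxa),
      setNames(sample(c("horticulture", "native", "both"), length(other_taxa),
                      replace = TRUE, prob = c(0.7, 0.2, 0.1)), other_taxa))
    all_taxa <- c(truth_taxa, other_taxa)
    checklist <- tibble(
      taxon = all_taxa,
      status = unname(status[all_taxa]),
      habitat = sample(c("W", "G", "H"), length(all_taxa), replace = TRUE),
      growth_form = sample(c("W", "H", "B"), length(all_taxa), replace = TRUE),
      use = sample(c("NP", "N", "P"), length(all_taxa), replace = TRUE,
                   prob = c(0.6, 0.2, 0.2)))

    windows <- c(
      setNames(rep(list(months), n_truth_taxa), truth_taxa),
      setNames(lapply(other_taxa, function(t) {
        list(months[1], months[2], months)[[sample.int(3, 1)]]
      }), other_taxa))
    zones <- default_zones(seed = seed + 2L)
    survey <- simulate_survey(zones, windows, months = months, seed = seed + 3L)

    mix_april <- geometric_mixture(truth_taxa, mixture_r)
    shift <- min(3L, n_truth_taxa - 1L)  # May ranking: rotation of April's
    rot <- ((seq_len(n_truth_taxa) - 1L + shift) %% n_truth_taxa) + 1L
    mix_may <- geometric_mixture(truth_taxa[rot], mixture_r)
    month_mixture <- setNames(list(mix_april, mix_may), months)

    samples <- tidyr::expand_grid(hive = hives, month = months)
    samples$sample_id <- sprintf("hive%s_%s", samples$hive, samples$month)
    samples$seed <- sample.int(2^31 - 1, nrow(samples))
    samples <- as_tibble(samples[, c("sample_id", "hive", "month", "seed")])
  })

  mixtures <- list()
  reads <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    mx <- truth_mixture(sid, month_mixture[[samples$month[i]]],
                        n_read_pairs = n_read_pairs,
                        error_rate = error_rate, seed = samples$seed[i])
    sim <- simulate_reads(library, mx, read_length = config$read_length)
    mixtures[[sid]] <- mx
    reads[[sid]] <- sim$pairs
    truth_rows[[sid]] <- sim$truth
  }

  list(config = config, library = library, checklist = checklist,
       zones = zones, survey = survey, samples = samples,
       mixtures = mixtures, reads = reads, truth = bind_rows(truth_rows))
}
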