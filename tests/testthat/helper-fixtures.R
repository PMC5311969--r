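# Shared fixtures and independent oracles, built in code.

tiny_library <- function(seed = 42) {
  simulate_reference(sim_config(n_families = 2, genera_per_family = 2,
                                species_per_genus = 2, amplicon_length = 80,
                                seed = seed))
}

# A hand-written taxonomy for assignment tests (no sequences needed).
rosaceae_taxonomy <- function() {
  tibble::tribble(
    ~seq_id, ~species,                ~genus,        ~family,
    "r1",    "Malus sylvestris",      "Malus",       "Rosaceae",
    "r2",    "Malus domestica",       "Malus",       "Rosaceae",
    "r3",    "Cotoneaster integrifolius", "Cotoneaster", "Rosaceae",
    "r4",    "Crataegus monogyna",    "Crataegus",   "Rosaceae",
    "r5",    "Prunus spinosa",        "Prunus",      "Rosaceae",
    "r6",    "Salix caprea",          "Salix",       "Salicaceae",
    "r7",    "",                      "Salix",       "Salicaceae",
    "r8",    "Quercus robur",         "Quercus",     "Fagaceae")
}

# Brute-force lowest-common-rank oracle: walk the distinct taxonomy triples
# of a tie set rank by rank, independent of assign()'s collapsing logic.
lcr_oracle <- function(seq_ids, taxonomy) {
  rows <- unique(taxonomy[match(seq_ids, taxonomy$seq_id),
                          c("species", "genus", "family")])
  if (length(unique(rows$family)) > 1) return("unknown")
  if (length(unique(rows$genus)) > 1) return("family")
  sp <- unique(rows$species)
  if (length(sp) == 1 && all(sp != "")) "species" else "genus"
}

# Random taxonomy over f families, g genera each, s species each.
random_taxonomy <- function(f, g, s) {
  rows <- expand.grid(fi = seq_len(f), gi = seq_len(g), si = seq_len(s))
  tibble::tibble(
    seq_id = sprintf("t%03d", seq_len(nrow(rows))),
    species = sprintf("G%d_%d species%d", rows$fi, rows$gi, rows$si),
    genus = sprintf("G%d_%d", rows$fi, rows$gi),
    family = sprintf("F%d", rows$fi))
}

# Exhaustive overlap-scan merge oracle in plain R: scores every admissible
# overlap as matches minus mismatches, ties toward the longer overlap.
merge_oracle <- function(s1, s2rc, min_overlap) {
  n1 <- nchar(s1); n2 <- nchar(s2rc)
  omax <- min(n1, n2)
  if (omax < min_overlap) return(NULL)
  best <- NULL
  for (o in min_overlap:omax) {
    a <- strsplit(substr(s1, n1 - o + 1, n1), "")[[1]]
    b <- strsplit(substr(s2rc, 1, o), "")[[1]]
    mm <- sum(a != b)
    score <- o - 2 * mm
    if (is.null(best) || score > best$score ||
        (score == best$score && o > best$o)) {
      best <- list(o = o, mm = mm, score = score)
    }
  }
  best
}

# Per-base identity of two equal-length sequences.
pairwise_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Biostrings local alignment score with the package's scoring scheme,
# used as the independent alignment oracle.
biostrings_local_score <- function(a, b, match = 1, mismatch = -2,
                                   gap_open = 2, gap_extend = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend))
}

# Composition built directly from counts, for unit tests.
comp_from_counts <- function(counts, hive = "A", month = "April") {
  tc <- tibble::tibble(label = names(counts), rank = "genus",
                       family = NA_character_,
                       genus_group = as.list(names(counts)),
                       n_reads = as.integer(counts))
  proportions(tc, hive, month)
}
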