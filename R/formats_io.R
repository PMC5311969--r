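#' Read a reference FASTA file
#'
#' Loads DNA sequences for the reference library. Sequence ids are the first
#' whitespace-delimited token of each header; bases are uppercased on load
#' and must be drawn from {A, C, G, T, N}.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `seq_id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop_fmt("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  seq_id <- unname(sub("\\s.*$", "", names(set)))
  sequence <- unname(toupper(as.character(set)))
  empty <- which(nchar(sequence) == 0)
  if (length(empty) > 0) {
    stop_fmt("empty sequence record in %s near line %d (record '%s')",
             path, fasta_record_line(path, empty[1]), seq_id[empty[1]])
  }
  bad <- which(grepl("[^ACGTN]", sequence))
  if (length(bad) > 0) {
    stop_fmt("illegal character in sequence of record '%s' near line %d in %s",
             seq_id[bad[1]], fasta_record_line(path, bad[1]), path)
  }
  if (anyDuplicated(seq_id)) {
    stop_fmt("duplicate sequence ids in %s: %s", path,
             paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  }
  tibble(seq_id = seq_id, sequence = sequence)
}

# Line number of the i-th FASTA header, for error messages.
fasta_record_line <- function(path, i) {
  headers <- grep("^>", readLines(path, warn = FALSE))
  if (i <= length(headers)) headers[i] else NA_integer_
}

#' Write a FASTA file
#'
#' @param sequences a tibble with `seq_id` and `sequence` columns, or a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    x <- setNames(sequences$sequence, sequences$seq_id)
  } else {
    x <- sequences
  }
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair batch
#'
#' Mates are paired by position; read ids must agree between files after
#' stripping a trailing `/1` or `/2` mate tag. Quality strings are kept in
#' their FASTQ encoding with the offset recorded as an attribute; use
#' [phred_to_int()] to decode.
#'
#' @param path_r1,path_r2 paths to the mate-1 and mate-2 FASTQ files.
#' @param quality_offset ASCII offset of the quality encoding (default 33).
#' @return a tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   and attribute `quality_offset`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2, quality_offset = 33L) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop_fmt("record-count mismatch between %s (%d) and %s (%d)",
             path_r1, nrow(r1), path_r2, nrow(r2))
  }
  stem1 <- sub("/[12]$", "", r1$id)
  stem2 <- sub("/[12]$", "", r2$id)
  bad <- which(stem1 != stem2)
  if (length(bad) > 0) {
    stop_fmt("read id mismatch at record %d: '%s' vs '%s'",
             bad[1], r1$id[bad[1]], r2$id[bad[1]])
  }
  out <- tibble(read_id = stem1,
                seq1 = r1$sequence, qual1 = r1$quality,
                seq2 = r2$sequence, qual2 = r2$quality)
  attr(out, "quality_offset") <- as.integer(quality_offset)
  out
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ file not found: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop_fmt("malformed FASTQ in %s: %s", path, conditionMessage(e))
  )
  qual <- unname(as.character(S4Vectors::mcols(set)$qualities))
  seqs <- unname(toupper(as.character(set)))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0) {
    stop_fmt("sequence/quality length mismatch at record %d of %s", bad[1], path)
  }
  tibble(id = unname(sub("\\s.*$", "", names(set))), sequence = seqs,
         quality = qual)
}

#' Write a read-pair batch to paired FASTQ files
#'
#' @param batch a read-pair batch as returned by [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param path_r1,path_r2 output paths.
#' @return the two paths, invisibly.
#' @export
write_fastq_pairs <- function(batch, path_r1, path_r2) {
  write_fastq_one(batch$read_id, batch$seq1, batch$qual1, path_r1, "/1")
  write_fastq_one(batch$read_id, batch$seq2, batch$qual2, path_r2, "/2")
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(ids, seqs, quals, path, mate_tag) {
  lines <- character(4L * length(ids))
  lines[seq_along(ids) * 4L - 3L] <- paste0("@", ids, mate_tag)
  lines[seq_along(ids) * 4L - 2L] <- seqs
  lines[seq_along(ids) * 4L - 1L] <- "+"
  lines[seq_along(ids) * 4L] <- quals
  writeLines(lines, path)
}

#' Read a taxonomy table
#'
#' Tab-separated with header columns `seq_id`, `species`, `genus`, `family`.
#' `species` may be empty for genus-level reference sequences; `genus` and
#' `family` must be non-empty and `seq_id` unique.
#'
#' @param path path to a TSV file.
#' @return a tibble keyed by `seq_id`.
#' @export
read_taxonomy_table <- function(path) {
  tab <- read_tsv_strict(path, c("seq_id", "species", "genus", "family"))
  tab$species[is.na(tab$species)] <- ""
  if (anyDuplicated(tab$seq_id)) {
    stop_fmt("duplicate seq_id in taxonomy table %s: %s", path,
             paste(unique(tab$seq_id[duplicated(tab$seq_id)]), collapse = ", "))
  }
  bad <- which(is.na(tab$genus) | tab$genus == "" | is.na(tab$family) | tab$family == "")
  if (length(bad) > 0) {
    stop_fmt("missing genus or family for seq_id %s in %s",
             paste(tab$seq_id[bad], collapse = ", "), path)
  }
  tab
}

#' @rdname read_taxonomy_table
#' @param taxonomy a taxonomy tibble.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[, c("seq_id", "species", "genus", "family")], path)
  invisible(path)
}

#' Assemble a validated reference library
#'
#' Joins reference sequences with their three-rank taxonomy and enforces the
#' library invariants: every FASTA record has a taxonomy row, ids are unique,
#' sequences are non-empty over {A,C,G,T,N}, genus and family are non-empty.
#'
#' @param sequences tibble from [read_fasta()].
#' @param taxonomy tibble from [read_taxonomy_table()].
#' @return a tibble with columns `seq_id`, `sequence`, `species`, `genus`,
#'   `family`, class `reference_library`.
#' @export
reference_library <- function(sequences, taxonomy) {
  missing <- setdiff(sequences$seq_id, taxonomy$seq_id)
  if (length(missing) > 0) {
    stop_fmt("reference sequences absent from taxonomy table: %s",
             paste(missing, collapse = ", "))
  }
  lib <- dplyr::inner_join(sequences, taxonomy, by = "seq_id")
  lib <- lib[match(sequences$seq_id, lib$seq_id), ]  # preserve FASTA order
  class(lib) <- c("reference_library", class(tibble()))
  lib
}

#' Read a regional plant checklist
#'
#' Tab-separated with header columns `taxon`, `status`, `habitat`,
#' `growth_form`, `use`. Codes are validated: status one of
#' native/both/horticulture; habitat W (woodland, hedgerow, scrub),
#' G (grassland) or H (horticultural planting); growth form W (woody),
#' H (herbaceous) or B (bulb/corm); use a subset of N (nectar), P (pollen).
#'
#' @param path path to a TSV file.
#' @return a tibble keyed by `taxon`.
#' @export
read_checklist <- function(path) {
  tab <- read_tsv_strict(path, c("taxon", "status", "habitat", "growth_form", "use"))
  tab$use[is.na(tab$use)] <- ""
  if (anyDuplicated(tab$taxon)) {
    stop_fmt("duplicate taxon in checklist %s: %s", path,
             paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "))
  }
  check_codes(tab$status, c("native", "both", "horticulture"), "status", path)
  check_codes(tab$habitat, c("W", "G", "H"), "habitat", path)
  check_codes(tab$growth_form, c("W", "H", "B"), "growth_form", path)
  bad_use <- which(grepl("[^NP]", tab$use))
  if (length(bad_use) > 0) {
    stop_fmt("invalid use code '%s' for taxon '%s' in %s",
             tab$use[bad_use[1]], tab$taxon[bad_use[1]], path)
  }
  tab
}

#' @rdname read_checklist
#' @param checklist a checklist tibble.
#' @export
write_checklist <- function(checklist, path) {
  readr::write_tsv(
    checklist[, c("taxon", "status", "habitat", "growth_form", "use")], path)
  invisible(path)
}

check_codes <- function(x, allowed, field, path) {
  bad <- which(!(x %in% allowed))
  if (length(bad) > 0) {
    stop_fmt("invalid %s code '%s' in %s (allowed: %s)",
             field, x[bad[1]], path, paste(allowed, collapse = ", "))
  }
}

#' Read a floral survey table
#'
#' Tab-separated with header columns `zone_id`, `area_m2`, `habitat_class`,
#' `month`, `taxon`: one row per (zone, month, taxon-in-flower) observation.
#' Zone areas must be consistent across rows; months are restricted to the
#' configured survey months; repeated observations of one taxon in one
#' zone-month collapse to a single record (set semantics).
#'
#' @param path path to a TSV file.
#' @param months allowed survey month labels.
#' @return a deduplicated survey tibble.
#' @export
read_survey_tables <- function(path, months = c("April", "May")) {
  tab <- read_tsv_strict(path, c("zone_id", "area_m2", "habitat_class", "month", "taxon"))
  tab$zone_id <- as.character(tab$zone_id)
  bad_month <- setdiff(unique(tab$month), months)
  if (length(bad_month) > 0) {
    stop_fmt("unknown month label(s) in %s: %s (expected %s)", path,
             paste(bad_month, collapse = ", "), paste(months, collapse = ", "))
  }
  areas <- unique(tab[, c("zone_id", "area_m2")])
  dup <- areas$zone_id[duplicated(areas$zone_id)]
  if (length(dup) > 0) {
    stop_fmt("conflicting areas for zone(s) %s in %s",
             paste(unique(dup), collapse = ", "), path)
  }
  if (any(tab$area_m2 <= 0)) stop_fmt("non-positive zone area in %s", path)
  out <- distinct(tab, zone_id, area_m2, habitat_class, month, taxon)
  attr(out, "months") <- months
  out
}

#' @rdname read_survey_tables
#' @param survey a survey tibble.
#' @export
write_survey_table <- function(survey, path) {
  readr::write_tsv(
    survey[, c("zone_id", "area_m2", "habitat_class", "month", "taxon")], path)
  invisible(path)
}

#' Zones of a survey
#'
#' @param survey a survey tibble from [read_survey_tables()].
#' @return a tibble of distinct `zone_id`, `area_m2`, `habitat_class`.
#' @export
survey_zones <- function(survey) {
  distinct(survey, zone_id, area_m2, habitat_class)
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_fmt("%s is missing required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  as_tibble(tab)
}
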