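#' Assign one read from its tied top hits
#'
#' Hierarchical lowest-common-rank rule: the tied top hits are collapsed to
#' their distinct (species, genus, family) triples; a single species gives a
#' species-rank assignment, several species of one genus a genus-rank
#' assignment, several genera of one family a family-rank assignment (with
#' the contributing genera recorded as a group), and hits spanning several
#' families are unknown. Family-rank labels render as the sorted constituent
#' genus names joined with "/" (e.g. "Cotoneaster/Crataegus/Malus").
#'
#' @param hit_set a `hit_set` from [top_hits()] or [seeded_top_hits()], or a
#'   character vector of top-hit `seq_id`s.
#' @param taxonomy tibble with `seq_id`, `species`, `genus`, `family` (a
#'   `reference_library` works).
#' @return list with `rank` (species/genus/family/unknown), `label`,
#'   `genus_group` (character vector, length >= 2 iff rank is family),
#'   `family` (NA when rank is unknown).
#' @export
assign <- function(hit_set, taxonomy) {
  top_ids <- if (inherits(hit_set, "hit_set")) {
    hit_set$hits$seq_id[hit_set$hits$is_top]
  } else {
    as.character(hit_set)
  }
  if (length(top_ids) == 0) {
    return(list(rank = "unknown", label = NA_character_,
                genus_group = character(0), family = NA_character_))
  }
  missing <- setdiff(top_ids, taxonomy$seq_id)
  if (length(missing) > 0) {
    stop_fmt("seq_id absent from taxonomy (library desynchronized): %s",
             paste(missing, collapse = ", "))
  }
  rows <- taxonomy[match(top_ids, taxonomy$seq_id), c("species", "genus", "family")]
  triples <- distinct(rows)
  families <- unique(triples$family)
  genera <- unique(triples$genus)
  species <- unique(triples$species[triples$species != ""])
  if (length(families) > 1) {
    list(rank = "unknown", label = NA_character_,
         genus_group = character(0), family = NA_character_)
  } else if (length(genera) > 1) {
    grp <- sort(genera)
    list(rank = "family", label = paste(grp, collapse = "/"),
         genus_group = grp, family = families)
  } else if (length(species) == 1 && all(triples$species != "")) {
    list(rank = "species", label = species,
         genus_group = genera, family = families)
  } else {
    list(rank = "genus", label = genera,
         genus_group = genera, family = families)
  }
}

#' Assign a batch of searched reads
#'
#' Applies [assign()] to every read of a [search_reads()] result. Reads with
#' empty hit sets (skipped as short, or sharing no k-mer with any reference)
#' are assigned rank `unknown`.
#'
#' @param search a [search_reads()] result.
#' @param taxonomy tibble with `seq_id`, `species`, `genus`, `family`.
#' @return tibble `read_id`, `rank`, `label`, `family`, `genus_group`
#'   (list-column).
#' @export
assign_reads <- function(search, taxonomy) {
  hits <- search$hits[search$hits$is_top, c("read_id", "seq_id")]
  missing <- setdiff(unique(hits$seq_id), taxonomy$seq_id)
  if (length(missing) > 0) {
    stop_fmt("seq_id absent from taxonomy (library desynchronized): %s",
             paste(missing, collapse = ", "))
  }
  ids <- search$reads$read_id
  rank <- rep("unknown", length(ids))
  label <- rep(NA_character_, length(ids))
  family <- rep(NA_character_, length(ids))
  genus_group <- rep(list(character(0)), length(ids))

  n_hits <- table(hits$read_id)
  single <- names(n_hits)[n_hits == 1]
  if (length(single) > 0) {
    # fast path: one top hit collapses trivially
    h1 <- hits[hits$read_id %in% single, ]
    ti <- match(h1$seq_id, taxonomy$seq_id)
    pos <- match(h1$read_id, ids)
    sp <- taxonomy$species[ti]
    rank[pos] <- ifelse(sp != "", "species", "genus")
    label[pos] <- ifelse(sp != "", sp, taxonomy$genus[ti])
    family[pos] <- taxonomy$family[ti]
    genus_group[pos] <- as.list(taxonomy$genus[ti])
  }
  multi <- names(n_hits)[n_hits > 1]
  if (length(multi) > 0) {
    split_ids <- split(hits$seq_id[hits$read_id %in% multi],
                       hits$read_id[hits$read_id %in% multi])
    for (rid in names(split_ids)) {
      res <- assign(split_ids[[rid]], taxonomy)
      pos <- match(rid, ids)
      rank[pos] <- res$rank
      label[pos] <- res$label
      family[pos] <- res$family
      genus_group[[pos]] <- res$genus_group
    }
  }
  tibble(read_id = ids, rank = rank, label = label, family = family,
         genus_group = genus_group)
}

#' Percentage of reads identifiable below the unknown rank
#'
#' @param assignments tibble from [assign_reads()] (reads with empty hit
#'   sets count as unknown in the denominator).
#' @return percentage of reads with rank species, genus or family.
#' @export
identifiable_fraction <- function(assignments) {
  if (nrow(assignments) == 0) stop_fmt("no assignments supplied")
  100 * sum(assignments$rank != "unknown") / nrow(assignments)
}

#' Aggregate assignments into per-taxon read counts
#'
#' @param assignments tibble from [assign_reads()].
#' @param drop_unknown drop unknown-rank reads (the default; they are
#'   excluded from composition denominators).
#' @return tibble `label`, `rank`, `family`, `genus_group` (list-column),
#'   `n_reads`, ordered by decreasing count.
#' @export
taxon_counts <- function(assignments, drop_unknown = TRUE) {
  a <- assignments
  if (drop_unknown) a <- a[a$rank != "unknown", ]
  if (nrow(a) == 0) {
    return(tibble(label = character(), rank = character(),
                  family = character(), genus_group = list(),
                  n_reads = integer()))
  }
  key <- paste(a$rank, a$label, sep = "\r")
  first <- !duplicated(key)
  counts <- as.integer(table(key)[key[first]])
  out <- tibble(label = a$label[first], rank = a$rank[first],
                family = a$family[first], genus_group = a$genus_group[first],
                n_reads = counts)
  arrange(out, dplyr::desc(n_reads), label)
}

#' Regional checklist filter
#'
#' Removes taxa absent from the regional checklist and excludes their reads
#' from downstream denominators. Matching is case-insensitive after
#' whitespace normalization: a species-level label is retained if the
#' species or its genus is on the checklist; a genus-level label if the
#' genus appears (as a checklist genus or label); a family-rank group if ANY
#' constituent genus appears.
#'
#' @param counts tibble from [taxon_counts()].
#' @param checklist tibble from [read_checklist()].
#' @return list with `retained` (filtered counts tibble) and `removed`
#'   (tibble `label`, `rank`, `n_reads`).
#' @export
regional_filter <- function(counts, checklist) {
  cl_labels <- normalize_label(checklist$taxon)
  cl_genera <- unique(genus_token(cl_labels))
  on_list <- vapply(seq_len(nrow(counts)), function(i) {
    lab <- normalize_label(counts$label[i])
    rank <- counts$rank[i]
    if (rank == "family") {
      any(normalize_label(counts$genus_group[[i]]) %in% cl_genera)
    } else if (rank == "species") {
      lab %in% cl_labels || genus_token(lab) %in% cl_genera
    } else {
      lab %in% cl_labels || lab %in% cl_genera
    }
  }, TRUE)
  list(retained = counts[on_list, ],
       removed = counts[!on_list, c("label", "rank", "n_reads")])
}
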