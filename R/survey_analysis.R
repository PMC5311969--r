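#' Floral availability by month and rank
#'
#' Per survey month, the deduplicated set of genera and of families recorded
#' in flower anywhere in the study site, plus a combined row equal to the
#' union over months. Survey taxa are reduced to their genus (first label
#' token); families come from the supplied genus-to-family mapping, and taxa
#' whose genus has no mapping are omitted from the family sets only.
#'
#' @param survey survey tibble from [read_survey_tables()] or
#'   [simulate_survey()].
#' @param taxonomy optional tibble with `genus` and `family` columns used to
#'   map survey genera to families (a `reference_library` works).
#' @return an `availability_table` tibble: `month` (survey months plus
#'   `"combined"`), `rank` (`"genus"`/`"family"`), `taxa` (list-column of
#'   sorted labels), `n`.
#' @export
availability <- function(survey, taxonomy = NULL) {
  months <- attr(survey, "months")
  if (is.null(months)) months <- sort(unique(survey$month))
  fam_of <- NULL
  if (!is.null(taxonomy)) {
    map <- distinct(as_tibble(taxonomy)[, c("genus", "family")])
    fam_of <- setNames(map$family, normalize_label(map$genus))
  }
  month_sets <- function(m) {
    taxa <- survey$taxon[survey$month == m]
    genera <- sort(unique(genus_token(normalize_label(taxa))))
    fams <- if (is.null(fam_of)) character(0) else
      sort(unique(unname(fam_of[genera[genera %in% names(fam_of)]])))
    list(genus = genera, family = fams)
  }
  sets <- lapply(months, month_sets)
  names(sets) <- months
  combined <- list(
    genus = sort(unique(unlist(lapply(sets, `[[`, "genus")))),
    family = sort(unique(unlist(lapply(sets, `[[`, "family")))))
  sets$combined <- combined
  out <- bind_rows(lapply(names(sets), function(m) {
    tibble(month = m, rank = c("genus", "family"),
           taxa = list(sets[[m]]$genus, sets[[m]]$family))
  }))
  out$n <- vapply(out$taxa, length, 1L)
  class(out) <- c("availability_table", class(tibble()))
  out
}

# The availability set for one month and rank.
available_set <- function(avail, month, rank) {
  row <- avail$taxa[avail$month == month & avail$rank == rank]
  if (length(row) == 0) stop_fmt("no availability row for %s/%s", month, rank)
  row[[1]]
}

#' Flowering density per zone
#'
#' Number of distinct genera in flower per square metre for each survey zone
#' in one month; zones with no flowering record that month have density 0.
#'
#' @param survey survey tibble.
#' @param month month label.
#' @return tibble `zone_id`, `area_m2`, `habitat_class`, `n_genera`,
#'   `genera_per_m2`.
#' @export
density_per_area <- function(survey, month) {
  zones <- survey_zones(survey)
  if (any(zones$area_m2 <= 0)) stop_fmt("zone areas must be positive")
  sub <- survey[survey$month == month, ]
  n_gen <- vapply(zones$zone_id, function(z) {
    length(unique(genus_token(normalize_label(sub$taxon[sub$zone_id == z]))))
  }, 1L)
  zones$n_genera <- unname(n_gen)
  zones$genera_per_m2 <- zones$n_genera / zones$area_m2
  zones
}

# Honey taxa expanded to genus level: genus- and species-rank labels
# contribute their genus, family-rank groups every constituent genus.
expand_honey_genera <- function(honey) {
  g <- character(0)
  for (i in seq_len(nrow(honey))) {
    g <- c(g, if (honey$rank[i] == "family") honey$genus_group[[i]]
           else genus_token(honey$label[i]))
  }
  sort(unique(normalize_label(g)))
}

expand_honey_families <- function(honey) {
  sort(unique(normalize_label(honey$family[!is.na(honey$family)])))
}

#' Plant use versus availability
#'
#' Compares the taxa recorded in honey with those in flower: the number of
#' honey genera (or families) found among the month's availability set, as a
#' count and as a half-away-from-zero rounded integer percentage of the
#' available total.
#'
#' @param honey a `sample_composition` (or taxon-count tibble with `label`,
#'   `rank`, `family`, `genus_group`).
#' @param avail an [availability()] table.
#' @param rank `"genus"` or `"family"`.
#' @param month month label (or `"combined"`).
#' @return tibble `month`, `rank`, `n_used`, `n_available`, `percent_used`.
#' @export
use_vs_availability <- function(honey, avail, rank = c("genus", "family"),
                                month = "combined") {
  rank <- match.arg(rank)
  pool <- available_set(avail, month, rank)
  if (length(pool) == 0) stop_fmt("no available taxa for %s/%s", month, rank)
  used <- if (rank == "genus") expand_honey_genera(honey)
          else expand_honey_families(honey)
  n_used <- length(intersect(used, normalize_label(pool)))
  tibble(month = month, rank = rank, n_used = n_used,
         n_available = length(pool),
         percent_used = percent_round(100 * n_used / length(pool)))
}

#' Approximate area of occurrence of a taxon
#'
#' Sum of the areas of the survey zones in which any species of the taxon's
#' genus flowered in the given month; a family-rank honey group uses the
#' union of zones over its constituent genera.
#'
#' @param survey survey tibble.
#' @param taxon taxon label (genus or species binomial).
#' @param month month label.
#' @param genus_group optional character vector of genera for family-rank
#'   groups (overrides `taxon`).
#' @return area in square metres (0 when the taxon was not recorded).
#' @export
area_of_occurrence <- function(survey, taxon, month, genus_group = NULL) {
  genera <- if (!is.null(genus_group) && length(genus_group) > 0) {
    normalize_label(genus_group)
  } else {
    genus_token(normalize_label(taxon))
  }
  sub <- survey[survey$month == month, ]
  hit <- genus_token(normalize_label(sub$taxon)) %in% genera
  zones <- distinct(sub[hit, c("zone_id", "area_m2")])
  sum(zones$area_m2)
}

#' Phenology concordance of honey detections with flowering
#'
#' Per honey taxon and month: whether it was in flower, its proportion of
#' honey DNA reads, whether its detections are concordant (detected only in
#' months when in flower), and a carry-over flag for taxa detected in honey
#' but never recorded in flower in any surveyed month (e.g. autumn-flowering
#' ivy appearing in spring honey).
#'
#' @param compositions_by_month named list: month -> pooled
#'   `sample_composition`.
#' @param avail an [availability()] table.
#' @return tibble `label`, `rank`, plus per-month `in_flower_*` and `prop_*`
#'   columns, `concordant`, `carry_over`.
#' @export
phenology_concordance <- function(compositions_by_month, avail) {
  months <- names(compositions_by_month)
  stopifnot(length(months) >= 2)
  all <- bind_rows(compositions_by_month)
  key <- paste(all$rank, all$label, sep = "\r")
  first <- !duplicated(key)
  taxa <- all[first, c("label", "rank", "genus_group")]

  taxon_genera <- lapply(seq_len(nrow(taxa)), function(i) {
    if (taxa$rank[i] == "family") normalize_label(taxa$genus_group[[i]])
    else genus_token(normalize_label(taxa$label[i]))
  })
  out <- taxa[, c("label", "rank")]
  for (m in months) {
    pool <- normalize_label(available_set(avail, m, "genus"))
    out[[paste0("in_flower_", tolower(m))]] <-
      vapply(taxon_genera, function(g) any(g %in% pool), TRUE)
    comp <- compositions_by_month[[m]]
    ckey <- paste(comp$rank, comp$label, sep = "\r")
    prop <- comp$proportion[match(paste(taxa$rank, taxa$label, sep = "\r"), ckey)]
    out[[paste0("prop_", tolower(m))]] <- ifelse(is.na(prop), 0, prop)
  }
  in_flower <- as.matrix(out[, paste0("in_flower_", tolower(months))])
  detected <- as.matrix(out[, paste0("prop_", tolower(months))]) > 0
  out$concordant <- rowSums(detected & !in_flower) == 0
  out$carry_over <- rowSums(in_flower) == 0 & rowSums(detected) > 0
  out
}
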