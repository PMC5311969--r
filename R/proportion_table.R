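#' Analyze an externally supplied per-hive proportion table
#'
#' Entry point for re-analyzing a published or otherwise pre-computed
#' per-hive composition, bypassing the sequence-processing stages: a TSV
#' with columns `hive`, `month`, `taxon`, `proportion` (percent within hive
#' x month) is loaded, each month is pooled across hives, and Simpson's
#' diversity per month plus pairwise between-hive Spearman correlations
#' (union taxon list, absent taxa as zero, Bonferroni over pairs x months)
#' are returned.
#'
#' @param path path to the proportion TSV.
#' @param pooling pooling rule across hives (see [pool_samples()]); with no
#'   read counts available, `"mean-of-proportions"` is the default.
#' @return list with `compositions` (per hive x month), `pooled_by_month`,
#'   `simpson` (tibble month/simpson) and `concordance` (the
#'   [hive_concordance()] table).
#' @export
analyze_proportion_table <- function(path,
                                     pooling = "mean-of-proportions") {
  tab <- read_tsv_strict(path, c("hive", "month", "taxon", "proportion"))
  comps <- list()
  for (h in unique(tab$hive)) {
    for (m in unique(tab$month)) {
      sub <- tab[tab$hive == h & tab$month == m & tab$proportion > 0, ]
      if (nrow(sub) == 0) next
      comp <- tibble(hive = h, month = m, label = sub$taxon,
                     rank = "genus", family = NA_character_,
                     genus_group = as.list(genus_token(sub$taxon)),
                     read_count = NA_integer_,
                     proportion = 100 * sub$proportion / sum(sub$proportion))
      class(comp) <- c("sample_composition", class(tibble()))
      comps[[paste(h, m)]] <- comp
    }
  }
  if (length(comps) == 0) stop_fmt("no usable rows in %s", path)
  months <- unique(tab$month)
  pooled <- lapply(months, function(m) {
    pool_samples(comps[grepl(paste0(" ", m, "$"), names(comps))],
                 mode = pooling, month = m)
  })
  names(pooled) <- months
  simpson <- tibble(month = months,
                    simpson = vapply(pooled, simpson_diversity, 1.0))
  list(compositions = comps, pooled_by_month = pooled, simpson = simpson,
       concordance = hive_concordance(comps))
}
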