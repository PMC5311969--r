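#' Per-sample taxon proportions
#'
#' Converts checklist-retained per-taxon read counts into percentages of the
#' identifiable, retained reads for one hive x month sample. Proportions sum
#' to 100.
#'
#' @param counts tibble from [taxon_counts()] (after [regional_filter()]).
#' @param hive_id,month sample labels.
#' @return a `sample_composition` tibble: `hive`, `month`, `label`, `rank`,
#'   `family`, `genus_group`, `read_count`, `proportion`.
#' @export
proportions <- function(counts, hive_id = NA_character_,
                        month = NA_character_) {
  total <- sum(counts$n_reads)
  if (nrow(counts) == 0 || total <= 0) {
    stop_fmt("zero retained reads for sample %s %s", hive_id, month)
  }
  out <- tibble(hive = hive_id, month = month,
                label = counts$label, rank = counts$rank,
                family = counts$family, genus_group = counts$genus_group,
                read_count = counts$n_reads,
                proportion = 100 * counts$n_reads / total)
  class(out) <- c("sample_composition", class(tibble()))
  out
}

#' Pool several sample compositions
#'
#' `"pooled-counts"` (default) sums read counts across samples and recomputes
#' proportions on the pooled denominator; `"mean-of-proportions"` averages
#' each taxon's percentage over the samples (absent taxa count as zero).
#'
#' @param compositions list of `sample_composition` tibbles.
#' @param mode pooling rule.
#' @param hive_id,month labels for the pooled pseudo-sample (default
#'   `"all"` / the shared month if unique).
#' @return a `sample_composition` tibble.
#' @export
pool_samples <- function(compositions, mode = c("pooled-counts",
                                                "mean-of-proportions"),
                         hive_id = "all", month = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(compositions) >= 1)
  all <- bind_rows(compositions)
  if (is.null(month)) {
    m <- unique(all$month)
    month <- if (length(m) == 1) m else "combined"
  }
  key <- paste(all$rank, all$label, sep = "\r")
  first <- !duplicated(key)
  meta <- all[first, c("label", "rank", "family", "genus_group")]
  if (mode == "pooled-counts") {
    cnt <- tapply(all$read_count, key, sum)[key[first]]
    out <- tibble(hive = hive_id, month = month, meta,
                  read_count = as.integer(cnt),
                  proportion = 100 * as.numeric(cnt) / sum(cnt))
  } else {
    psum <- tapply(all$proportion, key, sum)[key[first]]
    out <- tibble(hive = hive_id, month = month, meta,
                  read_count = NA_integer_,
                  proportion = as.numeric(psum) / length(compositions))
  }
  out <- arrange(out, dplyr::desc(proportion), label)
  class(out) <- c("sample_composition", class(tibble()))
  out
}

#' Classify taxa as major or minor forage
#'
#' Major taxa are those whose proportion of DNA reads strictly exceeds the
#' threshold (1 percent by default); everything else is minor. Exactly 1.00
#' percent is minor.
#'
#' @param composition a `sample_composition`.
#' @param threshold percentage threshold (strict).
#' @return the composition with a `class` column (`"major"`/`"minor"`).
#' @export
classify_major_minor <- function(composition, threshold = 1.0) {
  composition$class <- ifelse(composition$proportion > threshold,
                              "major", "minor")
  composition
}

#' Taxon richness of a composition
#'
#' @param composition a `sample_composition`.
#' @return number of taxa with at least one read (integer).
#' @export
richness <- function(composition) {
  if (all(is.na(composition$read_count))) {
    return(sum(composition$proportion > 0))
  }
  sum(composition$read_count > 0)
}

#' Simpson's diversity index (Gini-Simpson complement form)
#'
#' `D = 1 - sum(p_i^2)` with proportions as fractions: the probability that
#' two randomly drawn reads belong to different taxa. 0 for a single taxon;
#' at most `1 - 1/richness`, attained by a uniform composition.
#'
#' @param composition a `sample_composition` (proportions summing to 100).
#' @return numeric in [0, 1).
#' @export
simpson_diversity <- function(composition) {
  p <- composition$proportion / 100
  if (abs(sum(p) - 1) > 1e-6) {
    stop_fmt("proportions must sum to 100 (got %.6f)", 100 * sum(p))
  }
  1 - sum(p^2)
}
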