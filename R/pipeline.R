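#' Default analysis parameters
#'
#' One place for every tunable of the read-processing, search, assignment
#' and composition stages; values can be overridden per run via the config
#' file or argument.
#'
#' @return a nested list of parameters.
#' @export
default_params <- function() {
  list(
    trim = list(threshold_q = 20, window = 4L),
    merge = list(min_overlap = 20L, max_mismatch_fraction = 0.1),
    length_filter = list(min_exclusive = 450L),
    alignment = list(match = 1L, mismatch = -2L, gap_open = -2L,
                     gap_extend = -2L, lambda = 1.28, K = 0.46),
    search = list(engine = "seeded", k = 11L, min_query_length = 50L,
                  band_pad = 25L),
    pooling = "pooled-counts",
    major_threshold = 1.0,
    quality_offset = 33L)
}

merge_params <- function(overrides) {
  p <- default_params()
  if (is.null(overrides)) return(p)
  modifyList(p, overrides)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Simulate a dataset to disk
#'
#' Generates a full synthetic study ([simulate_study()]) and writes every
#' pipeline input file: reference FASTA plus taxonomy TSV, checklist TSV,
#' survey TSV, paired FASTQ per hive x month sample, the truth table, a
#' manifest echoing the seed and parameters, and a run-ready config.
#'
#' @param config a config list or YAML path with top-level `seed`,
#'   `output_dir` and an optional `simulate` block of [simulate_study()] /
#'   [sim_config()] arguments.
#' @return the dataset directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  dir <- config$output_dir %||% "dataset"
  sim <- config$simulate %||% list()
  cfg_args <- sim[intersect(names(sim),
                            names(formals(sim_config)))]
  cfg_args$seed <- seed
  study_args <- sim[intersect(names(sim), setdiff(names(formals(simulate_study)),
                                                  c("seed", "config")))]
  study <- do.call(simulate_study,
                   c(list(seed = seed, config = do.call(sim_config, cfg_args)),
                     study_args))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(dir, ...)
  write_fasta(study$library, path("reference.fasta"))
  write_taxonomy_table(study$library, path("taxonomy.tsv"))
  write_checklist(study$checklist, path("checklist.tsv"))
  write_survey_table(study$survey, path("survey.tsv"))
  readr::write_tsv(study$truth, path("truth.tsv"))

  samples <- study$samples
  samples$r1 <- path(paste0(samples$sample_id, "_R1.fastq"))
  samples$r2 <- path(paste0(samples$sample_id, "_R2.fastq"))
  for (i in seq_len(nrow(samples))) {
    write_fastq_pairs(study$reads[[samples$sample_id[i]]],
                      samples$r1[i], samples$r2[i])
  }

  run_config <- list(
    seed = seed,
    output_dir = file.path(dir, "results"),
    inputs = list(
      reference_fasta = path("reference.fasta"),
      taxonomy = path("taxonomy.tsv"),
      checklist = path("checklist.tsv"),
      survey = path("survey.tsv"),
      samples = lapply(seq_len(nrow(samples)), function(i) {
        as.list(samples[i, c("sample_id", "hive", "month", "r1", "r2")])
      })),
    params = config$params %||% list())
  yaml::write_yaml(run_config, path("run_config.yaml"))
  manifest <- list(seed = seed,
                   simulate = sim,
                   n_samples = nrow(samples),
                   files = sort(basename(c(
                     path(c("reference.fasta", "taxonomy.tsv", "checklist.tsv",
                            "survey.tsv", "truth.tsv", "run_config.yaml")),
                     samples$r1, samples$r2))))
  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline in memory
#'
#' Core end-to-end run over in-memory inputs: trim, merge, length-filter,
#' top-hit search, lowest-common-rank assignment, checklist filter,
#' composition, diversity, survey joins and the statistical layer.
#'
#' @param dataset list with `library` (a `reference_library`), `checklist`,
#'   `survey`, `samples` (tibble `sample_id`, `hive`, `month`) and `reads`
#'   (named list of read-pair batches keyed by sample id).
#' @param params parameter overrides merged onto [default_params()].
#' @return list with per-stage results: `accounting`, `assignments`,
#'   `compositions`, `pooled_by_month`, `combined`, `diversity`,
#'   `availability`, `use_vs_availability`, `phenology`, `stats`,
#'   `status_table`, `removed_taxa`.
#' @export
run_pipeline <- function(dataset, params = NULL) {
  p <- merge_params(params)
  lib <- dataset$library
  samples <- dataset$samples
  align <- do.call(alignment_params, p$alignment)
  months <- attr(dataset$survey, "months") %||% sort(unique(dataset$survey$month))

  accounting <- list()
  assignments <- list()
  compositions <- list()
  removed <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    batch <- dataset$reads[[sid]]
    if (is.null(batch)) stop_fmt("no reads for sample %s", sid)
    proc <- process_reads(batch,
                          threshold_q = p$trim$threshold_q,
                          window = p$trim$window,
                          min_overlap = p$merge$min_overlap,
                          max_mismatch_fraction = p$merge$max_mismatch_fraction,
                          min_exclusive = p$length_filter$min_exclusive,
                          offset = p$quality_offset)
    reads <- setNames(proc$merged$sequence, proc$merged$read_id)
    search <- search_reads(reads, lib, align,
                           engine = p$search$engine, k = p$search$k,
                           min_query_length = p$search$min_query_length,
                           band_pad = p$search$band_pad)
    asg <- assign_reads(search, lib)
    counts <- taxon_counts(asg)
    filt <- regional_filter(counts, dataset$checklist)
    comp <- proportions(filt$retained, samples$hive[i], samples$month[i])

    assignments[[sid]] <- asg
    compositions[[sid]] <- comp
    removed[[sid]] <- filt$removed
    accounting[[sid]] <- dplyr::bind_cols(
      tibble(sample_id = sid), proc$accounting,
      tibble(identifiable_pct = identifiable_fraction(asg),
             removed_by_checklist = sum(filt$removed$n_reads),
             retained_reads = sum(filt$retained$n_reads)))
  }
  accounting <- bind_rows(accounting)

  pooled_by_month <- lapply(months, function(m) {
    pool_samples(compositions[samples$sample_id[samples$month == m]],
                 mode = p$pooling, month = m)
  })
  names(pooled_by_month) <- months
  combined <- pool_samples(compositions, mode = p$pooling, month = "combined")
  combined_cls <- classify_major_minor(combined, p$major_threshold)

  diversity <- bind_rows(
    lapply(names(compositions), function(sid) {
      comp <- compositions[[sid]]
      tibble(hive = comp$hive[1], month = comp$month[1],
             richness = richness(comp), simpson = simpson_diversity(comp))
    }),
    lapply(months, function(m) {
      tibble(hive = "all", month = m,
             richness = richness(pooled_by_month[[m]]),
             simpson = simpson_diversity(pooled_by_month[[m]]))
    }),
    list(tibble(hive = "all", month = "combined",
                richness = richness(combined),
                simpson = simpson_diversity(combined))))

  avail <- availability(dataset$survey, lib)
  uva <- bind_rows(lapply(c(months, "combined"), function(m) {
    honey <- if (m == "combined") combined else pooled_by_month[[m]]
    bind_rows(use_vs_availability(honey, avail, "genus", m),
              use_vs_availability(honey, avail, "family", m))
  }))
  phen <- phenology_concordance(pooled_by_month, avail)

  stats_rows <- list(hive_concordance(compositions))
  for (metric in c("richness", "simpson")) {
    g <- split(diversity[[metric]][diversity$hive != "all"],
               diversity$month[diversity$hive != "all"])
    mw <- mann_whitney_u(g[[months[1]]], g[[months[2]]])
    mw$test <- paste0("mann_whitney_", metric)
    stats_rows[[length(stats_rows) + 1]] <- mw
  }
  area_cor <- area_abundance_correlations(compositions, dataset$survey)
  if (nrow(area_cor) > 0) stats_rows[[length(stats_rows) + 1]] <- area_cor
  sa <- status_association(dataset$checklist, combined_cls)
  stats_rows[[length(stats_rows) + 1]] <- sa$result
  stats <- bind_rows(stats_rows)

  list(accounting = accounting, assignments = assignments,
       compositions = compositions, pooled_by_month = pooled_by_month,
       combined = combined_cls, diversity = diversity, availability = avail,
       use_vs_availability = uva, phenology = phen, stats = stats,
       status_table = sa$table, removed_taxa = removed,
       params = p, months = months, samples = samples)
}

# Spearman correlation of DNA proportion against area of occurrence, per
# hive x month, over that sample's taxa.
area_abundance_correlations <- function(compositions, survey) {
  rows <- list()
  for (comp in compositions) {
    m <- comp$month[1]
    if (!m %in% unique(survey$month) || nrow(comp) < 3) next
    areas <- vapply(seq_len(nrow(comp)), function(i) {
      area_of_occurrence(survey, comp$label[i], m,
                         genus_group = if (comp$rank[i] == "family")
                           comp$genus_group[[i]] else NULL)
    }, 1.0)
    if (stats::sd(areas) == 0) next
    r <- spearman_rho(comp$proportion, areas, p_method = "t")
    r$test <- "area_vs_abundance"
    r$group1 <- comp$hive[1]
    r$group2 <- m
    rows[[length(rows) + 1]] <- r
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) out$p_adjusted <- bonferroni(out$p_value)
  out
}

#' Run the pipeline from a config file and write results
#'
#' Validates every referenced input path before any compute, loads the
#' inputs, executes [run_pipeline()] and writes the per-stage result tables
#' (TSV) plus a config echo into the output directory.
#'
#' @param config config list or YAML path (see [cmd_simulate()] for the
#'   layout it writes).
#' @return the results directory, invisibly.
#' @export
cmd_run <- function(config) {
  config <- read_config(config)
  inp <- config$inputs
  if (is.null(inp)) stop_fmt("config has no inputs block")
  needed <- c(inp$reference_fasta, inp$taxonomy, inp$checklist, inp$survey,
              unlist(lapply(inp$samples, function(s) c(s$r1, s$r2))))
  if (length(inp$samples) == 0) stop_fmt("config lists no samples")
  missing <- needed[!file.exists(needed)]
  if (length(missing) > 0) {
    stop_fmt("missing input file(s): %s", paste(missing, collapse = ", "))
  }

  p <- merge_params(config$params)
  lib <- reference_library(read_fasta(inp$reference_fasta),
                           read_taxonomy_table(inp$taxonomy))
  checklist <- read_checklist(inp$checklist)
  survey <- read_survey_tables(inp$survey)
  samples <- bind_rows(lapply(inp$samples, function(s) {
    tibble(sample_id = s$sample_id, hive = s$hive, month = s$month)
  }))
  reads <- setNames(lapply(inp$samples, function(s) {
    read_fastq_pairs(s$r1, s$r2, p$quality_offset)
  }), samples$sample_id)

  res <- run_pipeline(list(library = lib, checklist = checklist,
                           survey = survey, samples = samples, reads = reads),
                      config$params)

  dir <- config$output_dir %||% "results"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(res, dir)
  yaml::write_yaml(config, file.path(dir, "run_config_used.yaml"))
  invisible(dir)
}

collapse_group <- function(gg) {
  vapply(gg, function(g) paste(g, collapse = "/"), "")
}

flatten_composition <- function(comp) {
  tibble(hive = comp$hive, month = comp$month, label = comp$label,
         rank = comp$rank, family = comp$family,
         genus_group = collapse_group(comp$genus_group),
         read_count = comp$read_count, proportion = comp$proportion,
         class = if ("class" %in% names(comp)) comp$class else NA_character_)
}

write_results <- function(res, dir) {
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(res$accounting, "accounting.tsv")
  for (sid in names(res$assignments)) {
    a <- res$assignments[[sid]]
    w(tibble(read_id = a$read_id, rank = a$rank, label = a$label,
             genus_group = collapse_group(a$genus_group)),
      sprintf("assignments_%s.tsv", sid))
  }
  comp_all <- bind_rows(c(
    lapply(res$compositions, flatten_composition),
    lapply(res$pooled_by_month, flatten_composition),
    list(flatten_composition(res$combined))))
  w(comp_all, "composition.tsv")
  w(res$diversity, "diversity.tsv")
  av <- res$availability
  w(tibble(month = av$month, rank = av$rank, n = av$n,
           taxa = vapply(av$taxa, paste, "", collapse = ";")),
    "availability.tsv")
  w(res$use_vs_availability, "use_vs_availability.tsv")
  w(res$phenology, "phenology.tsv")
  w(res$stats, "stats.tsv")
  rem <- bind_rows(lapply(names(res$removed_taxa), function(sid) {
    r <- res$removed_taxa[[sid]]
    if (nrow(r) == 0) return(NULL)
    dplyr::bind_cols(tibble(sample_id = sid), r)
  }))
  if (is.null(rem) || nrow(rem) == 0) {
    rem <- tibble(sample_id = character(), label = character(),
                  rank = character(), n_reads = integer())
  }
  w(rem, "removed_taxa.tsv")
  invisible(dir)
}

#' Summarize a results directory
#'
#' Renders a human-readable summary of a [cmd_run()] results directory:
#' richness and diversity per hive and month, major/minor taxa, use versus
#' availability percentages and flagged carry-over taxa. A partial directory
#' yields an error listing the missing stages.
#'
#' @param results_dir path written by [cmd_run()].
#' @return the summary lines, invisibly; they are also printed.
#' @export
cmd_report <- function(results_dir) {
  needed <- c("accounting.tsv", "composition.tsv", "diversity.tsv",
              "availability.tsv", "use_vs_availability.tsv", "phenology.tsv",
              "stats.tsv")
  missing <- needed[!file.exists(file.path(results_dir, needed))]
  if (length(missing) > 0) {
    stop_fmt("results directory incomplete; missing stage output(s): %s",
             paste(missing, collapse = ", "))
  }
  rd <- function(name) readr::read_tsv(file.path(results_dir, name),
                                       show_col_types = FALSE, progress = FALSE)
  accounting <- rd("accounting.tsv")
  comp <- rd("composition.tsv")
  div <- rd("diversity.tsv")
  uva <- rd("use_vs_availability.tsv")
  phen <- rd("phenology.tsv")

  lines <- c(sprintf("Samples processed: %d", nrow(accounting)))
  for (i in seq_len(nrow(div))) {
    lines <- c(lines, sprintf(
      "Hive %s %s: richness %d, Simpson's D %.3f",
      div$hive[i], div$month[i], div$richness[i], div$simpson[i]))
  }
  majors <- comp[!is.na(comp$class) & comp$class == "major", ]
  lines <- c(lines, sprintf("Major taxa (>1%% combined): %s",
                            paste(majors$label, collapse = ", ")))
  for (i in seq_len(nrow(uva))) {
    lines <- c(lines, sprintf(
      "%s %s: %d of %d in flower used (%d%%)",
      uva$month[i], uva$rank[i], uva$n_used[i], uva$n_available[i],
      uva$percent_used[i]))
  }
  co <- phen$label[phen$carry_over]
  lines <- c(lines, sprintf("Carry-over taxa: %s",
                            if (length(co) > 0) paste(co, collapse = ", ")
                            else "none"))
  cat(lines, sep = "\n")
  invisible(lines)
}
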