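#' Alignment scoring parameters
#'
#' Defaults mirror the megablast reward/penalty family: +1 match, -2
#' mismatch, affine gaps costing `gap_open + L * gap_extend` for a gap of
#' length L. `lambda` and `K` are the Karlin-Altschul constants of the bit
#' score transform `S' = (lambda * S - ln K) / ln 2`; the defaults are the
#' published ungapped values for +1/-2 scoring. Ties between hits are decided
#' on raw scores, so `lambda`/`K` affect reporting only.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open,gap_extend gap penalties (<= 0).
#' @param lambda,K Karlin-Altschul constants (> 0).
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match = 1L, mismatch = -2L, gap_open = -2L,
                             gap_extend = -2L, lambda = 1.28, K = 0.46) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            lambda > 0, K > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "alignment_params")
}

#' Optimal local alignment score
#'
#' Smith-Waterman dynamic programming with affine gaps, score only. The empty
#' local alignment floors the score at zero.
#'
#' @param query,subject DNA sequence strings.
#' @param params an [alignment_params()].
#' @return the optimal raw score (integer).
#' @export
local_align_score <- function(query, subject, params = alignment_params()) {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop_fmt("local_align_score requires non-empty sequences")
  }
  sw_score_cpp(query, subject, params$match, params$mismatch,
               params$gap_open, params$gap_extend)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`; strictly increasing in `S`, so the set
#' of top hits is identical under raw and bit scores.
#'
#' @param S raw score(s).
#' @param params an [alignment_params()].
#' @return numeric bit score(s).
#' @export
bit_score <- function(S, params = alignment_params()) {
  (params$lambda * S - log(params$K)) / log(2)
}

#' Top-scoring reference hits for one read
#'
#' Scores the read against every sequence in the library (exhaustive engine)
#' and returns all hits, with the subset attaining the maximum raw score
#' flagged as top hits; tied top hits keep library order.
#'
#' @param read merged read sequence.
#' @param library a `reference_library`.
#' @param params an [alignment_params()].
#' @param min_query_length reads shorter than this are skipped with reason
#'   `"short"`.
#' @return a `hit_set`: list with `read_id` (NA here), `hits` (tibble
#'   `seq_id`, `raw_score`, `bit_score`, `is_top`), `top_score`, `status`.
#' @export
top_hits <- function(read, library, params = alignment_params(),
                     min_query_length = 50L) {
  if (nrow(library) == 0) stop_fmt("reference library is empty")
  if (nchar(read) < min_query_length) {
    return(structure(list(hits = empty_hits(), top_score = NA_integer_,
                          status = "short"), class = "hit_set"))
  }
  raw <- sw_scores_cpp(read, library$sequence, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  hits <- tibble(seq_id = library$seq_id, raw_score = raw,
                 bit_score = bit_score(raw, params),
                 is_top = raw == max(raw))
  structure(list(hits = hits, top_score = max(raw), status = "ok"),
            class = "hit_set")
}

#' Seeded top-hit search for one read
#'
#' Accelerated engine: only references sharing at least one exact k-mer with
#' the read are aligned. Equals [top_hits()] whenever the true top alignment
#' contains at least one exact k-mer match; a read sharing no k-mer with any
#' reference returns an empty hit set (status `"no_candidates"`).
#'
#' @inheritParams top_hits
#' @param k k-mer size of the seed index (default 11).
#' @return a `hit_set` as in [top_hits()], restricted to candidate
#'   references, with `engine = "heuristic"` recorded.
#' @export
seeded_top_hits <- function(read, library, params = alignment_params(),
                            k = 11L, min_query_length = 50L) {
  res <- search_reads(read, library, params, engine = "seeded", k = k,
                      min_query_length = min_query_length, keep = "all")
  hits <- res$hits[, c("seq_id", "raw_score", "bit_score", "is_top")]
  structure(list(hits = hits,
                 top_score = res$reads$top_score[1],
                 status = res$reads$status[1], engine = "heuristic"),
            class = "hit_set")
}

empty_hits <- function() {
  tibble(seq_id = character(), raw_score = integer(),
         bit_score = numeric(), is_top = logical())
}

#' Batch top-hit search
#'
#' Searches many merged reads against the library with either the exhaustive
#' Smith-Waterman engine or the k-mer seeded accelerator.
#'
#' @param reads character vector of merged read sequences (names used as read
#'   ids if present).
#' @param library a `reference_library`.
#' @param params an [alignment_params()].
#' @param engine `"seeded"` (default) or `"exhaustive"`.
#' @param k seed k-mer size (seeded engine).
#' @param min_query_length reads shorter than this are skipped.
#' @param keep `"top"` returns only top hits per read; `"all"` every aligned
#'   candidate.
#' @param band_pad half-width padding (in diagonals) of the seed-and-extend
#'   band around each candidate's seed k-mer diagonals; applies to the
#'   seeded engine's `"top"` path only. A negative value disables banding
#'   and runs full Smith-Waterman on every candidate.
#' @return list with `hits` (tibble `read_id`, `seq_id`, `raw_score`,
#'   `bit_score`, `is_top`) and `reads` (tibble `read_id`, `status`,
#'   `top_score`, `n_candidates`; status one of ok/short/no_candidates).
#' @export
search_reads <- function(reads, library, params = alignment_params(),
                         engine = c("seeded", "exhaustive"), k = 11L,
                         min_query_length = 50L, keep = c("top", "all"),
                         band_pad = 25L) {
  engine <- match.arg(engine)
  keep <- match.arg(keep)
  if (nrow(library) == 0) stop_fmt("reference library is empty")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  if (keep == "all") {
    # score every candidate per read; assemble full hit tables
    hit_list <- vector("list", length(reads))
    status <- character(length(reads))
    top_score <- rep(NA_integer_, length(reads))
    n_cand <- integer(length(reads))
    for (i in seq_along(reads)) {
      cand_idx <- seq_len(nrow(library))
      if (engine == "seeded") {
        cand_idx <- kmer_candidates(reads[i], library$sequence, k)
      }
      if (nchar(reads[i]) < min_query_length) {
        status[i] <- "short"
        hit_list[[i]] <- empty_hits()
        next
      }
      if (length(cand_idx) == 0) {
        status[i] <- "no_candidates"
        hit_list[[i]] <- empty_hits()
        next
      }
      raw <- sw_scores_cpp(reads[i], library$sequence[cand_idx], params$match,
                           params$mismatch, params$gap_open, params$gap_extend)
      status[i] <- "ok"
      top_score[i] <- max(raw)
      n_cand[i] <- length(cand_idx)
      hit_list[[i]] <- tibble(seq_id = library$seq_id[cand_idx],
                              raw_score = raw,
                              bit_score = bit_score(raw, params),
                              is_top = raw == max(raw))
    }
    hits <- bind_rows(lapply(seq_along(reads), function(i) {
      if (nrow(hit_list[[i]]) == 0) return(NULL)
      dplyr::bind_cols(tibble(read_id = ids[i]), hit_list[[i]])
    }))
    if (is.null(hits) || nrow(hits) == 0) {
      hits <- dplyr::bind_cols(tibble(read_id = character()), empty_hits())
    }
    reads_tab <- tibble(read_id = ids, status = status,
                        top_score = top_score, n_candidates = n_cand)
    return(list(hits = hits, reads = reads_tab, engine = engine))
  }

  res <- search_top_hits_cpp(unname(reads), library$sequence, params$match,
                             params$mismatch, params$gap_open,
                             params$gap_extend, as.integer(k),
                             engine == "seeded", as.integer(min_query_length),
                             as.integer(band_pad))
  hits <- tibble(read_id = ids[res$read_idx],
                 seq_id = library$seq_id[res$ref_idx],
                 raw_score = res$top_score[res$read_idx])
  hits$bit_score <- bit_score(hits$raw_score, params)
  hits$is_top <- TRUE
  reads_tab <- tibble(read_id = ids,
                      status = c("ok", "short", "no_candidates")[res$status + 1L],
                      top_score = res$top_score,
                      n_candidates = res$n_candidates)
  list(hits = hits, reads = reads_tab, engine = engine)
}

# Indices of library sequences sharing at least one exact k-mer with the read.
kmer_candidates <- function(read, refs, k) {
  if (nchar(read) < k) return(integer(0))
  rk <- unique(substring(read, seq_len(nchar(read) - k + 1),
                         seq_len(nchar(read) - k + 1) + k - 1))
  rk <- rk[!grepl("[^ACGT]", rk)]
  which(vapply(refs, function(s) {
    sk <- substring(s, seq_len(nchar(s) - k + 1), seq_len(nchar(s) - k + 1) + k - 1)
    any(rk %in% sk)
  }, TRUE, USE.NAMES = FALSE))
}
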