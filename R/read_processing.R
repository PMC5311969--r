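#' Quality-trim the 3' end of a read
#'
#' Windowed 3' trim with stride equal to the window size: blocks of `window`
#' bases anchored at the 3' end (the 5'-most block may be shorter) are
#' removed while their mean quality is below `threshold_q`. Never lengthens
#' a read; may return an empty read.
#'
#' @param seq sequence string.
#' @param qual quality string (same length), or an integer vector of scores.
#' @param threshold_q minimum mean window quality to keep (default 20).
#' @param window window size in bases (default 4).
#' @param offset Phred offset when `qual` is a string.
#' @return list with `seq` and `qual` (same representation as the input).
#' @export
quality_trim <- function(seq, qual, threshold_q = 20, window = 4L,
                         offset = 33L) {
  stopifnot(threshold_q >= 0, window >= 1)
  as_string <- is.character(qual)
  scores <- if (as_string) phred_to_int(qual, offset)[[1]] else as.integer(qual)
  n <- length(scores)
  if (nchar(seq) != n) stop_fmt("sequence/quality length mismatch")
  keep <- n
  while (keep > 0) {
    lo <- max(1L, keep - window + 1L)
    if (mean(scores[lo:keep]) >= threshold_q) break
    keep <- lo - 1L
  }
  list(seq = substr(seq, 1L, keep),
       qual = if (as_string) substr(qual, 1L, keep) else scores[seq_len(keep)])
}

#' Merge one mate pair into a full amplicon
#'
#' Mate 2 is supplied in sequencing orientation and reverse-complemented
#' internally. Every overlap length from `min_overlap` up to the shorter read
#' is scored as matches minus mismatches; the best-scoring overlap wins (ties
#' broken toward the longer overlap). The merge is rejected when no overlap
#' is admissible or when the best overlap's mismatch fraction exceeds
#' `max_mismatch_fraction`. Disagreeing overlap positions resolve to the
#' higher-quality base; a quality tie keeps the mate-1 base with the minimum
#' of the two qualities.
#'
#' @param seq1,qual1 mate-1 sequence and quality string.
#' @param seq2,qual2 mate-2 sequence and quality string (sequencing
#'   orientation).
#' @param min_overlap minimum admissible overlap in bp.
#' @param max_mismatch_fraction maximum tolerated mismatch fraction in the
#'   chosen overlap.
#' @return on success a list with `sequence`, `quality`, `overlap_length`,
#'   `mismatches_in_overlap` and `rejected = FALSE`; on rejection a list
#'   with `rejected = TRUE` and `reason` (`"no_overlap"` or `"mismatch"`).
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 20L,
                       max_mismatch_fraction = 0.1) {
  res <- merge_pairs_cpp(seq1, qual1, revcomp(seq2),
                         rev_string(qual2),
                         as.integer(min_overlap), max_mismatch_fraction)
  if (res$status[1] != 0L) {
    return(list(rejected = TRUE,
                reason = c("no_overlap", "mismatch")[res$status[1]]))
  }
  list(rejected = FALSE,
       sequence = res$sequence[1], quality = res$quality[1],
       overlap_length = res$overlap_length[1],
       mismatches_in_overlap = res$mismatches_in_overlap[1])
}

rev_string <- function(x) stringi::stri_reverse(x)

#' Length filter for merged reads
#'
#' Keeps merged amplicons strictly longer than `min_exclusive` (450 bp by
#' default: "over 450 bp" read strictly).
#'
#' @param length integer vector of merged read lengths.
#' @param min_exclusive exclusive lower bound in bp.
#' @return logical vector, `TRUE` to keep.
#' @export
length_filter <- function(length, min_exclusive = 450L) {
  length > min_exclusive
}

#' Trim, merge and length-filter a batch of read pairs
#'
#' Runs the full read-processing stage for one sample: 3' quality trimming of
#' both mates, overlap merging, and the strict >`min_exclusive` bp length
#' filter, with per-stage read accounting (`pairs_in = merged + rejected`,
#' `merged = kept + length_filtered`).
#'
#' @param batch read-pair batch tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param threshold_q,window quality-trim parameters (see [quality_trim()]).
#' @param min_overlap,max_mismatch_fraction merge parameters (see
#'   [merge_pair()]).
#' @param min_exclusive length-filter bound (see [length_filter()]).
#' @param offset Phred offset of the quality strings.
#' @return list with `merged` (tibble of kept reads: `read_id`, `sequence`,
#'   `quality`, `overlap_length`, `mismatches_in_overlap`), `rejected`
#'   (tibble `read_id`, `reason`) and `accounting` (one-row tibble).
#' @export
process_reads <- function(batch, threshold_q = 20, window = 4L,
                          min_overlap = 20L, max_mismatch_fraction = 0.1,
                          min_exclusive = 450L, offset = 33L) {
  n <- nrow(batch)
  t1 <- trim_batch(batch$seq1, batch$qual1, threshold_q, window, offset)
  t2 <- trim_batch(batch$seq2, batch$qual2, threshold_q, window, offset)
  res <- merge_pairs_cpp(t1$seq, t1$qual, revcomp(t2$seq),
                         rev_string(t2$qual),
                         as.integer(min_overlap), max_mismatch_fraction)
  ok <- res$status == 0L
  merged <- tibble(read_id = batch$read_id[ok],
                   sequence = res$sequence[ok],
                   quality = res$quality[ok],
                   overlap_length = res$overlap_length[ok],
                   mismatches_in_overlap = res$mismatches_in_overlap[ok])
  rejected <- tibble(read_id = batch$read_id[!ok],
                     reason = c("no_overlap", "mismatch")[res$status[!ok]])
  keep <- length_filter(nchar(merged$sequence), min_exclusive)
  accounting <- tibble(pairs_in = n,
                       merged = sum(ok),
                       rejected = sum(!ok),
                       length_filtered = sum(!keep),
                       kept = sum(keep))
  list(merged = merged[keep, ], rejected = rejected, accounting = accounting)
}

# Vectorized trim over a batch; empty reads allowed through (they are
# rejected at the merge stage as having no admissible overlap).
trim_batch <- function(seqs, quals, threshold_q, window, offset) {
  n <- length(seqs)
  out_s <- character(n)
  out_q <- character(n)
  for (i in seq_len(n)) {
    tr <- quality_trim(seqs[i], quals[i], threshold_q, window, offset)
    out_s[i] <- tr$seq
    out_q[i] <- tr$qual
  }
  list(seq = out_s, qual = out_q)
}
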