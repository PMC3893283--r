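# Read quality control: primer removal, sliding-window quality trimming,
# content and length filters, pair gating and overlap merging. Filter
# functions take a read_set and return the surviving (possibly trimmed)
# read_set; rejected reads are dropped, so pipeline counts are the row
# counts before/after each stage.

#' Remove the 5' primer from amplicon reads
#'
#' The primer must match the read start as a positional (Hamming) prefix
#' with at most `max_mismatch` mismatches; otherwise the read is rejected.
#' Reads shorter than the primer are rejected. Qualities are trimmed in
#' register.
#'
#' @param reads a [read_set()].
#' @param primer A/C/G/T primer string.
#' @param max_mismatch maximum Hamming mismatches tolerated in the primer.
#' @return the surviving reads, primer removed.
#' @export
strip_primers <- function(reads, primer, max_mismatch = 3) {
  np <- nchar(primer)
  long_enough <- nchar(reads$seq) >= np
  reads <- reads[long_enough, , drop = FALSE]
  if (!nrow(reads)) return(reads)
  pl <- strsplit(primer, "")[[1]]
  pm <- matrix(unlist(strsplit(substr(reads$seq, 1, np), "")),
               ncol = np, byrow = TRUE)
  mism <- rowSums(pm != matrix(pl, nrow(pm), np, byrow = TRUE))
  keep <- mism <= max_mismatch
  out <- reads[keep, , drop = FALSE]
  out$seq <- substring(out$seq, np + 1)
  out$qual <- substring(out$qual, np + 1)
  out
}

#' Trim reads at the first poor-quality window
#'
#' Scans successive windows of `window` bases (step 1) left to right and
#' truncates the read at the start of the first window whose mean phred
#' quality is below `min_avg_q`. Reads with no failing window (including
#' reads shorter than one window) are unchanged. Trimming can empty a read;
#' empty reads are removed later by the length filter.
#'
#' @inheritParams strip_primers
#' @param window window width in bases.
#' @param min_avg_q minimum acceptable mean quality within a window.
#' @return the read set with trimmed sequences and qualities.
#' @export
quality_trim <- function(reads, window = 10, min_avg_q = 25) {
  stopifnot(window >= 1)
  cut_at <- vapply(phred_decode(reads$qual), function(q) {
    len <- length(q)
    if (len < window) return(len)
    cs <- cumsum(c(0, q))
    means <- (cs[(window + 1):(len + 1)] - cs[1:(len - window + 1)]) / window
    bad <- which(means < min_avg_q)
    if (!length(bad)) len else bad[1] - 1L
  }, numeric(1))
  reads$seq <- substr(reads$seq, 1, cut_at)
  reads$qual <- substr(reads$qual, 1, cut_at)
  reads
}

#' Reject reads with excess ambiguity or homopolymer runs
#'
#' A read is rejected if it contains more than `max_ambiguous` ambiguous
#' bases (any character other than A/C/G/T, counted conservatively) or a
#' run of `homopolymer_len` or more identical consecutive bases.
#'
#' @inheritParams strip_primers
#' @param max_ambiguous maximum ambiguous bases tolerated.
#' @param homopolymer_len run length that triggers rejection.
#' @return the surviving reads.
#' @export
content_filter <- function(reads, max_ambiguous = 5, homopolymer_len = 6) {
  n_amb <- nchar(gsub("[ACGT]", "", reads$seq))
  homopat <- paste0("(.)\\1{", homopolymer_len - 1L, ",}")
  has_run <- grepl(homopat, reads$seq)
  reads[n_amb <= max_ambiguous & !has_run, , drop = FALSE]
}

#' Filter reads by length
#'
#' @inheritParams strip_primers
#' @param min_len,max_len inclusive length bounds.
#' @return reads with `min_len <= length <= max_len`.
#' @export
length_filter <- function(reads, min_len = 55, max_len = 106) {
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Keep only pairs whose mates both survived filtering
#'
#' @param fwd,rev filtered forward and reverse read sets.
#' @return list with elements `forward` and `reverse`, row-aligned by id.
#' @export
pair_gate <- function(fwd, rev) {
  ids <- intersect(fwd$id, rev$id)
  list(forward = fwd[match(ids, fwd$id), , drop = FALSE],
       reverse = rev[match(ids, rev$id), , drop = FALSE])
}

#' Merge paired-end reads by overlap
#'
#' The reverse mate is reverse-complemented, then the overlap length
#' `l >= min_overlap` minimizing the mismatch fraction is chosen (ties to
#' the longest). The pair merges only if mismatches/l is at most
#' `max_mismatch_density`; overlap conflicts take the higher-quality base
#' (ties to the forward base). Pairs with no qualifying overlap are dropped.
#'
#' @param fwd,rev row-aligned forward and reverse read sets (same ids, e.g.
#'   the output of [pair_gate()]).
#' @param min_overlap minimum overlap length in bases.
#' @param max_mismatch_density maximum mismatch fraction within the overlap.
#' @return merged [read_set()]; attribute `"overlap"` holds per-read overlap
#'   lengths and mismatch counts.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 15, max_mismatch_density = 0.10) {
  stopifnot(identical(fwd$id, rev$id))
  if (!nrow(fwd)) return(fwd)
  rc <- revcomp(rev$seq)
  rq <- rev_string(rev$qual)
  res <- cpp_merge_pairs(fwd$seq, fwd$qual, rc, rq,
                         as.integer(min_overlap), max_mismatch_density)
  ok <- res$ok
  out <- read_set(res$seq[ok], res$qual[ok], fwd$id[ok])
  attr(out, "overlap") <- data.frame(id = fwd$id[ok],
                                     overlap = res$overlap[ok],
                                     mismatches = res$mismatches[ok])
  out
}

#' Run the full QC pipeline on a set of read pairs
#'
#' Applies, per mate: primer removal, quality trimming, content filter and
#' length filter; gates pairs on both mates surviving; merges surviving
#' pairs by overlap. Stage counts (pairs whose mates have both survived all
#' stages so far) are non-increasing by construction.
#'
#' @param fwd,rev forward and reverse [read_set()]s with matching ids.
#' @param primers list with `fwd` and `rev` primer strings.
#' @param max_primer_mismatch,window,min_avg_q,max_ambiguous,homopolymer_len,min_len,max_len,min_overlap,max_mismatch_density
#'   stage thresholds; defaults are the pipeline's canonical values.
#' @return list with `merged` (a [read_set()]) and `report` (a
#'   `qc_report` data frame of per-stage pair counts).
#' @export
run_qc <- function(fwd, rev, primers = vert12s_primers(),
                   max_primer_mismatch = 3, window = 10, min_avg_q = 25,
                   max_ambiguous = 5, homopolymer_len = 6,
                   min_len = 55, max_len = 106,
                   min_overlap = 15, max_mismatch_density = 0.10) {
  stage_ids <- function(reads, primer) {
    ids <- list()
    reads <- strip_primers(reads, primer, max_primer_mismatch)
    ids$primer <- reads$id
    reads <- quality_trim(reads, window, min_avg_q)
    reads <- content_filter(reads, max_ambiguous, homopolymer_len)
    ids$content <- reads$id
    reads <- length_filter(reads, min_len, max_len)
    ids$length <- reads$id
    list(reads = reads, ids = ids)
  }
  f <- stage_ids(fwd, primers$fwd)
  r <- stage_ids(rev, primers$rev)
  gated <- pair_gate(f$reads, r$reads)
  merged <- merge_pairs(gated$forward, gated$reverse,
                        min_overlap, max_mismatch_density)
  counts <- c(
    input = nrow(fwd),
    primer = length(intersect(f$ids$primer, r$ids$primer)),
    content = length(intersect(f$ids$content, r$ids$content)),
    length = length(intersect(f$ids$length, r$ids$length)),
    merged = nrow(merged)
  )
  report <- data.frame(stage = names(counts), pairs = as.integer(counts),
                       row.names = NULL)
  report$fraction <- report$pairs / counts[["input"]]
  class(report) <- c("qc_report", "data.frame")
  list(merged = merged, report = report)
}
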