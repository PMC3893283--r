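#' Construct a read set
#'
#' A read set is a data frame with one row per read and columns `id`, `seq`
#' (A/C/G/T/N) and `qual` (phred+33 string, same length as `seq`).
#'
#' @param seq character vector of sequences.
#' @param qual character vector of phred+33 quality strings; defaults to
#'   Q40 throughout.
#' @param id read identifiers; auto-generated when `NULL`.
#' @return data frame of class `read_set`.
#' @export
read_set <- function(seq, qual = NULL, id = NULL) {
  if (is.null(qual))
    qual <- vapply(nchar(seq), function(l) strrep(rawToChar(as.raw(40 + 33)), l), "")
  if (is.null(id)) id <- sprintf("read%06d", seq_along(seq))
  if (any(nchar(seq) != nchar(qual)))
    stop_ednacensus("sequence and quality lengths differ")
  qr <- range(c(45L, unlist(phred_decode(qual))))
  if (qr[1] < 0 || qr[2] > 45)
    stop_ednacensus("phred qualities must lie in [0, 45]")
  structure(data.frame(id = id, seq = toupper(seq), qual = qual,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Read and write FASTQ (phred+33)
#'
#' Thin wrappers over Biostrings' quality-scaled string sets.
#'
#' @param reads a [read_set()].
#' @param path file path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a
#'   [read_set()].
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # suppressed: Biostrings warns about dropping its own metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  read_set(as.character(x), as.character(Biostrings::quality(x)), names(x))
}

#' Write a reference panel or database as FASTA
#'
#' Headers follow `id|species|genus|family|class`.
#'
#' @param records data frame with columns `id`, `species`, `genus`,
#'   `family`, `class`, `sequence`.
#' @param path output FASTA path.
#' @export
write_panel_fasta <- function(records, path) {
  hdr <- with(records, paste(id, species, genus, family, class, sep = "|"))
  x <- Biostrings::DNAStringSet(stats::setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 5))
    stop_ednacensus("FASTA headers must be id|species|genus|family|class")
  m <- do.call(rbind, parts)
  out <- data.frame(id = m[, 1], species = m[, 2], genus = m[, 3],
                    family = m[, 4], class = m[, 5],
                    sequence = as.character(x), row.names = NULL)
  class(out) <- c("reference_panel", "data.frame")
  out
}
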