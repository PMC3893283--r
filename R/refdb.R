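# Custom reference database: one randomly chosen species per genus, plus
# explicitly supplemented records for taxa missing from the base set. A
# taxon can exist in the study taxonomy but not in the database (no marker
# sequence available); downstream assignment then stops at family at best.

#' Keep one species per genus, chosen at random
#'
#' @param records data frame with at least `id`, `species`, `genus`,
#'   `family`, `class`, `sequence` columns.
#' @param seed integer seed; the selection is uniform per genus and
#'   deterministic under the seed.
#' @return a `reference_db` data frame with one record per genus and a
#'   `supplemental` flag column (all `FALSE`).
#' @export
dedupe_by_genus <- function(records, seed = 1) {
  .check_rank_chain(records)
  with_seed(seed, {
    picked <- unlist(lapply(split(seq_len(nrow(records)), records$genus),
                            function(i) i[sample.int(length(i), 1)]))
  })
  out <- records[sort(picked), , drop = FALSE]
  out$supplemental <- FALSE
  out$genus_duplicated <- FALSE
  rownames(out) <- NULL
  attr(out, "provenance") <- list(source_records = nrow(records), seed = seed,
                                  supplements = character(0))
  class(out) <- c("reference_db", "data.frame")
  out
}

.check_rank_chain <- function(records) {
  need <- c("species", "genus", "family", "class", "sequence")
  for (col in need) {
    if (!col %in% names(records))
      stop_ednacensus("records lack a '", col, "' column")
    bad <- which(is.na(records[[col]]) | !nzchar(records[[col]]))
    if (length(bad))
      stop_ednacensus("record ", records$id[bad[1]] %||% bad[1],
                      " (", records$species[bad[1]], ") is missing ", col)
  }
  invisible(TRUE)
}

#' Append supplemental records to a reference database
#'
#' Extras are appended verbatim; a supplement whose genus is already present
#' replaces nothing but is flagged `genus_duplicated`. Duplicate ids are an
#' error, as are extras with incomplete rank chains.
#'
#' @param db a `reference_db` from [dedupe_by_genus()].
#' @param extra_records data frame of records to append (same columns).
#' @return the extended `reference_db`.
#' @export
supplement <- function(db, extra_records) {
  if (!nrow(extra_records %||% data.frame())) return(db)
  .check_rank_chain(extra_records)
  if (any(extra_records$id %in% db$id))
    stop_ednacensus("duplicate record id(s): ",
                    paste(intersect(extra_records$id, db$id), collapse = ", "))
  extra <- extra_records[, c("id", "species", "genus", "family", "class", "sequence")]
  extra$supplemental <- TRUE
  extra$genus_duplicated <- extra$genus %in% db$genus
  prov <- attr(db, "provenance")
  out <- rbind(db[, names(extra)], extra)
  rownames(out) <- NULL
  prov$supplements <- c(prov$supplements, extra$species)
  attr(out, "provenance") <- prov
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Extract an amplicon from a genome by in silico PCR
#'
#' Finds the best forward-primer site and the best downstream
#' reverse-complemented reverse-primer site (each within `max_mismatch`
#' Hamming mismatches, no indels), on either strand, and returns the
#' between-primer insert reported 5' to 3' from the forward primer. Site
#' pairs whose insert falls outside [30, 300] bp are ignored.
#'
#' @param genome_sequence nucleotide string (e.g. a mitogenome).
#' @param fwd_primer,rev_primer primer strings, 5' to 3'.
#' @param max_mismatch per-primer mismatch tolerance.
#' @return a list with `amplicon`, `strand`, `start`, `end`, `mismatches`
#'   (insert coordinates, 1-based on the searched strand), or `NULL` when no
#'   qualifying site pair exists.
#' @export
in_silico_pcr <- function(genome_sequence, fwd_primer, rev_primer,
                          max_mismatch = 3) {
  if (!nzchar(fwd_primer) || !nzchar(rev_primer))
    stop_ednacensus("primers must be non-empty")
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(genome_sequence) else revcomp(genome_sequence)
    subj <- Biostrings::DNAString(s)
    fhits <- Biostrings::matchPattern(fwd_primer, subj, max.mismatch = max_mismatch)
    rhits <- Biostrings::matchPattern(revcomp(rev_primer), subj,
                                      max.mismatch = max_mismatch)
    if (!length(fhits) || !length(rhits)) next
    fmm <- Biostrings::neditAt(fwd_primer, subj, at = Biostrings::start(fhits))
    rmm <- Biostrings::neditAt(revcomp(rev_primer), subj,
                               at = Biostrings::start(rhits))
    for (i in seq_along(fhits)) for (j in seq_along(rhits)) {
      ins_start <- Biostrings::end(fhits)[i] + 1L
      ins_end <- Biostrings::start(rhits)[j] - 1L
      len <- ins_end - ins_start + 1L
      if (len < 30 || len > 300) next
      mm <- fmm[i] + rmm[j]
      if (is.null(best) || mm < best$mismatches) {
        best <- list(amplicon = substr(s, ins_start, ins_end),
                     strand = strand, start = ins_start, end = ins_end,
                     mismatches = as.integer(mm))
      }
    }
  }
  best
}

#' Write / read a reference database (FASTA + taxonomy sidecar)
#'
#' @param db a `reference_db`.
#' @param fasta_path,tsv_path output paths.
#' @return `write_refdb()` returns `fasta_path` invisibly; `read_refdb()`
#'   the reconstructed `reference_db`.
#' @export
write_refdb <- function(db, fasta_path, tsv_path) {
  write_panel_fasta(db, fasta_path)
  utils::write.table(
    db[, c("id", "species", "genus", "family", "class", "supplemental")],
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(fasta_path, tsv_path) {
  fa <- read_panel_fasta(fasta_path)
  side <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  out <- merge(fa, side[, c("id", "supplemental")], by = "id", sort = TRUE)
  out$genus_duplicated <- duplicated(out$genus) | duplicated(out$genus, fromLast = TRUE)
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Build the scenario reference database from a panel
#'
#' Emulates database construction against an incomplete public archive:
#' genera named in `exclude_genera` are withheld entirely (no marker
#' sequence available), `supplement_species` are withheld from the base set
#' and then appended as explicit supplements, and the remainder is deduped
#' to one species per genus.
#'
#' @param panel a [make_reference_panel()] panel.
#' @param seed selection seed for [dedupe_by_genus()].
#' @param exclude_genera genera absent from the database.
#' @param supplement_species species added back as supplements.
#' @return a `reference_db`.
#' @export
build_refdb <- function(panel, seed = 1, exclude_genera = character(0),
                        supplement_species = character(0)) {
  base <- panel[!(panel$genus %in% exclude_genera) &
                  !(panel$species %in% supplement_species), , drop = FALSE]
  db <- dedupe_by_genus(base, seed = seed)
  extras <- panel[panel$species %in% supplement_species &
                    !(panel$genus %in% exclude_genera), , drop = FALSE]
  supplement(db, extras)
}
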