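#' Construct a taxon composition profile
#'
#' A profile maps taxa (all at one stated rank) to proportions that sum to 1.
#' Profiles are the common currency of the pipeline: shed DNA per genus,
#' source compositions (intake, gel feed, pellet feed), and observed read
#' proportions are all profiles.
#'
#' @param x named non-negative numeric vector; names are taxa.
#' @param rank rank of the taxa (`"species"`, `"genus"`, `"family"` or
#'   `"class"`).
#' @param normalize if `TRUE`, rescale `x` to sum to 1; if `FALSE` (default)
#'   the sum must already be 1 within `tol`.
#' @param tol tolerance on the unit-sum invariant.
#' @return a named numeric vector of class `taxon_profile` with a `rank`
#'   attribute.
#' @export
taxon_profile <- function(x, rank = "genus", normalize = FALSE, tol = 1e-9) {
  if (!length(x)) stop_ednacensus("empty profile")
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    stop_ednacensus("profile values must have unique, non-empty taxon names")
  if (any(x < 0)) stop_ednacensus("profile proportions must be non-negative")
  rank <- match.arg(rank, TAXON_RANKS)
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  if (normalize) {
    s <- sum(x)
    if (s <= 0) stop_ednacensus("cannot normalize a zero profile")
    x <- x / s
  } else if (abs(sum(x) - 1) > tol) {
    stop_ednacensus("profile must sum to 1 (got ", format(sum(x)), ")")
  }
  structure(x, rank = rank, class = c("taxon_profile", "numeric"))
}

profile_rank <- function(p) attr(p, "rank")

#' @export
print.taxon_profile <- function(x, ...) {
  cat("<taxon_profile> rank=", profile_rank(x), ", ", length(x), " taxa\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Align two or more profiles on the union of their taxa (missing taxa -> 0).
# Returns a matrix with one row per profile.
align_profiles <- function(...) {
  ps <- list(...)
  taxa <- Reduce(union, lapply(ps, names))
  rows <- lapply(ps, function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p)] <- as.numeric(p)
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- taxa
  m
}

#' Collapse a profile to a coarser rank
#'
#' Proportions are summed within parent taxa; total mass is conserved.
#'
#' @param profile a [taxon_profile()].
#' @param to_rank target rank, at or above the profile's rank.
#' @param tax a [taxonomy()] covering every taxon in the profile (errors
#'   naming any missing taxon).
#' @return a [taxon_profile()] at `to_rank`.
#' @export
collapse_profile <- function(profile, to_rank, tax) {
  stopifnot(inherits(profile, "taxon_profile"))
  from <- profile_rank(profile)
  if (to_rank == from) return(profile)
  parents <- ancestor_at(tax, names(profile), from, to_rank)
  v <- tapply(as.numeric(profile), parents, sum)
  taxon_profile(stats::setNames(as.numeric(v), names(v)), rank = to_rank,
                tol = 1e-6)
}

#' Read / write profile tables
#'
#' Tab-separated with columns `taxon`, `rank`, `proportion` and optionally
#' `reads`.
#'
#' @param profile a [taxon_profile()].
#' @param path file path.
#' @param reads optional named vector of per-taxon read counts.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a [taxon_profile()].
#' @export
write_profile_tsv <- function(profile, path, reads = NULL) {
  df <- data.frame(taxon = names(profile),
                   rank = profile_rank(profile),
                   proportion = as.numeric(profile))
  df <- df[order(-df$proportion, df$taxon), ]
  if (!is.null(reads)) df$reads <- as.integer(reads[df$taxon])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxon_profile(stats::setNames(df$proportion, df$taxon),
                rank = unique(df$rank), tol = 1e-6)
}
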