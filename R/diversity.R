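# Shannon diversity and rarefaction. Subsampling is without replacement
# (multivariate hypergeometric): the pool is a finite set of assigned reads.

#' Shannon diversity index (natural log)
#'
#' H' = -sum(p_i * ln(p_i)) over taxa with p_i > 0, in nats. H' is 0 for a
#' single taxon and maximal (ln k) for the uniform profile over k taxa.
#'
#' @param profile a [taxon_profile()] or named numeric vector summing to 1.
#' @return H' in nats (non-negative).
#' @export
shannon <- function(profile) {
  p <- as.numeric(profile)
  if (!length(p)) stop_ednacensus("empty profile")
  if (abs(sum(p) - 1) > 1e-6) stop_ednacensus("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

# Multivariate hypergeometric subsampling: n independent draws of `depth`
# reads without replacement from the pool described by `counts`. Sequential
# conditional rhyper draws, vectorized across the n subsamples.
subsample_counts <- function(counts, depth, n) {
  k <- length(counts)
  total <- sum(counts)
  if (depth > total) stop_ednacensus("depth exceeds the read pool")
  out <- matrix(0L, n, k, dimnames = list(NULL, names(counts)))
  need <- rep(as.integer(depth), n)
  remaining <- total
  for (j in seq_len(k - 1)) {
    remaining <- remaining - counts[j]
    draw <- stats::rhyper(n, counts[j], remaining, need)
    out[, j] <- draw
    need <- need - draw
  }
  out[, k] <- need
  out
}

#' Rarefaction by repeated subsampling
#'
#' For each depth, `n_subsamples` subsamples are drawn without replacement
#' from the read pool and the observed richness (taxa with at least one
#' read) recorded.
#'
#' @param taxon_counts named integer vector of reads per taxon (the pool).
#' @param depths subsample sizes; all must be at most the pool size.
#' @param n_subsamples subsamples per depth.
#' @param seed integer seed.
#' @return object of class `rarefaction_curve`: list with `depths`,
#'   `mean_richness`, the full `richness` matrix (`n_subsamples` x depths),
#'   `n_subsamples`, `total_taxa`, `seed`.
#' @export
rarefy <- function(taxon_counts, depths, n_subsamples = 1000, seed = 1) {
  stopifnot(n_subsamples >= 1, all(depths >= 1))
  taxon_counts <- taxon_counts[taxon_counts > 0]
  total <- sum(taxon_counts)
  if (any(depths > total))
    stop_ednacensus("depth(s) exceed total reads (", total, ")")
  depths <- as.integer(depths)
  rich <- with_seed(seed, {
    vapply(depths, function(d) {
      rowSums(subsample_counts(taxon_counts, d, n_subsamples) > 0L)
    }, numeric(n_subsamples))
  })
  rich <- matrix(rich, nrow = n_subsamples,
                 dimnames = list(NULL, as.character(depths)))
  structure(list(depths = depths,
                 mean_richness = colMeans(rich),
                 richness = rich,
                 n_subsamples = n_subsamples,
                 total_taxa = length(taxon_counts),
                 seed = seed),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("<rarefaction_curve> ", length(x$depths), " depths (",
      min(x$depths), "-", max(x$depths), "), ", x$n_subsamples,
      " subsamples, ", x$total_taxa, " taxa in pool\n", sep = "")
  invisible(x)
}

#' Sliding-window confidence band for a rarefaction curve
#'
#' Windows of `window` reads of depth, overlapping by `overlap` (step =
#' `window * (1 - overlap)`), pool the subsample richness values whose depth
#' falls inside the window; the 2.5th and 97.5th percentiles of each pool
#' form the band, reported at the window midpoint.
#'
#' @param curve a [rarefy()] result.
#' @param window window width in reads of depth.
#' @param overlap fractional overlap between successive windows.
#' @return data frame with `midpoint`, `lo`, `hi`, `n_values`.
#' @export
ci_band <- function(curve, window = 20000, overlap = 0.20) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  if (max(curve$depths) < window)
    stop_ednacensus("curve spans less than one window")
  step <- window * (1 - overlap)
  starts <- seq(0, max(curve$depths), by = step)
  rows <- lapply(starts, function(s) {
    sel <- curve$depths >= s & curve$depths < s + window
    if (!any(sel)) return(NULL)
    vals <- as.numeric(curve$richness[, sel, drop = FALSE])
    qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    data.frame(midpoint = s + window / 2, lo = qs[1], hi = qs[2],
               n_values = length(vals))
  })
  do.call(rbind, rows)
}

#' Closed-form detection probability under subsampling
#'
#' Probability that a taxon with `taxon_reads` reads in a pool of
#' `total_reads` appears at least once in a without-replacement subsample of
#' `depth` reads (hypergeometric).
#'
#' @param total_reads pool size.
#' @param taxon_reads reads belonging to the taxon.
#' @param depth subsample size.
#' @return detection probability.
#' @export
detect_probability <- function(total_reads, taxon_reads, depth) {
  if (depth > total_reads - taxon_reads) return(1)
  1 - exp(lchoose(total_reads - taxon_reads, depth) - lchoose(total_reads, depth))
}
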