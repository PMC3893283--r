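# Detection accuracy against a known community: lowest detected rank per
# species, false-negative / false-positive rates, source attribution of
# tank-detected families, and rank-abundance agreement.

#' Lowest rank at which each species was detected
#'
#' A species is detected at genus if its genus appears in the genus-rank
#' tank profile; failing that, at family if its family appears in the
#' family-rank profile; otherwise it is undetected. A species whose genus
#' has no reference record can reach family at best.
#'
#' @param species character vector of species names (present in `tax`).
#' @param genus_profile,family_profile observed tank [taxon_profile()]s.
#' @param tax a [taxonomy()] containing every species (errors otherwise).
#' @return character vector: `"genus"`, `"family"` or `"none"`.
#' @export
lowest_rank_detected <- function(species, genus_profile, family_profile, tax) {
  lin <- lineages(tax)
  i <- match(species, lin$species)
  if (anyNA(i))
    stop_ednacensus("species not in taxonomy: ",
                    paste(species[is.na(i)], collapse = ", "))
  ifelse(lin$genus[i] %in% names(genus_profile), "genus",
         ifelse(lin$family[i] %in% names(family_profile), "family", "none"))
}

#' Family-level false-negative rate
#'
#' The fraction of community families (within an optional subset) with no
#' member detected at family rank or lower.
#'
#' @param community data frame with `species`, `family` and a detection
#'   column `detected_rank` (`"genus"`, `"family"` or `"none"`), e.g. the
#'   [open_sea_tank()] fixture or a pipeline detection table.
#' @param subset optional logical vector (length `nrow(community)`)
#'   restricting the community, e.g. bony fishes only.
#' @return list with `rate`, `undetected` (family names), `n_families`.
#' @export
false_negative_rate <- function(community, subset = NULL) {
  stopifnot(all(c("family", "detected_rank") %in% names(community)))
  if (!is.null(subset)) community <- community[subset, , drop = FALSE]
  if (!nrow(community)) stop_ednacensus("empty community subset")
  det <- tapply(community$detected_rank %in% c("genus", "family"),
                community$family, any)
  list(rate = sum(!det) / length(det),
       undetected = names(det)[!det],
       n_families = length(det))
}

#' Family-level false-positive rate
#'
#' The fraction of tank-detected families attributable to no source --
#' neither the tank community, nor the intake, nor either feed.
#'
#' @param detected_families families detected in the tank sample.
#' @param attribution data frame with columns `family` and `source`
#'   (`"tank"`, `"intake"`, `"feed"` or `"unknown"`), e.g. from
#'   [attribute_families()] or the [tank_family_sources()] fixture.
#' @return list with `rate`, `unexplained` (families), `n_detected`.
#' @export
false_positive_rate <- function(detected_families, attribution) {
  stopifnot(all(c("family", "source") %in% names(attribution)))
  if (!length(detected_families)) stop_ednacensus("no detected families")
  src <- attribution$source[match(detected_families, attribution$family)]
  unexplained <- detected_families[is.na(src) | src == "unknown"]
  list(rate = length(unexplained) / length(detected_families),
       unexplained = unexplained,
       n_detected = length(detected_families))
}

#' Attribute tank-detected families to sources
#'
#' A family is attributed to `tank` if a community member belongs to it,
#' else to `intake` or `feed` if the corresponding source profile carries it
#' above the retention threshold, else to `unknown`.
#'
#' @param detected_families families detected in the tank sample.
#' @param community community data frame with a `family` column.
#' @param sources list of genus-rank [taxon_profile()]s `intake`, `gel`,
#'   `pellet`.
#' @param tax a [taxonomy()] used to map source genera to families.
#' @param min_fraction retention threshold for a source to count.
#' @return data frame with `family` and `source`.
#' @export
attribute_families <- function(detected_families, community, sources, tax,
                               min_fraction = 1e-4) {
  fam_of <- function(profile) {
    fams <- ancestor_at(tax, names(profile), "genus", "family")
    unique(fams[as.numeric(profile) > min_fraction])
  }
  intake_f <- fam_of(sources$intake)
  feed_f <- union(fam_of(sources$gel), fam_of(sources$pellet))
  src <- ifelse(detected_families %in% community$family, "tank",
         ifelse(detected_families %in% intake_f, "intake",
         ifelse(detected_families %in% feed_f, "feed", "unknown")))
  data.frame(family = detected_families, source = src, row.names = NULL)
}

#' Detection report for a censused community
#'
#' @param community community data frame (`species`, `genus`, `family`,
#'   `class`).
#' @param genus_profile,family_profile observed tank profiles.
#' @param tax a [taxonomy()].
#' @param sources optional source profiles for false-positive attribution.
#' @param bony_class class label defining the bony-fish subset.
#' @return object of class `detection_report`: the per-species detection
#'   table, `fn_all` and `fn_bony` ([false_negative_rate()] results), and
#'   when sources are given `attribution` and `fp`
#'   ([false_positive_rate()] result).
#' @export
detection_report <- function(community, genus_profile, family_profile, tax,
                             sources = NULL, bony_class = "Actinopterygii") {
  det <- community
  det$detected_rank <- lowest_rank_detected(det$species, genus_profile,
                                            family_profile, tax)
  fn_all <- false_negative_rate(det)
  fn_bony <- false_negative_rate(det, subset = det$class == bony_class)
  out <- list(detection = det, fn_all = fn_all, fn_bony = fn_bony)
  if (!is.null(sources)) {
    detected_fams <- names(family_profile)
    out$attribution <- attribute_families(detected_fams, community, sources, tax)
    out$fp <- false_positive_rate(detected_fams, out$attribution)
  }
  structure(out, class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  cat("  families undetected:", x$fn_all$rate * x$fn_all$n_families, "/",
      x$fn_all$n_families, "(rate", signif(x$fn_all$rate, 3), ")\n")
  cat("  bony-fish families undetected:",
      x$fn_bony$rate * x$fn_bony$n_families, "/", x$fn_bony$n_families,
      "(rate", signif(x$fn_bony$rate, 3), ")\n")
  if (!is.null(x$fp))
    cat("  false-positive families:", length(x$fp$unexplained), "/",
        x$fp$n_detected, "(rate", signif(x$fp$rate, 3), ")\n")
  invisible(x)
}

#' Rank-abundance agreement between two composition vectors
#'
#' Reports whether the descending orders of the two vectors coincide
#' exactly, plus Kendall-style concordant/discordant pair counts. Invariant
#' to rescaling either vector.
#'
#' @param edna_props,biomass_props named numeric vectors over the same taxa.
#' @return list with `agree` (logical), `concordant`, `discordant`,
#'   `n_pairs`.
#' @export
rank_agreement <- function(edna_props, biomass_props) {
  if (length(edna_props) != length(biomass_props) ||
      !setequal(names(edna_props), names(biomass_props)))
    stop_ednacensus("vectors must cover the same taxa")
  b <- biomass_props[names(edna_props)]
  pairs <- utils::combn(length(edna_props), 2)
  s1 <- sign(edna_props[pairs[1, ]] - edna_props[pairs[2, ]])
  s2 <- sign(b[pairs[1, ]] - b[pairs[2, ]])
  concordant <- sum(s1 * s2 > 0)
  discordant <- sum(s1 * s2 < 0)
  agree <- identical(order(-as.numeric(edna_props)),
                     order(-as.numeric(b)))
  list(agree = agree, concordant = concordant, discordant = discordant,
       n_pairs = ncol(pairs))
}

#' Log-linear fit of composition against abundance
#'
#' Ordinary least squares of `y` on `ln(x)` (`y = a * ln(x) + b`), the
#' exploratory fit used to relate recovered sequence proportions to
#' biomass proportions.
#'
#' @param y_props response proportions.
#' @param x_props predictor proportions; all must be positive.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
log_abundance_fit <- function(y_props, x_props) {
  if (any(x_props <= 0)) stop_ednacensus("all x values must be positive")
  fit <- stats::lm(y_props ~ log(x_props))
  # summary.lm warns on exact fits; those are legitimate degenerate inputs
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
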