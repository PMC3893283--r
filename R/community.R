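#' The Open Sea Tank census fixture
#'
#' The packaged census of the 4.5-million-liter Monterey Bay Aquarium Open
#' Sea Tank mesocosm: 12 vertebrate species with approximate individual
#' counts, estimated biomass, and the lowest taxonomic rank at which each
#' was detected by 12S eDNA sequencing. This is the ground-truth community
#' against which detection accuracy is scored, and the template for the
#' synthetic scenario generator.
#'
#' @return a list with components:
#' \describe{
#'   \item{community}{data frame: `species`, `common_name`, `genus`,
#'     `family`, `class`, `group`, `count`, `biomass_kg`,
#'     `lowest_rank_detected` (as printed: Genus / Family / No detect) and
#'     `detected_rank` (canonical: genus / family / none).}
#'   \item{taxonomy}{a [taxonomy()] over the 12 species.}
#'   \item{detection}{data frame `species`, `detected_rank`.}
#' }
#' @export
open_sea_tank <- function() {
  path <- system.file("extdata", "open_sea_tank_community.tsv",
                      package = "ednacensus", mustWork = TRUE)
  com <- utils::read.delim(path, stringsAsFactors = FALSE)
  com$detected_rank <- c("Genus" = "genus", "Family" = "family",
                         "No detect" = "none")[com$lowest_rank_detected]
  tax <- taxonomy_from_lineages(com)
  list(community = com,
       taxonomy = tax,
       detection = data.frame(species = com$species,
                              detected_rank = com$detected_rank))
}

#' Exogenous taxa of the mesocosm study system
#'
#' Lineages for the non-tank vertebrates that reach the tank through the
#' seawater intake (human, anchovy, livestock, sea otter, dog), the
#' commercial feeds (menhaden, turkey, chicken), the contaminant lineage
#' (rainbow trout, family Salmonidae), plus a reference-only congener-free
#' carangid (*Seriola*) that lets pilot-fish reads resolve to family the way
#' an incomplete public database would.
#'
#' @return data frame with columns `species`, `genus`, `family`, `class`.
#' @export
exogenous_taxa <- function() {
  data.frame(
    species = c("Homo sapiens", "Engraulis mordax", "Bos taurus",
                "Sus scrofa", "Gallus gallus", "Meleagris gallopavo",
                "Enhydra lutris", "Canis lupus", "Brevoortia tyrannus",
                "Oncorhynchus mykiss", "Seriola lalandi"),
    genus = c("Homo", "Engraulis", "Bos", "Sus", "Gallus", "Meleagris",
              "Enhydra", "Canis", "Brevoortia", "Oncorhynchus", "Seriola"),
    family = c("Hominidae", "Engraulidae", "Bovidae", "Suidae",
               "Phasianidae", "Phasianidae", "Mustelidae", "Canidae",
               "Clupeidae", "Salmonidae", "Carangidae"),
    class = c("Mammalia", "Actinopterygii", "Mammalia", "Mammalia", "Aves",
              "Aves", "Mammalia", "Mammalia", "Actinopterygii",
              "Actinopterygii", "Actinopterygii")
  )
}

#' Tank-detected families and their attributable sources
#'
#' Fixture enumerating the vertebrate families detected in the tank sample
#' and the source class each could be traced to (`tank`, `intake`, `feed`,
#' or `unknown` for DNA attributable to no sampled source).
#'
#' @return data frame with columns `family`, `example_taxon`, `source`.
#' @export
tank_family_sources <- function() {
  path <- system.file("extdata", "tank_family_sources.tsv",
                      package = "ednacensus", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Study-system taxonomy (tank plus exogenous taxa)
#'
#' @return a [taxonomy()] spanning the 12 tank species and the exogenous
#'   taxa of [exogenous_taxa()].
#' @export
study_taxonomy <- function() {
  tank <- open_sea_tank()$community[, c("species", "genus", "family", "class")]
  taxonomy_from_lineages(rbind(tank, exogenous_taxa()))
}
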