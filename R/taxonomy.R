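TAXON_RANKS <- c("species", "genus", "family", "class")

#' Construct a taxonomy
#'
#' A taxonomy is a table of taxon nodes at the ranks species, genus, family
#' and class, in which every non-class node has exactly one parent at the
#' next-higher rank. It is the rank scaffold used when collapsing read
#' profiles from genus to family and when scoring detections against a known
#' community.
#'
#' @param nodes data frame with columns `name`, `rank`
#'   (one of `"species"`, `"genus"`, `"family"`, `"class"`) and `parent`
#'   (`NA` for class-rank nodes).
#' @return an object of class `taxonomy`.
#' @seealso [taxonomy_from_lineages()] for the usual constructor.
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("name", "rank", "parent") %in% names(nodes)))
  nodes <- nodes[, c("name", "rank", "parent")]
  nodes$name <- as.character(nodes$name)
  nodes$rank <- as.character(nodes$rank)
  nodes$parent <- as.character(nodes$parent)
  if (!all(nodes$rank %in% TAXON_RANKS))
    stop_ednacensus("unknown rank(s): ", paste(setdiff(nodes$rank, TAXON_RANKS), collapse = ", "))
  for (r in TAXON_RANKS) {
    nm <- nodes$name[nodes$rank == r]
    if (anyDuplicated(nm))
      stop_ednacensus("duplicated ", r, " name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  for (i in seq_len(3)) { # species->genus, genus->family, family->class
    child <- nodes[nodes$rank == TAXON_RANKS[i], ]
    parents <- nodes$name[nodes$rank == TAXON_RANKS[i + 1]]
    bad <- child$name[is.na(child$parent) | !(child$parent %in% parents)]
    if (length(bad))
      stop_ednacensus("node(s) without a valid ", TAXON_RANKS[i + 1], " parent: ",
                      paste(bad, collapse = ", "))
  }
  structure(list(nodes = nodes), class = "taxonomy")
}

#' Build a taxonomy from species lineages
#'
#' @param lineages data frame with columns `species`, `genus`, `family`,
#'   `class`, one row per species.
#' @return a [taxonomy()] object.
#' @export
taxonomy_from_lineages <- function(lineages) {
  stopifnot(all(c("species", "genus", "family", "class") %in% names(lineages)))
  l <- unique(lineages[, c("species", "genus", "family", "class")])
  nodes <- rbind(
    data.frame(name = l$species, rank = "species", parent = l$genus),
    unique(data.frame(name = l$genus, rank = "genus", parent = l$family)),
    unique(data.frame(name = l$family, rank = "family", parent = l$class)),
    unique(data.frame(name = unique(l$class), rank = "class", parent = NA_character_))
  )
  taxonomy(nodes)
}

#' Species-level lineage table of a taxonomy
#'
#' @param tax a [taxonomy()] object.
#' @return data frame with columns `species`, `genus`, `family`, `class`.
#' @export
lineages <- function(tax) {
  stopifnot(inherits(tax, "taxonomy"))
  n <- tax$nodes
  sp <- n[n$rank == "species", ]
  gn <- n[n$rank == "genus", ]
  fm <- n[n$rank == "family", ]
  genus <- sp$parent
  family <- gn$parent[match(genus, gn$name)]
  cls <- fm$parent[match(family, fm$name)]
  data.frame(species = sp$name, genus = genus, family = family, class = cls,
             row.names = NULL)
}

#' Map taxon names to an ancestor rank
#'
#' @param tax a [taxonomy()] object.
#' @param names taxon names, all at rank `from`.
#' @param from,to ranks; `to` must be equal to or coarser than `from`.
#' @return character vector of ancestor names at rank `to`; errors naming any
#'   taxon absent from the taxonomy.
#' @export
ancestor_at <- function(tax, names, from, to) {
  stopifnot(inherits(tax, "taxonomy"))
  i_from <- match(from, TAXON_RANKS)
  i_to <- match(to, TAXON_RANKS)
  if (is.na(i_from) || is.na(i_to) || i_to < i_from)
    stop_ednacensus("'to' must be a rank at or above '", from, "'")
  out <- names
  for (i in seq_len(i_to - i_from)) {
    lvl <- TAXON_RANKS[i_from + i - 1L]
    nd <- tax$nodes[tax$nodes$rank == lvl, ]
    idx <- match(out, nd$name)
    if (anyNA(idx))
      stop_ednacensus("taxon not in taxonomy at rank ", lvl, ": ",
                      paste(unique(out[is.na(idx)]), collapse = ", "))
    out <- nd$parent[idx]
  }
  out
}

#' @export
print.taxonomy <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = TAXON_RANKS))
  cat("<taxonomy> ", paste(tab, names(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}
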