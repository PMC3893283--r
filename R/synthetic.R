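#' The vertebrate 12S primer pair
#'
#' Forward and reverse primers bounding the 106 bp variable region of the
#' mitochondrial 12S rRNA gene used throughout the pipeline.
#'
#' @return list with elements `fwd` and `rev` (plain A/C/G/T strings).
#' @export
vert12s_primers <- function() {
  list(fwd = "ACTGGGATTAGATACCCC", rev = "TAGAACAGGCTCCTCTAG")
}

#' Biomass-driven DNA shedding profile
#'
#' Converts a community table into the genus-level composition of
#' tank-generated eDNA under a power-law shedding model: the proportion of
#' genus g is proportional to the sum over its amplifiable species of
#' biomass^gamma. `gamma = 1` is biomass-proportional shedding; `gamma < 1`
#' compresses differences between large and small species; `gamma = 0`
#' ignores biomass entirely. Species flagged non-amplifiable (primer
#' dropout) contribute nothing.
#'
#' @param community data frame with columns `genus`, `biomass_kg` and
#'   logical `amplifiable`.
#' @param shedding_exponent the exponent gamma (unitless).
#' @return a genus-rank [taxon_profile()].
#' @export
shed_profile <- function(community, shedding_exponent = 1) {
  stopifnot(all(c("genus", "biomass_kg", "amplifiable") %in% names(community)))
  if (any(community$biomass_kg <= 0)) stop_ednacensus("biomass must be > 0")
  amp <- community[community$amplifiable, ]
  if (!nrow(amp)) stop_ednacensus("no amplifiable species in community")
  w <- tapply(amp$biomass_kg^shedding_exponent, amp$genus, sum)
  taxon_profile(stats::setNames(as.numeric(w), names(w)), rank = "genus",
                normalize = TRUE)
}

#' Mix a tank-generated profile with exogenous sources
#'
#' Forms the observed tank composition as the weighted sum
#' `q * tank_gen + x * intake + y * gel + z * pellet` over the union of all
#' taxa. With weights on the simplex and unit-sum inputs, the output sums
#' to 1.
#'
#' @param tank_gen [taxon_profile()] of tank-generated DNA.
#' @param sources list with [taxon_profile()] elements `intake`, `gel`,
#'   `pellet`.
#' @param weights numeric `c(q, x, y, z)` or a [mixing_params()] object.
#' @return a [taxon_profile()] over the union of taxa.
#' @export
mix_profiles <- function(tank_gen, sources, weights) {
  if (inherits(weights, "mixing_params")) weights <- weights$source_weights
  weights <- as.numeric(weights)
  if (length(weights) != 4) stop_ednacensus("weights must be (q, x, y, z)")
  if (any(weights < 0)) stop_ednacensus("mixing weights must be non-negative")
  stopifnot(all(c("intake", "gel", "pellet") %in% names(sources)))
  for (p in c(list(tank_gen), sources[c("intake", "gel", "pellet")]))
    if (abs(sum(p) - 1) > 1e-9) stop_ednacensus("input profiles must sum to 1")
  m <- align_profiles(tank_gen, sources$intake, sources$gel, sources$pellet)
  v <- as.numeric(weights %*% m)
  taxon_profile(stats::setNames(v, colnames(m)), rank = profile_rank(tank_gen),
                normalize = abs(sum(weights) - 1) > 1e-9, tol = 1e-6)
}

# ---------------------------------------------------------------------------
# Reference panel generation.
#
# Sequences are built so that the 97%/99% identity thresholds are meaningful
# on an `amplicon_length` fragment:
#   congeners differ at <= 1 site        (identity >= 1 - 1/L >= 0.99)
#   confamilial genera differ at 2-3     (0.97 <= identity < 0.99)
#   cross-family pairs differ at >= 12   (identity < 0.97)
# Three diagnostic positions are reserved per amplicon: two genus sites and
# one species site; family backbones are random sequences kept free of long
# homopolymer runs (which would be rejected by read QC downstream).

BASES <- c("A", "C", "G", "T")

# random backbone with no run of 4+ identical bases
.random_backbone <- function(len) {
  v <- character(len)
  for (i in seq_len(len)) {
    ok <- BASES
    if (i > 3 && v[i - 1] == v[i - 2] && v[i - 2] == v[i - 3])
      ok <- setdiff(BASES, v[i - 1])
    v[i] <- sample(ok, 1)
  }
  v
}

.shift_base <- function(base, k) BASES[((match(base, BASES) - 1L + k) %% 4L) + 1L]

.max_run <- function(s) {
  r <- rle(strsplit(s, "")[[1]])
  max(r$lengths)
}

#' Generate a synthetic reference panel
#'
#' Builds one amplicon sequence per species in the taxonomy, with pairwise
#' identities engineered into three bands: congeners at or above 0.99,
#' confamilial (different-genus) pairs in [0.97, 0.99), and cross-family
#' pairs below 0.97. Genus pairs listed in `indistinct_genera` share their
#' genus-diagnostic sites, so their species fall in the congener band --
#' emulating marker regions that cannot separate two genera at the 99%
#' threshold.
#'
#' @param tax a [taxonomy()].
#' @param amplicon_length fragment length in bp; must lie in [100, 199] for
#'   the three bands to be simultaneously realizable.
#' @param seed integer seed; the panel is deterministic under it.
#' @param indistinct_genera list of length-2 character vectors naming
#'   same-family genus pairs to be made mutually unresolvable.
#' @return data frame of class `reference_panel` with columns `id`,
#'   `species`, `genus`, `family`, `class`, `sequence`.
#' @export
make_reference_panel <- function(tax, amplicon_length = 106, seed = 1,
                                 indistinct_genera = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  L <- as.integer(amplicon_length)
  if (L < 100 || L > 199)
    stop_ednacensus("amplicon_length must be in [100, 199] for the identity ",
                    "bands (<=1 congener diff, 2-3 confamilial diffs) to hold")
  lin <- lineages(tax)
  if (!nrow(lin)) stop_ednacensus("empty taxonomy")
  g_pos <- c(max(4L, floor(L * 0.2)), floor(L * 0.4))
  s_pos <- floor(L * 0.6)
  var_pos <- c(g_pos, s_pos)

  # genus "slots": indistinct pairs share one slot (same genus sites)
  slot_of <- stats::setNames(lin$genus, lin$genus)
  for (pair in indistinct_genera %||% list()) {
    fams <- unique(lin$family[lin$genus %in% pair])
    if (length(pair) != 2 || length(fams) != 1)
      stop_ednacensus("indistinct_genera entries must be same-family genus pairs")
    slot_of[pair[2]] <- pair[1]
  }

  build <- function() {
    fams <- sort(unique(lin$family))
    backbones <- lapply(stats::setNames(fams, fams),
                        function(f) .random_backbone(L))
    # cross-family backbone separation at non-diagnostic positions
    keep <- setdiff(seq_len(L), var_pos)
    if (length(fams) > 1) {
      for (i in seq_along(fams)[-1]) for (j in seq_len(i - 1)) {
        d <- sum(backbones[[i]][keep] != backbones[[j]][keep])
        if (d < 12) return(NULL)
      }
    }
    recs <- NULL
    for (f in fams) {
      fl <- lin[lin$family == f, ]
      slots <- unique(slot_of[unique(fl$genus)])
      if (length(slots) > 4)
        stop_ednacensus("infeasible band request: family ", f,
                        " needs more than 4 resolvable genus slots")
      for (si in seq_along(slots)) {
        gl <- fl[slot_of[fl$genus] == slots[si], ]
        sps <- gl$species
        if (length(sps) > 4)
          stop_ednacensus("infeasible band request: genus slot ", slots[si],
                          " has more than 4 species")
        for (ki in seq_along(sps)) {
          v <- backbones[[f]]
          v[g_pos[1]] <- .shift_base(backbones[[f]][g_pos[1]], si - 1L)
          v[g_pos[2]] <- .shift_base(backbones[[f]][g_pos[2]], si - 1L)
          v[s_pos] <- .shift_base(backbones[[f]][s_pos], ki - 1L)
          recs <- rbind(recs, data.frame(
            species = sps[ki],
            genus = gl$genus[ki],
            family = f,
            class = gl$class[ki],
            sequence = paste(v, collapse = "")
          ))
        }
      }
    }
    if (any(vapply(recs$sequence, .max_run, 1L) >= 6)) return(NULL)
    recs
  }

  recs <- with_seed(seed, {
    out <- NULL
    for (attempt in 1:100) {
      out <- build()
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(recs))
    stop_ednacensus("could not generate a band-conforming panel; ",
                    "try another seed or fewer taxa")
  recs <- recs[order(recs$species), ]
  recs <- data.frame(id = sprintf("ref%03d", seq_len(nrow(recs))), recs,
                     row.names = NULL)
  class(recs) <- c("reference_panel", "data.frame")
  .check_panel_bands(recs, indistinct_genera)
  recs
}

# brute-force verification of the engineered identity bands
.check_panel_bands <- function(panel, indistinct_genera = NULL) {
  n <- nrow(panel)
  if (n < 2) return(invisible(TRUE))
  L <- nchar(panel$sequence[1])
  mat <- do.call(rbind, strsplit(panel$sequence, ""))
  merged <- stats::setNames(panel$genus, panel$genus)
  for (pair in indistinct_genera %||% list()) merged[pair[2]] <- pair[1]
  for (i in 2:n) for (j in seq_len(i - 1)) {
    idy <- 1 - sum(mat[i, ] != mat[j, ]) / L
    same_genus <- merged[panel$genus[i]] == merged[panel$genus[j]]
    same_family <- panel$family[i] == panel$family[j]
    ok <- if (same_genus) idy >= 0.99
          else if (same_family) idy >= 0.97 && idy < 0.99
          else idy < 0.97
    if (!ok)
      stop_ednacensus("panel identity band violated for ", panel$species[i],
                      " vs ", panel$species[j], " (identity ", round(idy, 4), ")")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------

#' Define a mesocosm scenario with known ground truth
#'
#' Bundles everything the read simulator needs: the community (with
#' per-species biomass and an `amplifiable` primer-dropout flag), the
#' shedding exponent, exogenous source compositions, mixing weights, read
#' depth, per-base error rate and the scenario seed. An optional contaminant
#' profile is mixed in outside the four-source model (emulating trace DNA
#' attributable to no sampled source).
#'
#' @param community data frame with columns `species`, `genus`, `count`,
#'   `biomass_kg`, `amplifiable`.
#' @param source_profiles list of genus-rank [taxon_profile()]s named
#'   `intake`, `gel`, `pellet`.
#' @param mix_weights a [mixing_params()] object.
#' @param shedding_exponent power-law shedding exponent gamma.
#' @param read_depth number of read pairs to simulate.
#' @param error_rate per-base substitution probability in [0, 0.25).
#' @param seed integer seed governing every stochastic draw.
#' @param contam_profile optional genus-rank [taxon_profile()] of
#'   model-external contamination.
#' @param contam_weight proportion of reads drawn from `contam_profile`.
#' @param qc_fail list of per-read probabilities of planted QC failures,
#'   with elements `primer`, `quality`, `ambiguous`, `homopolymer`.
#' @return an object of class `mesocosm_truth`.
#' @export
mesocosm_truth <- function(community, source_profiles, mix_weights,
                           shedding_exponent = 1, read_depth = 20000L,
                           error_rate = 0.003, seed = 1,
                           contam_profile = NULL, contam_weight = 0,
                           qc_fail = list()) {
  stopifnot(all(c("species", "genus", "count", "biomass_kg", "amplifiable")
                %in% names(community)))
  if (any(community$biomass_kg <= 0)) stop_ednacensus("biomass must be > 0")
  if (any(community$count < 1)) stop_ednacensus("counts must be >= 1")
  read_depth <- as.integer(read_depth)
  if (read_depth < 1) stop_ednacensus("read_depth must be >= 1")
  if (error_rate < 0 || error_rate >= 0.25)
    stop_ednacensus("error_rate must be in [0, 0.25)")
  stopifnot(inherits(mix_weights, "mixing_params"))
  qc_fail <- utils::modifyList(
    list(primer = 0, quality = 0, ambiguous = 0, homopolymer = 0), qc_fail)
  if (contam_weight < 0 || contam_weight >= 1)
    stop_ednacensus("contam_weight must be in [0, 1)")
  if (contam_weight > 0 && is.null(contam_profile))
    stop_ednacensus("contam_weight > 0 requires a contam_profile")
  structure(list(community = community,
                 shedding_exponent = shedding_exponent,
                 source_profiles = source_profiles,
                 mix_weights = mix_weights,
                 read_depth = read_depth,
                 error_rate = error_rate,
                 seed = as.integer(seed),
                 contam_profile = contam_profile,
                 contam_weight = contam_weight,
                 qc_fail = qc_fail),
            class = "mesocosm_truth")
}

#' Expected observed tank composition under a scenario
#'
#' The genus-rank profile from which simulated read counts are drawn:
#' the shed profile mixed with the sources by (q, x, y, z), plus any
#' contaminant mass.
#'
#' @param truth a [mesocosm_truth()].
#' @return a genus-rank [taxon_profile()].
#' @export
expected_tank_profile <- function(truth) {
  shed <- shed_profile(truth$community, truth$shedding_exponent)
  mixed <- mix_profiles(shed, truth$source_profiles,
                        truth$mix_weights$source_weights)
  if (truth$contam_weight > 0) {
    m <- align_profiles(mixed, truth$contam_profile)
    v <- (1 - truth$contam_weight) * m[1, ] + truth$contam_weight * m[2, ]
    mixed <- taxon_profile(v, rank = "genus", normalize = TRUE)
  }
  mixed
}

#' Simulate paired-end amplicon reads for a scenario
#'
#' Draws per-genus read counts from a multinomial over the scenario's
#' expected tank composition, then emits read pairs as primer + template
#' copies with independent per-base substitution errors. Each mate is
#' primer (18 bp) plus the full amplicon; adapter read-through is not
#' simulated. Configurable fractions of forward mates are planted with QC
#' failures (corrupted primer, low-quality tail, excess ambiguous bases, or
#' a homopolymer run) so every filter stage is exercised.
#'
#' @param truth a [mesocosm_truth()].
#' @param panel a [make_reference_panel()] panel covering every genus with
#'   nonzero expected proportion.
#' @param primers primer pair as from [vert12s_primers()].
#' @return list with `forward` and `reverse` read sets (data frames `id`,
#'   `seq`, `qual`), a `truth_table` (`read_id`, `taxon`), and the expected
#'   `profile`.
#' @export
simulate_reads <- function(truth, panel, primers = vert12s_primers()) {
  stopifnot(inherits(truth, "mesocosm_truth"))
  prof <- expected_tank_profile(truth)
  tmpl <- stats::setNames(panel$sequence, panel$genus)
  tmpl <- tmpl[!duplicated(names(tmpl))] # one template per genus
  missing <- setdiff(names(prof)[as.numeric(prof) > 0], names(tmpl))
  if (length(missing))
    stop_ednacensus("no panel sequence for taxa: ", paste(missing, collapse = ", "))

  with_seed(truth$seed, {
    n <- truth$read_depth
    counts <- as.vector(stats::rmultinom(1, n, as.numeric(prof)))
    taxa <- rep(names(prof), counts)
    ord <- sample.int(n)
    taxa <- taxa[ord]
    ids <- sprintf("sim%07d", seq_len(n))

    fwd <- .apply_errors(paste0(primers$fwd, tmpl[taxa]), truth$error_rate)
    rev <- .apply_errors(paste0(primers$rev, revcomp(tmpl[taxa])),
                         truth$error_rate)
    fwd_seq <- fwd$seq; rev_seq <- rev$seq
    fwd_qual <- .draw_quals(nchar(fwd_seq), fwd$errors)
    rev_qual <- .draw_quals(nchar(rev_seq), rev$errors)

    # planted QC failures (forward mate only; the pair gate rejects the pair)
    pf <- truth$qc_fail
    cat_p <- c(primer = pf$primer, quality = pf$quality,
               ambiguous = pf$ambiguous, homopolymer = pf$homopolymer)
    if (sum(cat_p) > 0) {
      lab <- sample(c(names(cat_p), "clean"), n, replace = TRUE,
                    prob = c(cat_p, max(0, 1 - sum(cat_p))))
      np <- nchar(primers$fwd)
      i <- which(lab == "primer")
      if (length(i)) {
        pos <- c(1L, 5L, 9L, 13L)
        for (k in i) {
          v <- strsplit(substr(fwd_seq[k], 1, np), "")[[1]]
          v[pos] <- vapply(v[pos], .shift_base, "", k = 1L)
          fwd_seq[k] <- paste0(paste(v, collapse = ""),
                               substr(fwd_seq[k], np + 1, nchar(fwd_seq[k])))
        }
      }
      i <- which(lab == "quality")
      if (length(i)) {
        for (k in i) {
          len <- nchar(fwd_qual[k])
          bad <- intToUtf8(rep(15L + 33L, len - 49L))
          fwd_qual[k] <- paste0(substr(fwd_qual[k], 1, 49), bad)
        }
      }
      i <- which(lab == "ambiguous")
      if (length(i))
        for (k in i) substr(fwd_seq[k], 30, 35) <- "NNNNNN"
      i <- which(lab == "homopolymer")
      if (length(i))
        for (k in i) substr(fwd_seq[k], 40, 45) <- "AAAAAA"
    }

    list(forward = read_set(fwd_seq, fwd_qual, ids),
         reverse = read_set(rev_seq, rev_qual, ids),
         truth_table = data.frame(read_id = ids, taxon = taxa),
         profile = prof)
  })
}

# Substitution errors with their positions recorded, so that miscalled
# bases can be given low confidence scores (base-calling errors on real
# instruments are overwhelmingly low-quality calls).
.apply_errors <- function(seqs, rate) {
  errors <- vector("list", length(seqs))
  if (rate <= 0) return(list(seq = seqs, errors = errors))
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (k in which(nerr > 0)) {
    pos <- sample.int(lens[k], nerr[k])
    v <- strsplit(seqs[k], "")[[1]]
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(BASES, b), 1), "")
    seqs[k] <- paste(v, collapse = "")
    errors[[k]] <- pos
  }
  list(seq = seqs, errors = errors)
}

.draw_quals <- function(lens, errors = NULL) {
  total <- sum(lens)
  q <- sample(35:40, total, replace = TRUE) + 33L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(lens), function(k) {
    qi <- q[starts[k]:ends[k]]
    ep <- if (is.null(errors)) NULL else errors[[k]]
    if (length(ep)) qi[ep] <- sample(12:20, length(ep), replace = TRUE) + 33L
    intToUtf8(qi)
  }, "")
}
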