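# Default study-system scenario: the Open Sea Tank community plus the
# exogenous taxa reaching it through the intake and the two commercial
# feeds. Source compositions are seeded from the study system's reported
# values (human 50.7% of intake; menhaden 69.6% of gel and 46.2% of pellet;
# turkey 18.6% of gel); the remaining source mass is allocated once to
# plausible bay / feed taxa. All are configurable.

#' Default exogenous source compositions
#'
#' @return list of genus-rank [taxon_profile()]s `intake`, `gel`, `pellet`.
#' @export
default_source_profiles <- function() {
  list(
    intake = taxon_profile(c(Homo = 0.507, Engraulis = 0.15, Bos = 0.08,
                             Sus = 0.07, Gallus = 0.06, Enhydra = 0.05,
                             Canis = 0.04, Sardinops = 0.043),
                           rank = "genus"),
    gel = taxon_profile(c(Brevoortia = 0.696, Meleagris = 0.186,
                          Gallus = 0.06, Bos = 0.03, Sus = 0.028),
                        rank = "genus"),
    pellet = taxon_profile(c(Brevoortia = 0.462, Gallus = 0.2, Bos = 0.15,
                             Sus = 0.1, Meleagris = 0.088),
                           rank = "genus")
  )
}

#' Default mesocosm scenario
#'
#' Builds the full ground-truth scenario emulating the aquarium study
#' system: the 12-species tank community with primer dropout planted for
#' the cartilaginous fishes, the sea turtle and the ocean sunfish;
#' biomass-proportional shedding; source mixing weights
#' (q, x, y, z) = (69%, 30.9%, 0.14%, 0.024%) (renormalized); and a trace
#' Salmonidae contaminant (0.07% of reads) attributable to no source. The
#' in-tank genus generation weights (J, K, L, M) are derived from the shed
#' profile restricted to the four genus-resolvable tank genera, so the
#' recorded truth is exactly what an ideal mixing fit should recover.
#'
#' Two genera shed DNA but cannot reach genus-level assignment: the pilot
#' fish (*Naucrates*) has no reference record at all (its reads resolve to
#' family through a confamilial carangid), and the bonito (*Sarda*) has no
#' reference covering the amplicon, so its reads land in the confamilial
#' identity band of the other scombrids and resolve to family Scombridae.
#'
#' @param seed scenario seed.
#' @param read_depth number of simulated read pairs.
#' @param error_rate per-base substitution probability.
#' @param shedding_exponent power-law shedding exponent gamma.
#' @param qc_fail planted QC-failure fractions (see [mesocosm_truth()]);
#'   defaults emulate the study's roughly 80% QC pass rate.
#' @return list with components `truth` ([mesocosm_truth()]), `panel`
#'   (reference panel over tank + exogenous taxa), `taxonomy`,
#'   `tank_genera`, and the reference-database build instructions
#'   `refdb_exclude` / `refdb_supplements`.
#' @export
default_scenario <- function(seed = 1, read_depth = 20000,
                             error_rate = 0.003, shedding_exponent = 1,
                             qc_fail = list(primer = 0.05, quality = 0.10,
                                            ambiguous = 0.03,
                                            homopolymer = 0.02)) {
  fixture <- open_sea_tank()
  com <- fixture$community
  com$amplifiable <- com$class == "Actinopterygii" & com$species != "Mola mola"
  tax <- study_taxonomy()
  tank_genera <- c("Coryphaena", "Scomber", "Sardinops", "Thunnus")

  shed <- shed_profile(com, shedding_exponent)
  gw <- as.numeric(shed[tank_genera])
  gw <- stats::setNames(gw / sum(gw), tank_genera)

  qxyz <- c(q = 0.69, x = 0.309, y = 0.0014, z = 0.00024)
  qxyz <- qxyz / sum(qxyz)

  truth <- mesocosm_truth(
    community = com,
    source_profiles = default_source_profiles(),
    mix_weights = mixing_params(qxyz, gw),
    shedding_exponent = shedding_exponent,
    read_depth = read_depth,
    error_rate = error_rate,
    seed = seed,
    contam_profile = taxon_profile(c(Oncorhynchus = 1), rank = "genus"),
    contam_weight = 0.0007,
    qc_fail = qc_fail
  )

  panel <- make_reference_panel(tax, amplicon_length = 106, seed = seed)
  list(truth = truth, panel = panel, taxonomy = tax, tank_genera = tank_genera,
       refdb_exclude = c("Naucrates", "Sarda"),
       refdb_supplements = c("Coryphaena hippurus", "Sphyrna lewini"))
}
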