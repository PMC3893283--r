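test_that("the packaged tank census matches the printed community table", {
  fx <- open_sea_tank()
  com <- fx$community
  expect_equal(nrow(com), 12)
  expect_equal(sum(com$biomass_kg), 6824.45)

  sardine <- com[com$species == "Sardinops sagax", ]
  expect_equal(sardine$family, "Clupeidae")
  expect_equal(sardine$count, 13000)
  expect_equal(sardine$biomass_kg, 2600)
  expect_equal(sardine$lowest_rank_detected, "Genus")

  mola <- com[com$species == "Mola mola", ]
  expect_equal(mola$family, "Molidae")
  expect_equal(mola$count, 1)
  expect_equal(mola$biomass_kg, 1000)
  expect_equal(mola$lowest_rank_detected, "No detect")

  # taxonomy covers every species with a complete rank chain
  lin <- lineages(fx$taxonomy)
  expect_setequal(lin$species, com$species)
  expect_false(anyNA(lin))
})

test_that("shed_profile follows the power-law shedding model", {
  com2 <- data.frame(genus = c("A", "B"), biomass_kg = c(1, 1),
                     amplifiable = TRUE)
  expect_equal(as.numeric(shed_profile(com2, 1)), c(0.5, 0.5))

  com3 <- data.frame(genus = c("A", "B"), biomass_kg = c(2600, 2638),
                     amplifiable = TRUE)
  expect_equal(as.numeric(shed_profile(com3, 0)), c(0.5, 0.5))

  # the four detected tank genera, biomass-proportional (gamma = 1)
  com4 <- data.frame(genus = c("Coryphaena", "Sardinops", "Scomber", "Thunnus"),
                     biomass_kg = c(84, 2600, 7.7, 2638), amplifiable = TRUE)
  p <- shed_profile(com4, 1)
  expect_equal(as.numeric(p[c("Coryphaena", "Sardinops", "Scomber", "Thunnus")]),
               c(0.01576, 0.48784, 0.00144, 0.49496), tolerance = 1e-3)

  # non-amplifiable species contribute nothing
  com5 <- data.frame(genus = c("A", "B"), biomass_kg = c(10, 10),
                     amplifiable = c(TRUE, FALSE))
  expect_equal(as.numeric(shed_profile(com5, 1)), 1)
  expect_error(shed_profile(transform(com5, amplifiable = FALSE), 1),
               "amplifiable")
})

test_that("shed_profile is invariant to rescaling all biomasses", {
  set.seed(7)
  for (i in 1:5) {
    com <- data.frame(genus = paste0("g", 1:6),
                      biomass_kg = runif(6, 1, 2000),
                      amplifiable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
    g <- runif(1, 0.2, 1.5)
    p1 <- shed_profile(com, g)
    com$biomass_kg <- com$biomass_kg * runif(1, 0.01, 100)
    p2 <- shed_profile(com, g)
    expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-12)
  }
})

test_that("mix_profiles forms the weighted union composition", {
  tg <- taxon_profile(c(A = 0.6, B = 0.4))
  srcs <- list(intake = taxon_profile(c(C = 1)),
               gel = taxon_profile(c(D = 1)),
               pellet = taxon_profile(c(E = 1)))
  expect_equal(as.numeric(mix_profiles(tg, srcs, c(1, 0, 0, 0))[c("A", "B")]),
               c(0.6, 0.4))

  out <- mix_profiles(taxon_profile(c(A = 1)), srcs, c(0.5, 0.5, 0, 0))
  expect_equal(as.numeric(out[c("A", "C")]), c(0.5, 0.5))

  # three-taxon worked case, hand arithmetic
  tg3 <- taxon_profile(c(A = 0.5, B = 0.3, C = 0.2))
  s3 <- list(intake = taxon_profile(c(A = 0.1, C = 0.9)),
             gel = taxon_profile(c(B = 1)),
             pellet = taxon_profile(c(C = 1)))
  out3 <- mix_profiles(tg3, s3, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(as.numeric(out3[c("A", "B", "C")]),
               c(0.4 * 0.5 + 0.3 * 0.1,
                 0.4 * 0.3 + 0.2 * 1,
                 0.4 * 0.2 + 0.3 * 0.9 + 0.1 * 1),
               tolerance = 1e-12)
  expect_error(mix_profiles(tg3, s3, c(-0.1, 0.5, 0.3, 0.3)), "non-negative")
})

test_that("mix_profiles conserves mass for simplex weights", {
  set.seed(11)
  for (i in 1:10) {
    taxa <- paste0("t", 1:6)
    mk <- function() {
      v <- runif(6)
      taxon_profile(stats::setNames(v / sum(v), taxa))
    }
    w <- simplex_point(4)
    out <- mix_profiles(mk(), list(intake = mk(), gel = mk(), pellet = mk()), w)
    expect_equal(sum(out), 1, tolerance = 1e-9)
  }
})

test_that("reference panels respect the engineered identity bands", {
  panel <- tiny_panel(seed = 42)
  expect_equal(nrow(panel), 6)
  L <- nchar(panel$sequence[1])
  expect_equal(L, 106)

  # brute-force all-pairs check with an independent Hamming oracle
  for (i in 2:nrow(panel)) for (j in seq_len(i - 1)) {
    idy <- 1 - hamming(panel$sequence[i], panel$sequence[j]) / L
    if (panel$genus[i] == panel$genus[j]) {
      expect_gte(idy, 0.99)
    } else if (panel$family[i] == panel$family[j]) {
      expect_gte(idy, 0.97)
      expect_lt(idy, 0.99)
    } else {
      expect_lt(idy, 0.97)
    }
  }

  # congeners differ at no more than one site
  congeners <- panel[panel$genus == "Alpha", "sequence"]
  expect_lte(hamming(congeners[1], congeners[2]), 1)

  # determinism under the seed
  expect_identical(tiny_panel(seed = 42), tiny_panel(seed = 42))
  expect_false(identical(tiny_panel(seed = 42)$sequence,
                         tiny_panel(seed = 43)$sequence))
})

test_that("indistinct genus pairs land in the congener identity band", {
  panel <- tiny_panel(seed = 2, indistinct_genera = list(c("Alpha", "Beta")))
  a <- panel$sequence[panel$species == "Alpha one"]
  b <- panel$sequence[panel$species == "Beta one"]
  expect_gte(1 - hamming(a, b) / 106, 0.99)
  expect_error(tiny_panel(seed = 2, indistinct_genera = list(c("Alpha", "Gamma"))),
               "same-family")
})

test_that("simulated reads are exact templates when error-free", {
  lin <- tiny_lineages()[4, ] # a lone species
  tax1 <- taxonomy_from_lineages(lin)
  panel <- make_reference_panel(tax1, seed = 1)
  com <- data.frame(species = lin$species, genus = lin$genus,
                    family = lin$family, count = 5, biomass_kg = 10,
                    amplifiable = TRUE)
  truth <- mesocosm_truth(
    com,
    source_profiles = list(intake = taxon_profile(c(Gamma = 1)),
                           gel = taxon_profile(c(Gamma = 1)),
                           pellet = taxon_profile(c(Gamma = 1))),
    mix_weights = mixing_params(c(1, 0, 0, 0), c(Gamma = 1)),
    read_depth = 1000, error_rate = 0, seed = 9)
  sim <- simulate_reads(truth, panel)
  primers <- vert12s_primers()
  tmpl <- panel$sequence[1]
  expect_true(all(sim$forward$seq == paste0(primers$fwd, tmpl)))
  expect_true(all(sim$truth_table$taxon == "Gamma"))
  qc <- run_qc(sim$forward, sim$reverse)
  expect_equal(nrow(qc$merged), 1000)
  expect_true(all(qc$merged$seq == tmpl))
})

test_that("simulated taxon counts follow the mixed profile", {
  tax <- tiny_taxonomy()
  panel <- tiny_panel(seed = 5)
  lin <- tiny_lineages()
  com <- data.frame(species = lin$species, genus = lin$genus,
                    family = lin$family, count = 10,
                    biomass_kg = c(100, 100, 100, 100, 100, 100),
                    amplifiable = TRUE)
  mk1 <- function(g) taxon_profile(stats::setNames(1, g))
  truth <- mesocosm_truth(
    com, source_profiles = list(intake = mk1("Delta"), gel = mk1("Epsilon"),
                                pellet = mk1("Epsilon")),
    mix_weights = mixing_params(c(0.5, 0.3, 0.1, 0.1),
                                c(Alpha = 0.5, Beta = 0.5)),
    read_depth = 1e5, error_rate = 0, seed = 21)
  sim <- simulate_reads(truth, panel)
  prof <- sim$profile
  tab <- table(sim$truth_table$taxon)

  # binomial 3-sigma bound on each taxon count
  n <- truth$read_depth
  for (taxon in names(prof)) {
    p <- as.numeric(prof[taxon])
    expect_lt(abs(tab[[taxon]] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }

  # chi-square goodness of fit across seeds
  pvals <- vapply(1:5, function(s) {
    t2 <- mesocosm_truth(com, truth$source_profiles, truth$mix_weights,
                         read_depth = 5e4, error_rate = 0, seed = s)
    cnt <- table(factor(simulate_reads(t2, panel)$truth_table$taxon,
                        levels = names(prof)))
    suppressWarnings(stats::chisq.test(as.numeric(cnt),
                                       p = as.numeric(prof))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("read simulation is byte-identical under a fixed seed", {
  scen <- default_scenario(seed = 17, read_depth = 300)
  s1 <- simulate_reads(scen$truth, scen$panel)
  s2 <- simulate_reads(scen$truth, scen$panel)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$forward, f1)
  write_fastq(s2$forward, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("fastq and panel fasta round-trip losslessly", {
  rs <- read_set(c("ACGTACGTNA", "TTGCATGCAT"),
                 c(qual_at(38, 10), paste0(qual_at(2, 5), qual_at(41, 5))),
                 c("a", "b"))
  p <- tempfile(fileext = ".fastq")
  write_fastq(rs, p)
  back <- read_fastq(p)
  expect_equal(back$seq, rs$seq)
  expect_equal(back$qual, rs$qual)
  expect_equal(back$id, rs$id)

  panel <- tiny_panel(seed = 3)
  fa <- tempfile(fileext = ".fasta")
  write_panel_fasta(panel, fa)
  back <- read_panel_fasta(fa)
  expect_equal(back$sequence, panel$sequence)
  expect_equal(back$species, panel$species)
})

test_that("scenario invariants are enforced", {
  scen <- default_scenario(seed = 1, read_depth = 100)
  com <- scen$truth$community
  expect_error(mesocosm_truth(transform(com, biomass_kg = -1),
                              scen$truth$source_profiles,
                              scen$truth$mix_weights), "biomass")
  expect_error(mesocosm_truth(com, scen$truth$source_profiles,
                              scen$truth$mix_weights, error_rate = 0.3),
               "error_rate")
  expect_error(mesocosm_truth(com, scen$truth$source_profiles,
                              scen$truth$mix_weights, read_depth = 0),
               "read_depth")
  expect_error(mixing_params(c(0.5, 0.5, 0.2, -0.2), c(A = 1)), "sum to 1|\\[0, 1\\]")
})
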