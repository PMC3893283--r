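# ednacensus

Environmental DNA (eDNA) metabarcoding promises whole-community surveys
from a liter of water — but its error rates can only be measured against a
community whose composition is already known. `ednacensus` implements a
complete, testable census pipeline around such a benchmark: a
4.5-million-liter public aquarium tank holding 12 marine vertebrate species
of known count and biomass, surveyed with vertebrate-universal primers
flanking a 106 bp fragment of the mitochondrial 12S rRNA gene.

The package is aimed at researchers developing or validating eDNA survey
methods. It provides:

* **A ground-truth scenario generator** — the tank census as a packaged
  fixture, biomass-driven DNA shedding (proportion of genus *g* ∝
  Σ biomass^γ over its amplifiable species), planted primer-dropout taxa,
  exogenous DNA sources, and a paired-end read simulator with
  quality-correlated errors.
* **Read QC** — primer removal (≤3 Hamming mismatches), sliding-window
  quality trimming (first 10 bp window with mean Q < 25), ambiguity and
  homopolymer filters, 55–106 bp length bounds, pair gating, and
  quality-aware overlap merging (≥15 bp, ≤10% mismatch density).
* **Reference database tools** — one randomly chosen species per genus,
  explicit supplements, and in silico PCR against genome sequences.
* **Taxonomic assignment** — best-hit identity thresholds: ≥97% reaches
  family, ≥99% reaches genus when the hit set is genus-unique, with a
  lowest-common-ancestor fallback; a strictly-greater 0.01% abundance
  filter.
* **Diversity** — Shannon index and hypergeometric rarefaction with a
  sliding-window percentile band.
* **The source-apportionment mixing model** — the observed tank
  composition T is modeled as

      T(t) = q·G(t) + x·In(t) + y·Gel(t) + z·Pellet(t)

  with (q, x, y, z) the tank-generated / intake / gel-feed / pellet-feed
  weights and G carrying in-tank generation weights (J, K, L, M) for the
  four detectable tank genera; both quadruples live on simplexes. The fit
  draws parameter sets from two independent flat Dirichlet distributions,
  minimizes the residual sum of squares, and reports the best set with
  percentile intervals over the retained best ensemble.
* **Detection accounting** — per-species lowest detected rank,
  family-level false-negative and false-positive rates against the known
  community, source attribution, and rank-abundance comparison.

## Worked example

```r
library(ednacensus)

cfg <- default_config(seed = 1)
cfg$scenario$read_depth <- 10000L
run <- run_pipeline(cfg, verbose = FALSE)
print(run)
#> <edna_census_run> seed=1
#>     stage pairs fraction
#> 1   input 10000   1.0000
#> 2  primer  9477   0.9477
#> 3 content  8952   0.8952
#> 4  length  7973   0.7973
#> 5  merged  7973   0.7973
#> Shannon H' (genus): 1.613  (family): 1.605
#> <mixing_fit> n_samples=100000, retained=1000
#>   best RSS=0.00682, R2=0.9647
#>   q            0.6194  (0.419-0.841)
#>   x            0.3428  (0.0184-0.461)
#>   y            0.01304  (0.00272-0.215)
#>   z            0.02476  (0.00366-0.261)
#>   Coryphaena   0.02662  (0.00319-0.244)
#>   Scomber      0.02802  (0.003-0.239)
#>   Sardinops    0.5121  (0.183-0.662)
#>   Thunnus      0.4333  (0.216-0.665)
#> <detection_report>
#>   families undetected: 5 / 9 (rate 0.556 )
#>   bony-fish families undetected: 1 / 5 (rate 0.2 )
#>   false-positive families: 1 / 12 (rate 0.0833 )
```

Reading the output: 79.7% of the 10,000 simulated read pairs survive QC
and merge (the scenario plants primer, quality, ambiguity and homopolymer
failures at realistic rates). The mixing fit estimates that ~62% of tank
DNA is generated in the tank (the scenario's planted truth is 69%) and
~34% enters with the intake (truth 30.9%), with sardine and tuna dominating
in-tank generation — at this read depth and 10⁵ Monte-Carlo draws the
estimates carry the uncertainty the intervals indicate. The detection
report recovers the planted truth exactly: the 5 undetected families are
precisely the primer-dropout taxa (3 cartilaginous fishes, the sea turtle,
the ocean sunfish), 1 of 5 bony-fish families is missed, and of the 12
families detected in the tank exactly one (Salmonidae, the planted
contaminant) can be attributed to no source — a false-positive rate of
1/12 = 8.3%.

Individual stages are ordinary functions (`simulate_reads()`, `run_qc()`,
`assign_reads()`, `profile_from_assignments()`, `rarefy()`,
`fit_mixing()`, `detection_report()`, …) and can be driven separately; see
the methods vignette (`vignettes/edna-mesocosm-census.Rmd`) for the models,
parameter meanings and design choices.

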