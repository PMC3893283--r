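primers <- vert12s_primers()

test_that("primer stripping tolerates up to three mismatches", {
  tmpl <- random_dna(80)
  clean <- one_read(paste0(primers$fwd, tmpl))
  out <- strip_primers(clean, primers$fwd)
  expect_equal(out$seq, tmpl)

  for (nmm in 0:4) {
    seq <- paste0(mutate_seq(primers$fwd, seq_len(nmm) * 4), tmpl)
    out <- strip_primers(one_read(seq), primers$fwd)
    if (nmm <= 3) {
      expect_equal(out$seq, tmpl)
    } else {
      expect_equal(nrow(out), 0)
    }
  }

  # primer longer than the read
  expect_equal(nrow(strip_primers(one_read("ACGT"), primers$fwd)), 0)
})

test_that("quality trimming cuts at the first poor 10 bp window", {
  r <- one_read(random_dna(30), qual_at(40, 30))
  expect_equal(quality_trim(r)$seq, r$seq)

  # Q40 x 20 then Q10 x 10: scanning windows at step 1, the first window
  # with mean < 25 starts at base 17 (4 x 40 + 6 x 10 = 22), so 16 bases
  # remain; located here by exhaustive scan
  qual <- paste0(qual_at(40, 20), qual_at(10, 10))
  q <- utf8ToInt(qual) - 33L
  first_bad <- NA
  for (i in 1:21) if (mean(q[i:(i + 9)]) < 25) { first_bad <- i; break }
  expect_equal(first_bad, 17)
  out <- quality_trim(one_read(random_dna(30), qual))
  expect_equal(nchar(out$seq), first_bad - 1L)
  expect_equal(nchar(out$qual), first_bad - 1L)

  # uniformly poor read: the window at position 1 fails, read emptied
  out <- quality_trim(one_read(random_dna(30), qual_at(24, 30)))
  expect_equal(nchar(out$seq), 0)

  # shorter than one window: unchanged
  out <- quality_trim(one_read(random_dna(5), qual_at(24, 5)))
  expect_equal(nchar(out$seq), 5)
})

test_that("content filter applies the ambiguity and homopolymer rules", {
  five_n <- paste(rep("ACGTN", 5), collapse = "")
  expect_equal(nrow(content_filter(one_read(five_n))), 1)
  six_n <- paste0(five_n, "NAC")
  expect_equal(nrow(content_filter(one_read(six_n))), 0)
  embedded <- paste0("ACGT", "AAAAAA", "CGTA")
  expect_equal(nrow(content_filter(one_read(embedded))), 0)
  five_run <- paste0("ACGT", "AAAAA", "CGTA")
  expect_equal(nrow(content_filter(one_read(five_run))), 1)
})

test_that("length filter bounds are inclusive", {
  for (len in c(54, 55, 80, 106, 107)) {
    out <- length_filter(one_read(random_dna(len)))
    expect_equal(nrow(out), as.integer(len >= 55 && len <= 106), info = len)
  }
})

test_that("pair gate requires both mates to survive", {
  f <- read_set(c(random_dna(60), random_dna(60)), id = c("a", "b"))
  r <- read_set(random_dna(60), id = "a")
  g <- pair_gate(f, r)
  expect_equal(g$forward$id, "a")
  expect_equal(g$reverse$id, "a")
  g0 <- pair_gate(f[0, ], r)
  expect_equal(nrow(g0$forward), 0)
})

test_that("pair merging follows the mismatch-density rule", {
  # full overlap of identical 50-mers
  tmpl <- random_dna(50)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tmpl)))
  m <- merge_pairs(one_read(tmpl), one_read(rc))
  expect_equal(m$seq, tmpl)
  expect_equal(attr(m, "overlap")$overlap, 50)

  # a 15 bp overlap with one mismatch: density 1/15 = 0.067 <= 0.10, accept
  set.seed(31)
  left <- random_dna(25)
  right <- random_dna(25)
  ov <- random_dna(15)
  fwd <- paste0(left, ov)
  rc_rev <- paste0(mutate_seq(ov, 8), right) # 1 mismatch in the overlap
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc_rev)))
  m <- merge_pairs(one_read(fwd), one_read(rev))
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "overlap")$overlap, 15)
  expect_equal(attr(m, "overlap")$mismatches, 1)
  expect_equal(nchar(m$seq), 25 + 15 + 25)

  # two mismatches in 15 bp: density 0.133 > 0.10, reject
  rc_rev2 <- paste0(mutate_seq(ov, c(5, 8)), right)
  rev2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc_rev2)))
  m2 <- merge_pairs(one_read(fwd), one_read(rev2))
  expect_equal(nrow(m2), 0)

  # no qualifying overlap at all
  m3 <- merge_pairs(one_read(random_dna(20)), one_read(random_dna(20)))
  expect_equal(nrow(m3), 0)
})

test_that("merge conflicts take the higher-quality base", {
  tmpl <- "ACGTACGTACGTACGTACGT" # 20 bp, full overlap
  alt <- mutate_seq(tmpl, 10)
  rc_alt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  # reverse mate disagrees at base 10 but carries higher quality there
  f <- one_read(tmpl, qual_at(20, 20))
  r <- one_read(rc_alt, qual_at(30, 20))
  m <- merge_pairs(f, r, min_overlap = 15, max_mismatch_density = 0.10)
  expect_equal(substr(m$seq, 10, 10), substr(alt, 10, 10))
  # equal quality: forward base wins
  m2 <- merge_pairs(one_read(tmpl, qual_at(30, 20)),
                    one_read(rc_alt, qual_at(30, 20)))
  expect_equal(m2$seq, tmpl)
})

test_that("full QC is idempotent and transparent to clean reads", {
  scen <- default_scenario(seed = 8, read_depth = 400, error_rate = 0,
                           qc_fail = list())
  sim <- simulate_reads(scen$truth, scen$panel)
  qc <- run_qc(sim$forward, sim$reverse)
  # clean error-free pairs all pass and merge to their exact templates
  expect_equal(nrow(qc$merged), 400)
  tmpl <- stats::setNames(scen$panel$sequence, scen$panel$genus)
  truth_taxon <- sim$truth_table$taxon[match(qc$merged$id, sim$truth_table$read_id)]
  expect_true(all(qc$merged$seq == tmpl[truth_taxon]))

  # re-running the per-mate filters on already-passed reads changes nothing
  passed <- qc$merged
  again <- length_filter(content_filter(quality_trim(passed)))
  expect_equal(again$seq, passed$seq)

  # stage counts never increase downstream
  expect_true(all(diff(qc$report$pairs) <= 0))
})

test_that("planted QC failures are caught by the intended stages", {
  scen <- default_scenario(seed = 12, read_depth = 2000, error_rate = 0,
                           qc_fail = list(primer = 0.1, quality = 0.1,
                                          ambiguous = 0.1, homopolymer = 0.1))
  sim <- simulate_reads(scen$truth, scen$panel)
  qc <- run_qc(sim$forward, sim$reverse)
  frac <- qc$report$fraction[qc$report$stage == "merged"]
  expect_lt(frac, 0.70)
  expect_gt(frac, 0.50)
  # surviving reads are still exact templates (error_rate 0)
  tmpl <- stats::setNames(scen$panel$sequence, scen$panel$genus)
  truth_taxon <- sim$truth_table$taxon[match(qc$merged$id, sim$truth_table$read_id)]
  expect_true(all(qc$merged$seq == tmpl[truth_taxon]))
})
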