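# Shared fixtures: a small four-family taxonomy, read construction helpers,
# and an independent Hamming-identity oracle used to cross-check alignment
# based identities on substitution-only sequences.

tiny_lineages <- function() {
  data.frame(
    species = c("Alpha one", "Alpha two", "Beta one", "Gamma one",
                "Delta one", "Epsilon one"),
    genus = c("Alpha", "Alpha", "Beta", "Gamma", "Delta", "Epsilon"),
    family = c("Fam1", "Fam1", "Fam1", "Fam2", "Fam3", "Fam4"),
    class = c("Cls1", "Cls1", "Cls1", "Cls1", "Cls2", "Cls2")
  )
}

tiny_taxonomy <- function() taxonomy_from_lineages(tiny_lineages())

tiny_panel <- function(seed = 42, ...) {
  make_reference_panel(tiny_taxonomy(), amplicon_length = 106, seed = seed, ...)
}

# Hamming distance between equal-length strings (independent of Biostrings)
hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# substitute `n` positions of a sequence with different bases
mutate_seq <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# quality string at a constant phred score
qual_at <- function(q, len) strrep(intToUtf8(q + 33L), len)

# a read_set holding one read
one_read <- function(seq, qual = NULL, id = "r1") read_set(seq, qual, id)

# paired reads covering `template` exactly, primers attached
template_pair <- function(template, primers = vert12s_primers(), q = 40,
                          id = "p1") {
  fwd <- paste0(primers$fwd, template)
  rev <- paste0(primers$rev, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(template))))
  list(forward = read_set(fwd, qual_at(q, nchar(fwd)), id),
       reverse = read_set(rev, qual_at(q, nchar(rev)), id))
}

random_dna <- function(n, avoid_runs = TRUE) {
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (avoid_runs) {
    for (i in seq_len(n)) {
      if (i > 3 && v[i] == v[i - 1] && v[i] == v[i - 2] && v[i] == v[i - 3])
        v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    }
  }
  paste(v, collapse = "")
}

# uniform random point on the k-simplex (independent of the package's
# Dirichlet sampler)
simplex_point <- function(k) {
  e <- -log(runif(k))
  e / sum(e)
}
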