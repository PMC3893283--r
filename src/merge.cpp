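#include <Rcpp.h>
using namespace Rcpp;

// Paired-end overlap merge. Inputs: forward sequence/quality and the
// reverse mate already reverse-complemented (quality reversed in register).
// For every candidate overlap length l >= min_overlap the mismatch fraction
// between the forward suffix and reverse prefix is computed; the l with the
// smallest fraction wins, ties going to the longest l. A pair merges only
// if the winning fraction is <= max_mismatch_density. Overlap conflicts are
// resolved by the higher-quality base, ties to the forward base.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fseq, CharacterVector fqual,
                     CharacterVector rseq, CharacterVector rqual,
                     int min_overlap, double max_mismatch_density) {
  const int n = fseq.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  IntegerVector olen(n), omism(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fseq[i]);
    std::string fq = as<std::string>(fqual[i]);
    std::string r = as<std::string>(rseq[i]);
    std::string rq = as<std::string>(rqual[i]);
    const int lf = f.size(), lr = r.size();
    const int maxl = std::min(lf, lr);
    int bestl = -1, bestm = 0;
    double bestfrac = 2.0;
    for (int l = min_overlap; l <= maxl; ++l) {
      int m = 0;
      for (int k = 0; k < l; ++k)
        if (f[lf - l + k] != r[k]) ++m;
      const double frac = (double)m / l;
      if (frac < bestfrac - 1e-12 ||
          (std::abs(frac - bestfrac) <= 1e-12 && l > bestl)) {
        bestfrac = frac; bestl = l; bestm = m;
      }
    }
    if (bestl < 0 || bestfrac > max_mismatch_density + 1e-12) {
      ok[i] = false;
      continue;
    }
    std::string seq = f.substr(0, lf - bestl);
    std::string qual = fq.substr(0, lf - bestl);
    for (int k = 0; k < bestl; ++k) {
      const char fb = f[lf - bestl + k], rb = r[k];
      const char fqc = fq[lf - bestl + k], rqc = rq[k];
      if (fb == rb) {
        seq += fb;
        qual += std::max(fqc, rqc);
      } else if (rqc > fqc) {
        seq += rb;
        qual += rqc;
      } else {
        seq += fb;
        qual += fqc;
      }
    }
    seq += r.substr(bestl);
    qual += rq.substr(bestl);
    ok[i] = true;
    mseq[i] = seq;
    mqual[i] = qual;
    olen[i] = bestl;
    omism[i] = bestm;
  }
  return List::create(_["ok"] = ok, _["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = olen, _["mismatches"] = omism);
}
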