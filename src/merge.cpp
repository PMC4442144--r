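#include <Rcpp.h>
using namespace Rcpp;

// Overlap-maximizing merge of a mate pair. r2rc is read 2 already
// reverse-complemented into read-1 orientation. For each candidate overlap
// length L (suffix of r1 vs prefix of r2rc), the number of matching bases
// is counted; the eligible overlap (L >= min_overlap, mismatch fraction <=
// max_mismatch_frac) with the most matches wins, ties going to the longer
// overlap. Scanning descends from the largest L and stops once no shorter
// overlap can beat the current best match count.
// [[Rcpp::export]]
List merge_overlap_cpp(CharacterVector r1, CharacterVector r2rc,
                       int min_overlap, double max_mismatch_frac) {
  int n = r1.size();
  IntegerVector overlap(n), mism(n);
  LogicalVector ok(n);
  CharacterVector merged(n);
  List mm_pos(n), mm_alt(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string b = as<std::string>(r2rc[i]);
    int la = a.size(), lb = b.size();
    int best_L = -1, best_matches = -1, best_mm = 0;
    int Lmax = std::min(la, lb);
    for (int L = Lmax; L >= min_overlap; --L) {
      if (best_matches >= L) break; // no shorter overlap can win
      int mm = 0;
      const char *pa = a.data() + (la - L);
      const char *pb = b.data();
      for (int k = 0; k < L; ++k) if (pa[k] != pb[k]) ++mm;
      if ((double)mm / L > max_mismatch_frac) continue;
      int matches = L - mm;
      if (matches > best_matches) {
        best_matches = matches; best_L = L; best_mm = mm;
      }
    }
    if (best_L < 0) {
      ok[i] = false; overlap[i] = NA_INTEGER; mism[i] = NA_INTEGER;
      merged[i] = NA_STRING;
      mm_pos[i] = IntegerVector(0); mm_alt[i] = CharacterVector(0);
    } else {
      ok[i] = true; overlap[i] = best_L; mism[i] = best_mm;
      // overlap bases resolved in favor of read 1; positions where the
      // mates disagree are recorded (1-based, merged coordinates) with
      // read 2's base, so downstream verification can use both
      // observations of the overlap
      IntegerVector pos(best_mm); CharacterVector alt(best_mm);
      int j = 0;
      const char *pa = a.data() + (la - best_L);
      const char *pb = b.data();
      for (int k = 0; k < best_L; ++k) {
        if (pa[k] != pb[k]) {
          pos[j] = la - best_L + k + 1;
          alt[j] = std::string(1, pb[k]);
          ++j;
        }
      }
      merged[i] = a + b.substr(best_L);
      mm_pos[i] = pos; mm_alt[i] = alt;
    }
  }
  return List::create(_["merged"] = merged, _["overlap_len"] = overlap,
                      _["n_overlap_mismatches"] = mism, _["ok"] = ok,
                      _["mm_pos"] = mm_pos, _["mm_alt"] = mm_alt);
}

// Mismatch count between equal-length strings, NA on length mismatch.
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector x, CharacterVector y) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(x[i]);
    std::string b = as<std::string>(y[i % y.size()]);
    if (a.size() != b.size()) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++mm;
    out[i] = mm;
  }
  return out;
}
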