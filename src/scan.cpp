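#include <Rcpp.h>
using namespace Rcpp;

// Window scan kernel for miRNA target prediction. Enumerates, for every
// window of length |m|-1, |m|, |m|+1 on the transcript, the admissible
// alignments (gapless; one single-nt target bulge when longer; one
// single-nt miRNA gap when shorter), scores them with the position-
// dependent penalty system (WC 0, G:U 0.5, mismatch/bulge/gap 1, doubled
// at miRNA positions 2-13) and reports windows whose minimum score is at
// or below max_score. Semantics mirror align_site() in R; the two are
// cross-checked in the test suite.

static inline double pair_pen(char m, char s) {
  // WC
  if ((m == 'A' && s == 'U') || (m == 'U' && s == 'A') ||
      (m == 'G' && s == 'C') || (m == 'C' && s == 'G')) return 0.0;
  // G:U wobble
  if ((m == 'G' && s == 'U') || (m == 'U' && s == 'G')) return 0.5;
  return 1.0;
}

static inline double wt(int p) { return (p >= 2 && p <= 13) ? 2.0 : 1.0; }

// [[Rcpp::export(name = ".scan_windows")]]
DataFrame scan_windows(std::string mirna, std::string transcript,
                       double max_score) {
  int n = mirna.size();
  int T = transcript.size();
  std::vector<int> out_start, out_w, out_lesion;
  std::vector<double> out_score;

  for (int w = n - 1; w <= n + 1; ++w) {
    if (w > T || w < 1) continue;
    for (int s0 = 0; s0 + w <= T; ++s0) {
      const char *s = transcript.c_str() + s0;
      double best = R_PosInf;
      int best_lesion = NA_INTEGER;
      if (w == n) {
        double sc = 0.0;
        for (int p = 1; p <= n && sc <= max_score; ++p) {
          sc += wt(p) * pair_pen(mirna[p - 1], s[n - p]);
        }
        if (sc < best) { best = sc; best_lesion = NA_INTEGER; }
      } else if (w == n + 1) {
        for (int b = 1; b <= n; ++b) {
          double sc = wt(b) * 1.0;
          for (int p = 1; p <= n && sc <= max_score; ++p) {
            if (p == b) continue;
            int j = (p < b) ? (w - p + 1) : (w - p);
            sc += wt(p) * pair_pen(mirna[p - 1], s[j - 1]);
          }
          if (sc < best) { best = sc; best_lesion = b; }
        }
      } else { // w == n - 1, one miRNA gap
        for (int b = 1; b <= n; ++b) {
          double sc = wt(b) * 1.0;
          for (int p = 1; p <= n && sc <= max_score; ++p) {
            if (p == b) continue;
            int j = (p < b) ? (w - p + 1) : (w - p + 2);
            sc += wt(p) * pair_pen(mirna[p - 1], s[j - 1]);
          }
          if (sc < best) { best = sc; best_lesion = b; }
        }
      }
      if (best <= max_score) {
        out_start.push_back(s0);
        out_w.push_back(w);
        out_score.push_back(best);
        out_lesion.push_back(best_lesion);
      }
    }
  }
  return DataFrame::create(_["start"] = out_start, _["width"] = out_w,
                           _["score"] = out_score,
                           _["lesion_pos"] = out_lesion);
}
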