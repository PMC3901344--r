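#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Exact longest common substring between two strings by dynamic programming
// over suffix-match lengths (O(n*m) time, O(m) memory). Ties are broken by
// the lexicographically smallest (startA, startB) position pair.
// [[Rcpp::export]]
List lcs_pair(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, bestA = 0, bestB = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) {
          best = cur[j];
          bestA = i - cur[j];
          bestB = j - cur[j];
        } else if (cur[j] == best && best > 0) {
          int sa = i - cur[j], sb = j - cur[j];
          if (sa < bestA || (sa == bestA && sb < bestB)) {
            bestA = sa; bestB = sb;
          }
        }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return List::create(_["length"] = best,
                      _["start_a"] = bestA,
                      _["start_b"] = bestB);
}

static int lcs_len_only(const std::string &a, const std::string &b,
                        std::vector<int> &prev, std::vector<int> &cur) {
  const int n = a.size(), m = b.size();
  std::fill(prev.begin(), prev.begin() + m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}

// Monte-Carlo null distribution of the longest common substring between two
// independent random sequences of given lengths and base composition.
// Uses a self-contained mt19937 stream so results are identical across
// platforms for a given seed.
// [[Rcpp::export]]
IntegerVector lcs_null_distribution(int len_a, int len_b,
                                    NumericVector probs, int reps,
                                    int seed) {
  if (probs.size() != 4) stop("probs must have length 4 (A,C,G,T)");
  double tot = probs[0] + probs[1] + probs[2] + probs[3];
  double cum[4];
  double acc = 0.0;
  for (int k = 0; k < 4; ++k) { acc += probs[k] / tot; cum[k] = acc; }
  cum[3] = 1.0;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw_seq = [&](int len) {
    std::string s(len, 'A');
    for (int i = 0; i < len; ++i) {
      double u = unif(rng);
      int k = 0;
      while (k < 3 && u > cum[k]) ++k;
      s[i] = bases[k];
    }
    return s;
  };
  IntegerVector out(reps);
  int m = std::max(len_a, len_b);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int r = 0; r < reps; ++r) {
    std::string a = draw_seq(len_a), b = draw_seq(len_b);
    out[r] = lcs_len_only(a, b, prev, cur);
  }
  return out;
}
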