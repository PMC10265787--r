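#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

// Extended Smith-Waterman for read-vs-read overlap detection.
//
// Enumerates distinct significant local alignments between two short reads by
// Waterman-Eggert-style suboptimal alignment: the best local alignment
// (affine gaps) is reported, its aligned base pairs are masked, and the DP is
// rerun until the best score falls below min_score or max_patterns have been
// produced. Masking forbids re-using an aligned pair as an aligned column, so
// each reported pattern is a genuinely distinct overlap configuration -- on a
// tandem repeat this yields one pattern per unit shift instead of a cloud of
// single-gap perturbations of the strongest alignment.
//
// Each pattern's implied ending-base offset is read off its end cell (i2, j2)
// (alignments end on a matching pair, so the end cell fixes the registration):
//
//     offset = (len_b - j2) - (len_a - i2)
//
// Patterns are filtered (not masked) by min_overlap on both spans and by the
// overlap/dovetail/containment condition: unaligned overhang on the inner
// side of each end <= max_hang. A gap of length L costs
// gap_open + (L-1) * gap_extend (penalties passed as positive numbers).

struct Pat { int offset, score, i1, j1, i2, j2; };

// [[Rcpp::export]]
DataFrame sw_overlap_patterns(std::string a, std::string b,
                              int match, int mismatch,
                              int gap_open, int gap_extend,
                              int min_score, int min_overlap,
                              int max_hang, int max_patterns = 8) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<Pat> out;
  if (n > 0 && m > 0) {
    const int W = m + 1;
    const int NEG = -1000000000;
    std::vector<int> H((size_t)(n + 1) * W, 0), E(H), F(H);
    std::vector<unsigned char> dH(H.size(), 0), dE(H.size(), 0), dF(H.size(), 0);
    std::vector<bool> mask((size_t)n * m, false);

    for (int round = 0; round < max_patterns; ++round) {
      for (int j = 0; j <= m; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
      int best = 0, bi = 0, bj = 0;
      for (int i = 1; i <= n; ++i) {
        size_t r = (size_t)i * W, rp = (size_t)(i - 1) * W;
        H[r] = 0; E[r] = NEG; F[r] = NEG;
        for (int j = 1; j <= m; ++j) {
          int e_open = H[r + j - 1] - gap_open;
          int e_ext  = E[r + j - 1] - gap_extend;
          if (e_open >= e_ext) { E[r + j] = e_open; dE[r + j] = 1; }
          else                 { E[r + j] = e_ext;  dE[r + j] = 2; }
          int f_open = H[rp + j] - gap_open;
          int f_ext  = F[rp + j] - gap_extend;
          if (f_open >= f_ext) { F[r + j] = f_open; dF[r + j] = 1; }
          else                 { F[r + j] = f_ext;  dF[r + j] = 2; }
          int s = mask[(size_t)(i - 1) * m + (j - 1)] ? NEG
                  : ((a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : -mismatch);
          int diag = (s == NEG) ? NEG : H[rp + j - 1] + s;
          int hv = diag; unsigned char hd = 1;
          if (E[r + j] > hv) { hv = E[r + j]; hd = 2; }
          if (F[r + j] > hv) { hv = F[r + j]; hd = 3; }
          if (hv <= 0) { hv = 0; hd = 0; }
          H[r + j] = hv; dH[r + j] = hd;
          if (hv > best) { best = hv; bi = i; bj = j; }
        }
      }
      if (best < min_score) break;

      // traceback from (bi, bj); mask aligned pairs; record span
      int i = bi, j = bj, i1 = bi, j1 = bj;
      int state = 0; // 0 = H, 1 = E, 2 = F
      while (i > 0 && j > 0) {
        size_t r = (size_t)i * W;
        if (state == 0) {
          unsigned char d = dH[r + j];
          if (d == 0) break;
          if (d == 1) {
            mask[(size_t)(i - 1) * m + (j - 1)] = true;
            i1 = i; j1 = j;
            --i; --j;
            if (H[(size_t)i * W + j] == 0 && dH[(size_t)i * W + j] == 0) break;
          } else if (d == 2) state = 1;
          else state = 2;
        } else if (state == 1) {
          if (dE[r + j] == 1) state = 0;
          --j;
        } else {
          if (dF[r + j] == 1) state = 0;
          --i;
        }
      }
      Pat p;
      p.score = best; p.i1 = i1; p.j1 = j1; p.i2 = bi; p.j2 = bj;
      p.offset = (m - bj) - (n - bi);
      int spanA = p.i2 - p.i1 + 1, spanB = p.j2 - p.j1 + 1;
      int left_hang  = std::min(p.i1 - 1, p.j1 - 1);
      int right_hang = std::min(n - p.i2, m - p.j2);
      if (spanA >= min_overlap && spanB >= min_overlap &&
          left_hang <= max_hang && right_hang <= max_hang)
        out.push_back(p);
    }
  }
  const int k = (int)out.size();
  IntegerVector off(k), sc(k), i1(k), i2(k), j1(k), j2(k);
  for (int t = 0; t < k; ++t) {
    off[t] = out[t].offset; sc[t] = out[t].score;
    i1[t] = out[t].i1; i2[t] = out[t].i2; j1[t] = out[t].j1; j2[t] = out[t].j2;
  }
  return DataFrame::create(Named("offset") = off, Named("score") = sc,
                           Named("i1") = i1, Named("i2") = i2,
                           Named("j1") = j1, Named("j2") = j2);
}
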