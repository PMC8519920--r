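#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T=3, anything else = -1 (never produced after
// validation on the R side).
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const double NEG_INF = -1e18;

// Semi-global (overlap) affine-gap alignment, Gotoh recurrences.
// Both leading and trailing end gaps are free on both sequences; internal
// gaps of length L cost gap_open + (L-1) * gap_ext.
// Returns the optimal score; if tb != nullptr, fills the aligned column
// list as pairs of 0-based indices (-1 = gap) restricted to the aligned core
// (leading/trailing free gaps are reattached by the caller when printing).
struct AlignResult {
  double score;
  std::vector<int> ai, bj; // aligned columns, -1 for gap
};

static AlignResult sg_align(const std::string& a, const std::string& b,
                            double match, double mismatch,
                            double gap_open, double gap_ext,
                            bool traceback) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG_INF); // gap in b (consumes a)
  std::vector<double> F((m + 1) * (n + 1), NEG_INF); // gap in a (consumes b)
  // trace codes: H: 0=diag,1=E,2=F ; E: 0=open(H),1=ext ; F likewise
  std::vector<unsigned char> tH, tE, tF;
  if (traceback) {
    tH.assign((m + 1) * (n + 1), 0);
    tE.assign((m + 1) * (n + 1), 0);
    tF.assign((m + 1) * (n + 1), 0);
  }
#define IX(i, j) ((i) * (n + 1) + (j))
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e_open = H[IX(i - 1, j)] - gap_open;
      double e_ext  = E[IX(i - 1, j)] - gap_ext;
      E[IX(i, j)] = std::max(e_open, e_ext);
      double f_open = H[IX(i, j - 1)] - gap_open;
      double f_ext  = F[IX(i, j - 1)] - gap_ext;
      F[IX(i, j)] = std::max(f_open, f_ext);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H[IX(i - 1, j - 1)] + s;
      double best = diag;
      unsigned char code = 0;
      if (E[IX(i, j)] > best) { best = E[IX(i, j)]; code = 1; }
      if (F[IX(i, j)] > best) { best = F[IX(i, j)]; code = 2; }
      H[IX(i, j)] = best;
      if (traceback) {
        tH[IX(i, j)] = code;
        tE[IX(i, j)] = (e_ext > e_open) ? 1 : 0;
        tF[IX(i, j)] = (f_ext > f_open) ? 1 : 0;
      }
    }
  }
  // free trailing gaps: best over last row and last column
  double best = NEG_INF;
  int bi = m, bj = n;
  for (int j = 0; j <= n; ++j)
    if (H[IX(m, j)] > best) { best = H[IX(m, j)]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (H[IX(i, n)] > best) { best = H[IX(i, n)]; bi = i; bj = n; }
  AlignResult res;
  res.score = best;
  if (!traceback) return res;

  // walk back from (bi, bj) through the H/E/F automaton to a border cell
  std::vector<int> rai, rbj;
  // trailing free gaps
  for (int i = m; i > bi; --i) { rai.push_back(i - 1); rbj.push_back(-1); }
  for (int j = n; j > bj; --j) { rai.push_back(-1); rbj.push_back(j - 1); }
  int i = bi, j = bj;
  int state = 0; // 0=H,1=E,2=F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char c = tH[IX(i, j)];
      if (c == 0) {
        rai.push_back(i - 1); rbj.push_back(j - 1);
        --i; --j;
      } else {
        state = c;
      }
    } else if (state == 1) {
      rai.push_back(i - 1); rbj.push_back(-1);
      unsigned char c = tE[IX(i, j)];
      --i;
      state = (c == 1) ? 1 : 0;
    } else {
      rai.push_back(-1); rbj.push_back(j - 1);
      unsigned char c = tF[IX(i, j)];
      --j;
      state = (c == 1) ? 2 : 0;
    }
  }
  // leading free gaps
  while (i > 0) { rai.push_back(i - 1); rbj.push_back(-1); --i; }
  while (j > 0) { rai.push_back(-1); rbj.push_back(j - 1); --j; }
  std::reverse(rai.begin(), rai.end());
  std::reverse(rbj.begin(), rbj.end());
  res.ai = std::move(rai);
  res.bj = std::move(rbj);
  return res;
#undef IX
}

// [[Rcpp::export]]
NumericVector cpp_sg_align_scores(CharacterVector a, CharacterVector b,
                                  double match, double mismatch,
                                  double gap_open, double gap_ext) {
  const int np = a.size();
  if (b.size() != np) stop("sequence vectors must have equal length");
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]);
    std::string sb = as<std::string>(b[p]);
    out[p] = sg_align(sa, sb, match, mismatch, gap_open, gap_ext, false).score;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sg_align_one(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  AlignResult r = sg_align(a, b, match, mismatch, gap_open, gap_ext, true);
  const int L = (int)r.ai.size();
  std::string sa(L, '-'), sb(L, '-');
  for (int k = 0; k < L; ++k) {
    if (r.ai[k] >= 0) sa[k] = a[r.ai[k]];
    if (r.bj[k] >= 0) sb[k] = b[r.bj[k]];
  }
  return List::create(_["score"] = r.score,
                      _["aligned_a"] = sa,
                      _["aligned_b"] = sb);
}

// Nearest-neighbour enthalpy/entropy of the duplex implied by the semi-global
// alignment of strand a against the reverse complement of strand b (rcb is
// passed already reverse-complemented). Matched alignment columns are
// Watson-Crick pairs; maximal runs of consecutive matched columns are helices
// scored by stacked dinucleotides; each helix interruption beyond the first
// helix adds break_dh (kcal/mol, temperature-independent destabilisation).
// dh16/ds16 are indexed by 4*first_base + second_base of the top-strand
// dinucleotide. init terms apply to the two outermost pairs of the duplex.
// [[Rcpp::export]]
List cpp_duplex_hs_batch(CharacterVector a, CharacterVector rcb,
                         NumericVector dh16, NumericVector ds16,
                         double init_at_dh, double init_at_ds,
                         double init_gc_dh, double init_gc_ds,
                         double break_dh,
                         double match, double mismatch,
                         double gap_open, double gap_ext) {
  const int np = a.size();
  if (rcb.size() != np) stop("sequence vectors must have equal length");
  NumericVector DH(np), DS(np), SCORE(np);
  IntegerVector NPAIR(np), NHELIX(np), MAXHELIX(np);
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]);
    std::string sb = as<std::string>(rcb[p]);
    AlignResult r = sg_align(sa, sb, match, mismatch, gap_open, gap_ext, true);
    SCORE[p] = r.score;
    const int L = (int)r.ai.size();
    double dh = 0.0, ds = 0.0;
    int npair = 0, nhelix = 0, run = 0, maxrun = 0;
    int first_pair = -1, last_pair = -1;
    for (int k = 0; k < L; ++k) {
      bool paired = r.ai[k] >= 0 && r.bj[k] >= 0 &&
        sa[r.ai[k]] == sb[r.bj[k]];
      if (paired) {
        ++npair;
        if (first_pair < 0) first_pair = k;
        last_pair = k;
        if (run == 0) ++nhelix;
        ++run;
        if (run > maxrun) maxrun = run;
        // stack with previous column if it was paired and adjacent in both
        if (k > 0 && run > 1) {
          int i0 = r.ai[k - 1], i1 = r.ai[k];
          int c0 = base_code(sa[i0]), c1 = base_code(sa[i1]);
          dh += dh16[4 * c0 + c1];
          ds += ds16[4 * c0 + c1];
        }
      } else {
        run = 0;
      }
    }
    if (npair > 0) {
      // duplex initiation at the two terminal pairs
      int ends[2] = { first_pair, last_pair };
      int nterm = (first_pair == last_pair) ? 1 : 2;
      for (int t = 0; t < nterm; ++t) {
        char cb = sa[r.ai[ends[t]]];
        if (cb == 'A' || cb == 'T') { dh += init_at_dh; ds += init_at_ds; }
        else                        { dh += init_gc_dh; ds += init_gc_ds; }
      }
      if (nhelix > 1) dh += break_dh * (nhelix - 1);
    }
    DH[p] = dh; DS[p] = ds;
    NPAIR[p] = npair; NHELIX[p] = nhelix; MAXHELIX[p] = maxrun;
  }
  return List::create(_["delta_H"] = DH, _["delta_S"] = DS,
                      _["n_pairs"] = NPAIR, _["n_helices"] = NHELIX,
                      _["max_helix"] = MAXHELIX,
                      _["alignment_score"] = SCORE);
}

// Longest common substring length (contiguous), classic O(nm) DP.
// [[Rcpp::export]]
IntegerVector cpp_lcs_batch(CharacterVector a, CharacterVector b) {
  const int np = a.size();
  if (b.size() != np) stop("string vectors must have equal length");
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]);
    std::string sb = as<std::string>(b[p]);
    const int m = (int)sa.size(), n = (int)sb.size();
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        cur[j] = (sa[i - 1] == sb[j - 1]) ? prev[j - 1] + 1 : 0;
        if (cur[j] > best) best = cur[j];
      }
      std::swap(prev, cur);
    }
    out[p] = best;
  }
  return out;
}

// Minimum free energy of single-strand hairpin folding: Zuker-style DP with
// stacks, hairpin loops (min size 3), bulges and internal loops; external
// bases are free and any set of disjoint closed structures may sit at the
// external level. All energies are free energies at the target temperature,
// precomputed on the R side:
//   stack_dg: 16-vector indexed by 4*b(i) + b(i+1) for pair (i,j) stacked on
//             (i+1, j-1);
//   hairpin_dg / bulge_dg / iloop_dg: penalty by loop size (1-based index).
// [[Rcpp::export]]
double cpp_hairpin_mfe(std::string seq, NumericVector stack_dg,
                       NumericVector hairpin_dg, NumericVector bulge_dg,
                       NumericVector iloop_dg) {
  const int n = (int)seq.size();
  if (n < 5) return 0.0;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  auto pairs = [&](int i, int j) { return code[i] + code[j] == 3; }; // WC only
  auto loopv = [](NumericVector& v, int size) {
    if (size <= 0) return 1e9;
    int k = std::min(size, (int)v.size());
    return v[k - 1];
  };
  const double INF = 1e9;
  std::vector<double> V(n * n, INF);
  // j - i from small to large
  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (!pairs(i, j)) continue;
      double best = loopv(hairpin_dg, j - i - 1); // hairpin closure
      // stack
      if (j - i - 2 >= 4 && pairs(i + 1, j - 1)) {
        double e = stack_dg[4 * code[i] + code[i + 1]] + V[(i + 1) * n + (j - 1)];
        if (e < best) best = e;
      }
      // bulge / internal loops (at least one unpaired base between pairs)
      for (int k = i + 1; k < j - 4; ++k) {
        for (int l = j - 1; l > k + 3; --l) {
          int left = k - i - 1, right = j - l - 1;
          if (left + right == 0) continue; // stack handled above
          if (left + right > 30) continue;
          if (!pairs(k, l) || V[k * n + l] >= INF) continue;
          double pen = (left == 0 || right == 0)
            ? loopv(bulge_dg, left + right)
            : loopv(iloop_dg, left + right);
          double e = pen + V[k * n + l];
          if (e < best) best = e;
        }
      }
      V[i * n + j] = best;
    }
  }
  // external level
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    for (int i = 1; i <= j - 4; ++i) {
      double v = V[(i - 1) * n + (j - 1)];
      if (v < INF) W[j] = std::min(W[j], W[i - 1] + v);
    }
  }
  return std::min(0.0, W[n]);
}
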