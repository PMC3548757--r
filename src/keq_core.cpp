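// Exhaustive nearest-neighbor K_eq enumeration for one probe variant
// against a set of target segments.
//
// Conventions (shared with the R level):
//   bases coded A=0, C=1, G=2, T=3, abasic=4 (probe only);
//   a strand's "binding frame" g is the reverse complement of the strand
//   sequence, laid 5'->3' along the probe, so a Watson-Crick pair is base
//   equality and probe position p pairs g position p + d on diagonal d;
//   step lookup index (x, y, gw, gz) -> ((x*4+y)*4+gw)*4+gz with x,y the
//   probe dinucleotide and gw,gz the binding-frame dinucleotide.
//
// Fragment-end weighting (finite segments): an end strictly inside the
// segment requires a cut (factor p); an end at the segment boundary is a
// molecule end (factor 1); j-1 internal junctions stay uncut (q^(j-1)).
// The aggregated path groups fragments by their energy window on the
// probe: for windows touching a probe edge, all fragments extending past
// that edge share the window's energy, and their summed end factor is
// exactly q (the tail-concentration marginal), emitted as an "open" side
// state. States: 0 = cut, 1 = segment boundary, 2 = open (past the probe).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double GAS_R = 8.314462618;
static const double EXP_CLAMP = 700.0;

struct NNTables {
  const double *dH, *dS, *initH, *initS;
  const int *defined, *mismatch;
  double tempK, saltTerm;  // saltTerm = saltCoef * log(na), per pair
};

// helix-initiation class of a terminal pair: G/C if either base of the
// pair is G or C (strand-symmetric; for Watson-Crick pairs this is the
// standard classification). Bases coded A=0,C=1,G=2,T=3; the partner
// strand base is the complement of the binding-frame base, and C/G is
// closed under complementation, so the test uses the frame base as is.
static inline int initBase(int probeBase, int frameBase) {
  bool gc = (probeBase == 1 || probeBase == 2 ||
             frameBase == 1 || frameBase == 2);
  return gc ? 1 : 0;  // index into initH/initS: 0 = A/T, 1 = G/C
}

static inline int stepIdx(int x, int y, int gw, int gz) {
  return ((x * 4 + y) * 4 + gw) * 4 + gz;
}

// dH/dS of one step, Rcpp::stop on a missing single-mismatch value;
// undefined double-mismatch contexts contribute zero and are counted.
static inline void stepTerms(const NNTables &tb, int x, int y, int gw,
                             int gz, double &h, double &s, long &undef) {
  int idx = stepIdx(x, y, gw, gz);
  if (tb.defined[idx]) { h = tb.dH[idx]; s = tb.dS[idx]; return; }
  int nmm = (x != gw) + (y != gz);
  if (nmm >= 2) { h = 0.0; s = 0.0; ++undef; return; }
  static const char *B = "ACGT";
  static const char *C = "TGCA";
  std::string step;
  step += B[x]; step += B[y]; step += '/';
  step += C[gw]; step += C[gz];
  stop("no NN parameter for step %s", step.c_str());
}

// free energy of the window [a, b] (probe coords, inclusive) on diagonal
// d against binding frame g; at most one abasic position in the probe.
// Returns false if fewer than 2 paired (non-abasic) positions.
static bool windowDG(const std::vector<int> &probe,
                     const std::vector<int> &g, int a, int b, int d,
                     const NNTables &tb, double &dg, long &undef) {
  int abas = -1, paired = 0;
  for (int p = a; p <= b; ++p) {
    if (probe[p - 1] == 4) abas = p; else ++paired;
  }
  if (paired < 2) return false;
  dg = 0.0;
  int starts[2] = {a, -1}, ends[2] = {b, -1};
  int nseg = 1;
  if (abas >= 0) {
    starts[0] = a; ends[0] = abas - 1;
    starts[1] = abas + 1; ends[1] = b;
    nseg = 2;
  }
  for (int sgi = 0; sgi < nseg; ++sgi) {
    int x0 = starts[sgi], x1 = ends[sgi];
    int len = x1 - x0 + 1;
    if (len < 2) continue;  // a lone pair at a nick contributes nothing
    double H = 0.0, S = 0.0, h, s;
    for (int p = x0; p < x1; ++p) {
      stepTerms(tb, probe[p - 1], probe[p], g[p + d - 1], g[p + d],
                h, s, undef);
      H += h; S += s;
    }
    H += tb.initH[initBase(probe[x0 - 1], g[x0 + d - 1])] +
         tb.initH[initBase(probe[x1 - 1], g[x1 + d - 1])];
    S += tb.initS[initBase(probe[x0 - 1], g[x0 + d - 1])] +
         tb.initS[initBase(probe[x1 - 1], g[x1 + d - 1])];
    dg += (H - tb.tempK * S) + tb.saltTerm * (len - 1);
  }
  return true;
}

static inline double keqOf(double dg, double tempK, long &clamped) {
  double ex = -dg / (GAS_R * tempK);
  if (ex > EXP_CLAMP) { ex = EXP_CLAMP; ++clamped; }
  else if (ex < -EXP_CLAMP) { ex = -EXP_CLAMP; ++clamped; }
  return std::exp(ex);
}

static NNTables makeTables(const NumericVector &dH, const NumericVector &dS,
                           const IntegerVector &defined,
                           const IntegerVector &mismatch,
                           const NumericVector &initH,
                           const NumericVector &initS,
                           double tempK, double saltTerm) {
  NNTables tb;
  tb.dH = dH.begin(); tb.dS = dS.begin();
  tb.defined = defined.begin(); tb.mismatch = mismatch.begin();
  tb.initH = initH.begin(); tb.initS = initS.begin();
  tb.tempK = tempK; tb.saltTerm = saltTerm;
  return tb;
}

static std::vector<int> rcVec(const std::vector<int> &v) {
  std::vector<int> out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = 3 - v[v.size() - 1 - i];
  return out;
}

// [[Rcpp::export]]
List cpp_keq_entries(IntegerVector probe, List segments, NumericVector dH,
                     NumericVector dS, IntegerVector defined,
                     IntegerVector mismatch, NumericVector initH,
                     NumericVector initS, double tempK, double saltTerm,
                     bool allowLeftOverhang) {
  NNTables tb = makeTables(dH, dS, defined, mismatch, initH, initS,
                           tempK, saltTerm);
  int P = probe.size();
  std::vector<int> pv(probe.begin(), probe.end());
  std::vector<int> segv, outSeg, outStrand, outI, outJ, outK, outClass;
  std::vector<double> outKeq;
  long undef = 0, clamped = 0;
  for (int si = 0; si < segments.size(); ++si) {
    IntegerVector seg = segments[si];
    std::vector<int> fwd(seg.begin(), seg.end());
    int L = (int)fwd.size();
    for (int strand = 0; strand < 2; ++strand) {
      // strand sequence t: fwd = segment, rev = revcomp(segment);
      // binding frame g = revcomp(t)
      std::vector<int> g = (strand == 0) ? rcVec(fwd) : fwd;
      for (int i = 1; i <= L - 1; ++i) {
        for (int j = 2; j <= L - i + 1; ++j) {
          // fragment t[i .. i+j-1] in g coords: [ga, gb]
          int ga = L - (i + j - 1) + 1, gb = L - i + 1;
          for (int d = ga - P; d <= gb - 2; ++d) {
            int wa = std::max(ga, 1 + d), wb = std::min(gb, P + d);
            if (wb - wa + 1 < 2) continue;
            if (!allowLeftOverhang && ga < 1 + d) continue;
            double dg;
            if (!windowDG(pv, g, wa - d, wb - d, d, tb, dg, undef))
              continue;
            double K = keqOf(dg, tempK, clamped);
            int leftOpen = (i == 1) ? 1 : 0;           // t 5' end at boundary
            int rightOpen = (i + j - 1 == L) ? 1 : 0;  // t 3' end at boundary
            int cls = leftOpen && rightOpen ? 3 : (rightOpen ? 2 :
                      (leftOpen ? 1 : 0));
            outSeg.push_back(si + 1);
            outStrand.push_back(strand);
            outI.push_back(i);
            outJ.push_back(j);
            // probe-frame coordinate of the fragment's 5' end (equals
            // the position of its 5'-most paired base unless the
            // fragment overhangs the probe's 3' side, where it can
            // exceed the probe length; keeps (i,j,k) unique)
            outK.push_back(gb - d);
            outClass.push_back(cls);
            outKeq.push_back(K);
          }
        }
      }
    }
  }
  List res = List::create(
      _["segment"] = wrap(outSeg), _["strand"] = wrap(outStrand),
      _["i"] = wrap(outI), _["j"] = wrap(outJ), _["k"] = wrap(outK),
      _["class"] = wrap(outClass), _["keq"] = wrap(outKeq));
  res.attr("undef_steps") = (double)undef;
  res.attr("clamped") = (double)clamped;
  return res;
}

// Aggregated duplex-window sums for one probe variant: per (segment,
// left state, right state, window length j), the total K_eq and the
// totals restricted to K_eq >= each wash-grid value.
// [[Rcpp::export]]
List cpp_keq_agg(IntegerVector probe, List segments, NumericVector dH,
                 NumericVector dS, IntegerVector defined,
                 IntegerVector mismatch, NumericVector initH,
                 NumericVector initS, double tempK, double saltTerm,
                 NumericVector washGrid, bool allowLeftOverhang) {
  NNTables tb = makeTables(dH, dS, defined, mismatch, initH, initS,
                           tempK, saltTerm);
  int P = probe.size();
  int G = washGrid.size();
  int nseg = segments.size();
  std::vector<int> pv(probe.begin(), probe.end());
  long undef = 0, clamped = 0;
  // accumulator [seg][ls][rs][j] -> (sumK, sumK >= w_1, ..., sumK >= w_G)
  int jdim = P + 1;
  std::vector<double> acc((size_t)nseg * 9 * jdim * (1 + G), 0.0);
  auto slot = [&](int si, int ls, int rs, int j) {
    return (((size_t)si * 9 + ls * 3 + rs) * jdim + j) * (1 + G);
  };
  std::vector<double> SH(P + 1), SS(P + 1);
  for (int si = 0; si < nseg; ++si) {
    IntegerVector seg = segments[si];
    std::vector<int> fwd(seg.begin(), seg.end());
    int L = (int)fwd.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<int> g = (strand == 0) ? rcVec(fwd) : fwd;
      for (int d = 1 - P + 1; d <= L - 2; ++d) {
        int plo = std::max(1, 1 - d), phi = std::min(P, L - d);
        if (phi - plo + 1 < 2) continue;
        // abasic position (if any) inside [plo, phi]
        int abas = -1;
        for (int p = plo; p <= phi; ++p)
          if (pv[p - 1] == 4) { abas = p; break; }
        // prefix sums of step terms along the diagonal; SH[p] = sum of
        // steps (plo..p) -> step between p and p+1 stored at index p
        SH[plo - 1] = 0.0; SS[plo - 1] = 0.0;
        for (int p = plo; p < phi; ++p) {
          double h = 0.0, s = 0.0;
          if (pv[p - 1] != 4 && pv[p] != 4)
            stepTerms(tb, pv[p - 1], pv[p], g[p + d - 1], g[p + d],
                      h, s, undef);
          SH[p] = SH[p - 1] + h;
          SS[p] = SS[p - 1] + s;
        }
        auto helixHS = [&](int x0, int x1, double &H, double &S,
                           int &pairs) {
          int len = x1 - x0 + 1;
          if (len < 2) { pairs = 0; return; }
          H = SH[x1 - 1] - SH[x0 - 1] +
              tb.initH[initBase(pv[x0 - 1], g[x0 + d - 1])] +
              tb.initH[initBase(pv[x1 - 1], g[x1 + d - 1])];
          S = SS[x1 - 1] - SS[x0 - 1] +
              tb.initS[initBase(pv[x0 - 1], g[x0 + d - 1])] +
              tb.initS[initBase(pv[x1 - 1], g[x1 + d - 1])];
          pairs = len;
        };
        for (int a = plo; a <= phi - 1; ++a) {
          for (int b = a + 1; b <= phi; ++b) {
            int j = b - a + 1;
            double dg = 0.0;
            if (abas >= a && abas <= b) {
              if (j - 1 < 2) continue;  // < 2 paired positions
              double H1 = 0, S1 = 0, H2 = 0, S2 = 0;
              int p1 = 0, p2 = 0;
              helixHS(a, abas - 1, H1, S1, p1);
              helixHS(abas + 1, b, H2, S2, p2);
              if (p1 >= 2)
                dg += (H1 - tb.tempK * S1) + tb.saltTerm * (p1 - 1);
              if (p2 >= 2)
                dg += (H2 - tb.tempK * S2) + tb.saltTerm * (p2 - 1);
            } else {
              double H = 0, S = 0; int pr = 0;
              helixHS(a, b, H, S, pr);
              dg = (H - tb.tempK * S) + tb.saltTerm * (pr - 1);
            }
            double K = keqOf(dg, tempK, clamped);
            int ga = a + d, gb = b + d;
            // side options: {state, valid}
            int lstates[2], nls = 0;
            lstates[nls++] = (ga == 1) ? 1 : 0;     // exact end
            if (a == 1 && ga > 1 && allowLeftOverhang)
              lstates[nls++] = 2;                   // extends past probe
            int rstates[2], nrs = 0;
            rstates[nrs++] = (gb == L) ? 1 : 0;
            if (b == P && gb < L) rstates[nrs++] = 2;
            for (int li = 0; li < nls; ++li)
              for (int ri = 0; ri < nrs; ++ri) {
                size_t s0 = slot(si, lstates[li], rstates[ri], j);
                acc[s0] += K;
                for (int wgi = 0; wgi < G; ++wgi) {
                  if (K >= washGrid[wgi]) acc[s0 + 1 + wgi] += K;
                  else break;  // washGrid sorted ascending
                }
              }
          }
        }
      }
    }
  }
  // emit non-empty rows
  std::vector<double> rows;
  int ncol = 4 + 1 + G;
  for (int si = 0; si < nseg; ++si)
    for (int ls = 0; ls < 3; ++ls)
      for (int rs = 0; rs < 3; ++rs)
        for (int j = 2; j <= P; ++j) {
          size_t s0 = slot(si, ls, rs, j);
          if (acc[s0] == 0.0) continue;
          rows.push_back(si + 1); rows.push_back(ls);
          rows.push_back(rs); rows.push_back(j);
          for (int c = 0; c <= G; ++c) rows.push_back(acc[s0 + c]);
        }
  int nrow = (int)rows.size() / ncol;
  NumericMatrix out(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) out(r, c) = rows[(size_t)r * ncol + c];
  List res = List::create(_["agg"] = out);
  res.attr("undef_steps") = (double)undef;
  res.attr("clamped") = (double)clamped;
  return res;
}
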