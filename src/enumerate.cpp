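#include <Rcpp.h>
using namespace Rcpp;

// Bounded combinatorial enumeration of elemental compositions whose
// monoisotopic mass falls inside a ppm window around a target neutral mass.
// Element order throughout: C, H, N, O, S, Na, Mg, Cl. Heteroatom loops are
// pruned on cumulative mass; the C/H pair is solved per branch, so the inner
// work per heteroatom combination is O(#feasible C values).

static const double M_C  = 12.0;
static const double M_H  = 1.0078250319;
static const double M_N  = 14.0030740052;
static const double M_O  = 15.9949146221;
static const double M_S  = 31.9720707;
static const double M_NA = 22.98976928;
static const double M_MG = 23.9850417;
static const double M_CL = 34.96885268;

// [[Rcpp::export(name = ".enumerate_cpp")]]
List enumerate_cpp(double target, double tol_ppm,
                   IntegerVector lo_bound, IntegerVector hi_bound) {
  const double lo = target * (1.0 - tol_ppm * 1e-6);
  const double hi = target * (1.0 + tol_ppm * 1e-6);

  // bounds arrive in canonical element order C,H,N,O,S,Na,Mg,Cl
  const int cL = lo_bound[0], cH = hi_bound[0];
  const int hL = lo_bound[1], hH = hi_bound[1];
  const int nL = lo_bound[2], nH_ = hi_bound[2];
  const int oL = lo_bound[3], oH = hi_bound[3];
  const int sL = lo_bound[4], sH = hi_bound[4];
  const int naL = lo_bound[5], naH = hi_bound[5];
  const int mgL = lo_bound[6], mgH = hi_bound[6];
  const int clL = lo_bound[7], clH = hi_bound[7];

  // minimal mass the C/H part must still contribute
  const double min_ch = M_C * cL + M_H * hL;

  std::vector<int> counts;   // flattened rows, 8 per hit
  std::vector<double> masses;

  for (int ncl = clL; ncl <= clH; ++ncl) {
    double m_cl = M_CL * ncl;
    if (m_cl + min_ch > hi) break;
    for (int nmg = mgL; nmg <= mgH; ++nmg) {
      double m_mg = m_cl + M_MG * nmg;
      if (m_mg + min_ch > hi) break;
      for (int nna = naL; nna <= naH; ++nna) {
        double m_na = m_mg + M_NA * nna;
        if (m_na + min_ch > hi) break;
        for (int ns = sL; ns <= sH; ++ns) {
          double m_s = m_na + M_S * ns;
          if (m_s + min_ch > hi) break;
          for (int no = oL; no <= oH; ++no) {
            double m_o = m_s + M_O * no;
            if (m_o + min_ch > hi) break;
            for (int nn = nL; nn <= nH_; ++nn) {
              double m_het = m_o + M_N * nn;
              if (m_het + min_ch > hi) break;
              for (int nc = cL; nc <= cH; ++nc) {
                double m_c = m_het + M_C * nc;
                if (m_c + M_H * hL > hi) break;
                // solve the H count range inside the window
                double h_lo = (lo - m_c) / M_H;
                double h_hi = (hi - m_c) / M_H;
                int h0 = (int)std::ceil(h_lo - 1e-12);
                int h1 = (int)std::floor(h_hi + 1e-12);
                if (h0 < hL) h0 = hL;
                if (h1 > hH) h1 = hH;
                for (int nh = h0; nh <= h1; ++nh) {
                  double m = m_c + M_H * nh;
                  if (m < lo || m > hi) continue;
                  counts.push_back(nc); counts.push_back(nh);
                  counts.push_back(nn); counts.push_back(no);
                  counts.push_back(ns); counts.push_back(nna);
                  counts.push_back(nmg); counts.push_back(ncl);
                  masses.push_back(m);
                }
              }
            }
          }
        }
      }
    }
  }

  int nrow = (int)masses.size();
  IntegerMatrix cm(nrow, 8);
  NumericVector mv(nrow);
  for (int i = 0; i < nrow; ++i) {
    for (int j = 0; j < 8; ++j) cm(i, j) = counts[(size_t)i * 8 + j];
    mv[i] = masses[i];
  }
  colnames(cm) = CharacterVector::create("C", "H", "N", "O", "S",
                                         "Na", "Mg", "Cl");
  return List::create(_["counts"] = cm, _["mass"] = mv);
}
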