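#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Truncated 4-D Gaussian kernel smoothing of LOR-bin counts.
//
// Each event carries a 4-D LOR coordinate x = (u_a, v_a, u_b, v_b) on a faced
// block pair; its unit count is spread over the bin lattice of that pair with
// weight exp(-1/2 dx' H^-1 dx), truncated at the 95% kernel volume contour
// (Mahalanobis^2 <= chi2), and renormalized over the in-bounds truncated
// neighborhood so that every event deposits exactly one count (discrete
// normalization N).  Kernel support never crosses block-pair boundaries.
//
// A dense per-pair buffer is reused across pairs; smoothed values are either
// gathered at caller-supplied query bins ("occupied" mode) or returned for
// every nonzero bin ("full" mode, small problems / oracle tests).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_kde_smooth(IntegerVector ev_pair, NumericMatrix coords,
                    NumericVector h2, double pitch, int n_u, int n_v,
                    double half_w, double half_h, double chi2,
                    IntegerVector q_pair, NumericVector q_pa,
                    NumericVector q_pb, bool full, int n_pairs) {
  const int P = n_u * n_v;
  const double P2 = (double)P * (double)P;
  if (P2 > 5e7) stop("pixel grid too fine for dense per-pair smoothing");
  std::vector<double> buf((size_t)P * P, 0.0);
  std::vector<size_t> touched;

  // events grouped by pair
  std::vector<std::vector<int>> by_pair(n_pairs);
  for (R_xlen_t i = 0; i < ev_pair.size(); ++i)
    by_pair[ev_pair[i]].push_back((int)i);
  std::vector<std::vector<int>> q_by_pair(n_pairs);
  for (R_xlen_t i = 0; i < q_pair.size(); ++i)
    q_by_pair[q_pair[i]].push_back((int)i);

  // per-dimension search half-width in index units
  const int dims_n[4] = {n_u, n_v, n_u, n_v};
  const double lo[4] = {-half_w, -half_h, -half_w, -half_h};
  double s[4];
  for (int d = 0; d < 4; ++d) s[d] = std::sqrt(chi2 * h2[d]);

  NumericVector q_val(q_pair.size());
  double total_mass = 0.0;
  std::vector<double> full_bins, full_vals, full_pairs;
  std::vector<std::pair<size_t, double>> scratch;
  scratch.reserve(4096);

  for (int p = 0; p < n_pairs; ++p) {
    if (by_pair[p].empty() && q_by_pair[p].empty()) continue;
    touched.clear();
    for (int ei : by_pair[p]) {
      double x[4] = {coords(ei, 0), coords(ei, 1), coords(ei, 2), coords(ei, 3)};
      int ilo[4], ihi[4];
      for (int d = 0; d < 4; ++d) {
        ilo[d] = std::max(0, (int)std::ceil((x[d] - s[d] - lo[d]) / pitch - 0.5));
        ihi[d] = std::min(dims_n[d] - 1,
                          (int)std::floor((x[d] + s[d] - lo[d]) / pitch - 0.5));
      }
      scratch.clear();
      double wsum = 0.0;
      for (int i0 = ilo[0]; i0 <= ihi[0]; ++i0) {
        double d0 = x[0] - (lo[0] + (i0 + 0.5) * pitch);
        double m0 = d0 * d0 / h2[0];
        if (m0 > chi2) continue;
        for (int i1 = ilo[1]; i1 <= ihi[1]; ++i1) {
          double d1 = x[1] - (lo[1] + (i1 + 0.5) * pitch);
          double m1 = m0 + d1 * d1 / h2[1];
          if (m1 > chi2) continue;
          for (int i2 = ilo[2]; i2 <= ihi[2]; ++i2) {
            double d2 = x[2] - (lo[2] + (i2 + 0.5) * pitch);
            double m2 = m1 + d2 * d2 / h2[2];
            if (m2 > chi2) continue;
            size_t pa = (size_t)i0 * n_v + i1;
            for (int i3 = ilo[3]; i3 <= ihi[3]; ++i3) {
              double d3 = x[3] - (lo[3] + (i3 + 0.5) * pitch);
              double m3 = m2 + d3 * d3 / h2[3];
              if (m3 > chi2) continue;
              double w = std::exp(-0.5 * m3);
              size_t idx = pa * (size_t)P + (size_t)i2 * n_v + i3;
              scratch.emplace_back(idx, w);
              wsum += w;
            }
          }
        }
      }
      if (scratch.empty()) {
        // delta-kernel limit: bandwidth far below the pitch, keep the raw bin
        int iu_a = std::min(n_u - 1, std::max(0, (int)std::floor((x[0] - lo[0]) / pitch)));
        int iv_a = std::min(n_v - 1, std::max(0, (int)std::floor((x[1] - lo[1]) / pitch)));
        int iu_b = std::min(n_u - 1, std::max(0, (int)std::floor((x[2] - lo[2]) / pitch)));
        int iv_b = std::min(n_v - 1, std::max(0, (int)std::floor((x[3] - lo[3]) / pitch)));
        size_t idx = ((size_t)iu_a * n_v + iv_a) * (size_t)P + (size_t)iu_b * n_v + iv_b;
        scratch.emplace_back(idx, 1.0);
        wsum = 1.0;
      }
      for (auto& e : scratch) {
        if (buf[e.first] == 0.0) touched.push_back(e.first);
        buf[e.first] += e.second / wsum;
      }
      total_mass += 1.0;
    }
    for (int qi : q_by_pair[p]) {
      size_t idx = (size_t)q_pa[qi] * (size_t)P + (size_t)q_pb[qi];
      q_val[qi] = buf[idx];
    }
    if (full) {
      std::sort(touched.begin(), touched.end());
      touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
      for (size_t idx : touched) {
        if (buf[idx] != 0.0) {
          full_pairs.push_back(p);
          full_bins.push_back((double)idx);
          full_vals.push_back(buf[idx]);
        }
      }
    }
    for (size_t idx : touched) buf[idx] = 0.0;
  }

  List out = List::create(_["values"] = q_val, _["total_mass"] = total_mass);
  if (full) {
    out["full_pair"] = wrap(full_pairs);
    out["full_index"] = wrap(full_bins);  // pa * P + pb within the pair
    out["full_value"] = wrap(full_vals);
  }
  return out;
}
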