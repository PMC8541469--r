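#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Incremental ray traversal (Siddon-style) computing exact intersection
// lengths of a LOR with a regular voxel grid, plus the list-mode EM engine:
// sensitivity image over the enumerable bin-level LOR set and OSEM/MLEM
// updates with an additive per-event scatter term in the forward model.
// ---------------------------------------------------------------------------

namespace {

struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, vox;
};

// visit(voxel_linear_index, length) for each voxel crossed by segment p1-p2;
// returns the chord length inside the grid
template <typename F>
double traverse(const double* p1, const double* p2, const Grid& g, F&& visit) {
  double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return 0.0;
  double org[3] = {g.ox, g.oy, g.oz};
  int dim[3] = {g.nx, g.ny, g.nz};
  double a0 = 0.0, a1 = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    double lo = org[ax], hi = org[ax] + dim[ax] * g.vox;
    if (std::fabs(d[ax]) < 1e-12) {
      if (p1[ax] < lo || p1[ax] > hi) return 0.0;
    } else {
      double t1 = (lo - p1[ax]) / d[ax], t2 = (hi - p1[ax]) / d[ax];
      a0 = std::max(a0, std::min(t1, t2));
      a1 = std::min(a1, std::max(t1, t2));
    }
  }
  if (a0 >= a1) return 0.0;

  int idx[3], step[3];
  double anext[3], adelta[3];
  // locate the entry voxel just inside the entry face
  double start = a0 + 1e-9 * (a1 - a0);
  for (int ax = 0; ax < 3; ++ax) {
    double pm = p1[ax] + start * d[ax];
    idx[ax] = (int)std::floor((pm - org[ax]) / g.vox);
    idx[ax] = std::max(0, std::min(dim[ax] - 1, idx[ax]));
    if (d[ax] > 1e-12) {
      step[ax] = 1;
      anext[ax] = (org[ax] + (idx[ax] + 1) * g.vox - p1[ax]) / d[ax];
      adelta[ax] = g.vox / d[ax];
    } else if (d[ax] < -1e-12) {
      step[ax] = -1;
      anext[ax] = (org[ax] + idx[ax] * g.vox - p1[ax]) / d[ax];
      adelta[ax] = -g.vox / d[ax];
    } else {
      step[ax] = 0;
      anext[ax] = 2.0;  // beyond a1
      adelta[ax] = 0.0;
    }
  }
  double cur = a0;
  while (cur < a1 - 1e-12) {
    int m = 0;
    if (anext[1] < anext[m]) m = 1;
    if (anext[2] < anext[m]) m = 2;
    double an = std::min(anext[m], a1);
    double len = (an - cur) * L;
    if (len > 0.0) {
      int lin = idx[0] + dim[0] * (idx[1] + dim[1] * idx[2]);
      visit(lin, len);
    }
    if (anext[m] >= a1) break;
    cur = anext[m];
    idx[m] += step[m];
    if (idx[m] < 0 || idx[m] >= dim[m]) break;
    anext[m] += adelta[m];
  }
  return (a1 - a0) * L;
}

}  // namespace

// [[Rcpp::export]]
List cpp_project(NumericVector p1, NumericVector p2, IntegerVector dim,
                 NumericVector origin, double vox) {
  Grid g{dim[0], dim[1], dim[2], origin[0], origin[1], origin[2], vox};
  std::vector<int> idx;
  std::vector<double> len;
  double chord = traverse(&p1[0], &p2[0], g, [&](int i, double l) {
    idx.push_back(i + 1);  // 1-based for R
    len.push_back(l);
  });
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len),
                      _["chord"] = chord);
}

// Sensitivity image(s): sum of a_ij over every allowed bin-level LOR,
// accumulated per ordered subset (column) of block pairs.
// [[Rcpp::export]]
NumericMatrix cpp_sensitivity(IntegerMatrix pairs, IntegerVector pair_subset,
                              int n_subsets, int n_blocks, double apothem,
                              NumericVector u_centers, NumericVector v_centers,
                              IntegerVector dim, NumericVector origin,
                              double vox) {
  Grid g{dim[0], dim[1], dim[2], origin[0], origin[1], origin[2], vox};
  int nvox = g.nx * g.ny * g.nz;
  int n_u = u_centers.size(), n_v = v_centers.size();
  NumericMatrix sens(nvox, n_subsets);
  std::vector<double> bc(n_blocks), bs(n_blocks);
  for (int k = 0; k < n_blocks; ++k) {
    double a = 2.0 * M_PI * k / n_blocks;
    bc[k] = std::cos(a); bs[k] = std::sin(a);
  }
  for (int ip = 0; ip < pairs.nrow(); ++ip) {
    int ka = pairs(ip, 0), kb = pairs(ip, 1);
    int sub = pair_subset[ip];
    double* col = &sens(0, sub);
    double na[2] = {bc[ka], bs[ka]}, ta[2] = {-bs[ka], bc[ka]};
    double nb[2] = {bc[kb], bs[kb]}, tb[2] = {-bs[kb], bc[kb]};
    for (int iua = 0; iua < n_u; ++iua) {
      for (int iva = 0; iva < n_v; ++iva) {
        double pa[3] = {apothem * na[0] + u_centers[iua] * ta[0],
                        apothem * na[1] + u_centers[iua] * ta[1],
                        v_centers[iva]};
        for (int iub = 0; iub < n_u; ++iub) {
          double bx = apothem * nb[0] + u_centers[iub] * tb[0];
          double by = apothem * nb[1] + u_centers[iub] * tb[1];
          for (int ivb = 0; ivb < n_v; ++ivb) {
            double pb[3] = {bx, by, v_centers[ivb]};
            traverse(pa, pb, g, [&](int i, double l) { col[i] += l; });
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return sens;
}

// OSEM with additive scatter term S_i in the forward model; n_subsets = 1 is
// plain MLEM.  loglik[k] = sum_events log(fwd + S) - sum_j senstot_j n_j,
// the list-mode Poisson log-likelihood up to a constant in n.
// [[Rcpp::export]]
List cpp_osem(NumericMatrix ep, NumericVector S, IntegerVector ev_subset,
              NumericVector img0, NumericMatrix sens, IntegerVector dim,
              NumericVector origin, double vox, int n_iter, int n_subsets,
              double eps) {
  Grid g{dim[0], dim[1], dim[2], origin[0], origin[1], origin[2], vox};
  int nvox = g.nx * g.ny * g.nz;
  R_xlen_t nev = ep.nrow();
  std::vector<double> img(img0.begin(), img0.end());
  std::vector<double> acc(nvox), senstot(nvox, 0.0);
  for (int j = 0; j < nvox; ++j)
    for (int s = 0; s < n_subsets; ++s) senstot[j] += sens(j, s);
  std::vector<std::vector<R_xlen_t>> by_sub(n_subsets);
  for (R_xlen_t e = 0; e < nev; ++e) by_sub[ev_subset[e]].push_back(e);

  NumericVector loglik(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    for (int sub = 0; sub < n_subsets; ++sub) {
      if (by_sub[sub].empty()) continue;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (R_xlen_t e : by_sub[sub]) {
        double p1[3] = {ep(e, 0), ep(e, 1), ep(e, 2)};
        double p2[3] = {ep(e, 3), ep(e, 4), ep(e, 5)};
        double f = 0.0;
        traverse(p1, p2, g, [&](int j, double l) { f += l * img[j]; });
        double w = 1.0 / std::max(f + S[e], eps);
        traverse(p1, p2, g, [&](int j, double l) { acc[j] += l * w; });
      }
      for (int j = 0; j < nvox; ++j) {
        double sj = sens(j, sub);
        if (sj > 0.0) img[j] *= acc[j] / sj;
      }
      Rcpp::checkUserInterrupt();
    }
    double ll = 0.0;
    for (R_xlen_t e = 0; e < nev; ++e) {
      double p1[3] = {ep(e, 0), ep(e, 1), ep(e, 2)};
      double p2[3] = {ep(e, 3), ep(e, 4), ep(e, 5)};
      double f = 0.0;
      traverse(p1, p2, g, [&](int j, double l) { f += l * img[j]; });
      ll += std::log(std::max(f + S[e], eps));
    }
    for (int j = 0; j < nvox; ++j) ll -= senstot[j] * img[j];
    loglik[it] = ll;
  }
  return List::create(_["image"] = wrap(img), _["loglik"] = loglik);
}
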