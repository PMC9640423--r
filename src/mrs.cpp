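// Multiresolution region-merging segmentation (Baatz–Schäpe style).
//
// Bottom-up pairwise merging from single-pixel segments. A merge of
// segments a, b is allowed iff
//   f = w_shape * h_shape + (1 - w_shape) * h_colour < scale^2
// with
//   h_colour  = sum_b (n_m sigma_m,b - n_a sigma_a,b - n_b sigma_b,b)
//   h_shape   = w_cmpct * h_compact + (1 - w_cmpct) * h_smooth
//   h_compact = P_m sqrt(n_m) - (P_a sqrt(n_a) + P_b sqrt(n_b))
//   h_smooth  = n_m P_m / B_m - (n_a P_a / B_a + n_b P_b / B_b)
// where sigma is the population sd per band, P the perimeter in pixel
// edges and B the bounding-box perimeter. Merging follows local
// mutual-best-fitting: sweeps in ascending segment id; a segment merges
// with its cheapest neighbour (ties -> lowest id) only if it is that
// neighbour's cheapest neighbour in return; sweeps repeat to a fixed
// point. The merged segment keeps the smaller id. 4-connectivity.
// Initial ids are column-major pixel order (R layout), so the R reference
// implementation in the test suite can reproduce the ordering exactly.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  bool alive = false;
  double n = 0;
  std::vector<double> sum, sum2;
  double perim = 0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  std::map<int, double> nbr;  // neighbour id -> shared edge count
};

inline double seg_colour(const Seg &s, int nb) {
  double tot = 0;
  for (int b = 0; b < nb; ++b) {
    double mu = s.sum[b] / s.n;
    double var = s.sum2[b] / s.n - mu * mu;
    if (var < 0) var = 0;
    tot += s.n * std::sqrt(var);
  }
  return tot;
}

inline double bbox_perim(int rmin, int rmax, int cmin, int cmax) {
  return 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
}

}  // namespace

// [[Rcpp::export(name = ".mrs_segment_cpp")]]
IntegerVector mrs_segment_cpp(NumericVector bands, int H, int W, int NB,
                              LogicalVector valid, double scale,
                              double shape_weight, double compactness_weight) {
  const double thr = scale * scale;
  const int N = H * W;
  std::vector<Seg> segs(N + 1);
  std::vector<int> parent(N + 1, 0);

  auto val = [&](int px, int b) -> double { return bands[b * N + px]; };

  for (int px = 0; px < N; ++px) {
    if (!valid[px]) continue;
    int id = px + 1;
    parent[id] = id;
    Seg &s = segs[id];
    s.alive = true;
    s.n = 1;
    s.sum.resize(NB);
    s.sum2.resize(NB);
    for (int b = 0; b < NB; ++b) {
      double v = val(px, b);
      s.sum[b] = v;
      s.sum2[b] = v * v;
    }
    s.perim = 4;
    s.rmin = s.rmax = px % H;
    s.cmin = s.cmax = px / H;
  }
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int px = c * H + r;
      if (!valid[px]) continue;
      if (r + 1 < H && valid[px + 1]) {
        segs[px + 1].nbr[px + 2] += 1;
        segs[px + 2].nbr[px + 1] += 1;
      }
      if (c + 1 < W && valid[px + H]) {
        segs[px + 1].nbr[px + H + 1] += 1;
        segs[px + H + 1].nbr[px + 1] += 1;
      }
    }
  }

  auto cost = [&](int ia, int ib) -> double {
    const Seg &A = segs[ia];
    const Seg &B = segs[ib];
    double n_m = A.n + B.n;
    double colour_m = 0;
    for (int b = 0; b < NB; ++b) {
      double s = A.sum[b] + B.sum[b];
      double s2 = A.sum2[b] + B.sum2[b];
      double mu = s / n_m;
      double var = s2 / n_m - mu * mu;
      if (var < 0) var = 0;
      colour_m += n_m * std::sqrt(var);
    }
    double h_colour = colour_m - seg_colour(A, NB) - seg_colour(B, NB);

    double shared = A.nbr.at(ib);
    double P_m = A.perim + B.perim - 2.0 * shared;
    double h_compact = P_m * std::sqrt(n_m) -
      (A.perim * std::sqrt(A.n) + B.perim * std::sqrt(B.n));
    int rmin = std::min(A.rmin, B.rmin), rmax = std::max(A.rmax, B.rmax);
    int cmin = std::min(A.cmin, B.cmin), cmax = std::max(A.cmax, B.cmax);
    double h_smooth = n_m * P_m / bbox_perim(rmin, rmax, cmin, cmax) -
      (A.n * A.perim / bbox_perim(A.rmin, A.rmax, A.cmin, A.cmax) +
       B.n * B.perim / bbox_perim(B.rmin, B.rmax, B.cmin, B.cmax));
    double h_shape = compactness_weight * h_compact +
      (1 - compactness_weight) * h_smooth;
    return shape_weight * h_shape + (1 - shape_weight) * h_colour;
  };

  auto best_of = [&](int id, double &bc) -> int {
    const Seg &S = segs[id];
    int best = 0;
    bc = R_PosInf;
    for (const auto &kv : S.nbr) {
      double c = cost(id, kv.first);
      if (c < bc - 1e-12 || (std::fabs(c - bc) <= 1e-12 && kv.first < best)) {
        bc = c;
        best = kv.first;
      }
    }
    return best;
  };

  auto do_merge = [&](int ia, int ib) {
    int keep = std::min(ia, ib), drop = std::max(ia, ib);
    Seg &K = segs[keep];
    Seg &D = segs[drop];
    double shared = K.nbr.at(drop);
    K.perim = K.perim + D.perim - 2.0 * shared;
    K.n += D.n;
    for (int b = 0; b < NB; ++b) {
      K.sum[b] += D.sum[b];
      K.sum2[b] += D.sum2[b];
    }
    K.rmin = std::min(K.rmin, D.rmin);
    K.rmax = std::max(K.rmax, D.rmax);
    K.cmin = std::min(K.cmin, D.cmin);
    K.cmax = std::max(K.cmax, D.cmax);
    K.nbr.erase(drop);
    for (const auto &kv : D.nbr) {
      if (kv.first == keep) continue;
      K.nbr[kv.first] += kv.second;
      Seg &Nb = segs[kv.first];
      Nb.nbr.erase(drop);
      Nb.nbr[keep] = K.nbr[kv.first];
    }
    parent[drop] = keep;
    D = Seg();
  };

  bool merged_any = true;
  std::vector<int> order;
  order.reserve(N);
  while (merged_any) {
    merged_any = false;
    order.clear();
    for (int id = 1; id <= N; ++id)
      if (segs[id].alive) order.push_back(id);
    for (int id : order) {
      if (!segs[id].alive || segs[id].nbr.empty()) continue;
      double ca;
      int b = best_of(id, ca);
      if (!(ca < thr)) continue;
      double cb;
      int bb = best_of(b, cb);
      if (bb != id) continue;
      do_merge(id, b);
      merged_any = true;
    }
    Rcpp::checkUserInterrupt();
  }

  auto find = [&](int id) {
    int root = id;
    while (parent[root] != root) root = parent[root];
    while (parent[id] != root) {
      int nxt = parent[id];
      parent[id] = root;
      id = nxt;
    }
    return root;
  };

  // relabel 1..n_segments in order of first pixel (column-major scan)
  IntegerVector out(N, NA_INTEGER);
  std::map<int, int> remap;
  int next_id = 0;
  for (int px = 0; px < N; ++px) {
    if (!valid[px]) continue;
    int root = find(px + 1);
    auto it = remap.find(root);
    if (it == remap.end()) {
      remap[root] = ++next_id;
      out[px] = next_id;
    } else {
      out[px] = it->second;
    }
  }
  out.attr("n_segments") = next_id;
  return out;
}
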