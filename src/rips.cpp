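// Vietoris-Rips persistent homology by boundary-matrix reduction over GF(2).
//
// Simplices up to skeleton dimension max_dim + 1 are enumerated under the
// diameter cutoff and sorted into filtration order (diameter, then
// dimension, then vertex order).  Columns are processed from the top
// dimension down with the "twist" shortcut (a simplex identified as a pivot
// is cleared so its own column is never reduced).  Columns whose raw pivot
// is unclaimed are paired without being materialised; their boundaries are
// recomputed on demand if a later reduction needs them -- in Rips
// filtrations the vast majority of pairs resolve this way.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Simplex {
  double diam;
  int dim;
  int v[4];
};

inline void sym_diff(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  out.insert(out.end(), a.begin() + i, a.end());
  out.insert(out.end(), b.begin() + j, b.end());
  a.swap(out);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix rips_persistence_cpp(NumericMatrix dmat, double max_scale,
                                   int max_dim) {
  const int n = dmat.nrow();
  const int skel = max_dim + 1;
  const double* D = REAL(dmat);
  auto d = [&](int i, int j) { return D[i + (R_xlen_t)n * j]; };

  std::vector<Simplex> simp;
  simp.reserve((size_t)n * 8);
  for (int i = 0; i < n; ++i) simp.push_back({0.0, 0, {i, -1, -1, -1}});

  std::vector<std::vector<int>> nb(n);  // neighbours j > i under the cutoff
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d(i, j) <= max_scale) nb[i].push_back(j);

  // edges, with an O(1) (i, j) -> simplex-id table
  std::vector<int> edge_id((size_t)n * n, -1);
  const size_t edge_begin = simp.size();
  for (int i = 0; i < n; ++i)
    for (int j : nb[i]) {
      edge_id[(size_t)i * n + j] = (int)simp.size();
      simp.push_back({d(i, j), 1, {i, j, -1, -1}});
    }
  const size_t tri_begin = simp.size();
  const size_t n_edges = tri_begin - edge_begin;

  // triangles, grouped by their (i, j) edge with k ascending, so a
  // (i, j, k) -> simplex-id lookup is a binary search within the group
  const size_t hard_cap = 60000000;
  std::vector<int> tri_start(n_edges + 1, 0);
  if (skel >= 2) {
    for (size_t e = edge_begin; e < tri_begin; ++e) {
      int i = simp[e].v[0], j = simp[e].v[1];
      double de = simp[e].diam;
      for (int k : nb[j]) {
        double dik = d(i, k);
        if (dik <= max_scale) {
          double diam = std::max(de, std::max(dik, d(j, k)));
          simp.push_back({diam, 2, {i, j, k, -1}});
          if (simp.size() > hard_cap)
            stop("Rips filtration too large; lower max_scale or max_points");
        }
      }
      tri_start[e - edge_begin + 1] = (int)(simp.size() - tri_begin);
    }
  }
  const size_t tet_begin = simp.size();

  auto find_tri = [&](int i, int j, int k) -> int {
    // vertices must be sorted ascending
    int e = edge_id[(size_t)i * n + j] - (int)edge_begin;
    int lo = tri_start[e], hi = tri_start[e + 1];
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      int kv = simp[tri_begin + mid].v[2];
      if (kv < k) lo = mid + 1;
      else if (kv > k) hi = mid;
      else return (int)(tri_begin + mid);
    }
    return -1;  // unreachable for a valid filtration
  };

  if (skel >= 3) {
    for (size_t t = tri_begin; t < tet_begin; ++t) {
      int i = simp[t].v[0], j = simp[t].v[1], k = simp[t].v[2];
      double dt = simp[t].diam;
      for (int l : nb[k]) {
        double dil = d(i, l), djl = d(j, l);
        if (dil <= max_scale && djl <= max_scale) {
          double diam = std::max(std::max(dt, d(k, l)), std::max(dil, djl));
          simp.push_back({diam, 3, {i, j, k, l}});
          if (simp.size() > hard_cap)
            stop("Rips filtration too large; lower max_scale or max_points");
        }
      }
    }
  }

  const size_t total = simp.size();

  std::vector<int> ord(total);
  for (size_t s = 0; s < total; ++s) ord[s] = (int)s;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (simp[a].diam != simp[b].diam) return simp[a].diam < simp[b].diam;
    if (simp[a].dim != simp[b].dim) return simp[a].dim < simp[b].dim;
    for (int q = 0; q <= simp[a].dim; ++q)
      if (simp[a].v[q] != simp[b].v[q]) return simp[a].v[q] < simp[b].v[q];
    return false;
  });
  std::vector<int> pos(total);
  for (size_t p = 0; p < total; ++p) pos[ord[p]] = (int)p;

  // boundary facet positions (unsorted), into out[0..dim]
  auto boundary = [&](int s, int* out) -> int {
    const Simplex& sx = simp[s];
    if (sx.dim == 1) {
      out[0] = pos[sx.v[0]];
      out[1] = pos[sx.v[1]];
      return 2;
    }
    if (sx.dim == 2) {
      out[0] = pos[edge_id[(size_t)sx.v[0] * n + sx.v[1]]];
      out[1] = pos[edge_id[(size_t)sx.v[0] * n + sx.v[2]]];
      out[2] = pos[edge_id[(size_t)sx.v[1] * n + sx.v[2]]];
      return 3;
    }
    out[0] = pos[find_tri(sx.v[0], sx.v[1], sx.v[2])];
    out[1] = pos[find_tri(sx.v[0], sx.v[1], sx.v[3])];
    out[2] = pos[find_tri(sx.v[0], sx.v[2], sx.v[3])];
    out[3] = pos[find_tri(sx.v[1], sx.v[2], sx.v[3])];
    return 4;
  };

  std::vector<int> owner(total, -1);  // pivot row -> column position
  std::vector<char> cleared(total, 0), paired_birth(total, 0),
      is_death(total, 0);
  std::vector<double> births, deaths;
  std::vector<int> out_dim;

  for (int dd = skel; dd >= 1; --dd) {
    // columns that needed additions, keyed by column position
    std::unordered_map<int, std::vector<int>> colstore;
    int bnd[4];
    std::vector<int> col;
    auto column_of = [&](int q, std::vector<int>& out) {
      auto it = colstore.find(q);
      if (it != colstore.end()) { out = it->second; return; }
      int m = boundary(ord[q], bnd);
      out.assign(bnd, bnd + m);
      std::sort(out.begin(), out.end());
    };
    for (size_t p = 0; p < total; ++p) {
      int s = ord[p];
      if (simp[s].dim != dd || cleared[p]) continue;
      int m = boundary(s, bnd);
      int piv = *std::max_element(bnd, bnd + m);
      bool reduced_now = false;
      if (owner[piv] >= 0) {
        col.assign(bnd, bnd + m);
        std::sort(col.begin(), col.end());
        std::vector<int> other;
        while (!col.empty()) {
          piv = col.back();
          if (owner[piv] < 0) break;
          column_of(owner[piv], other);
          sym_diff(col, other);
        }
        if (col.empty()) continue;  // creates a class (maybe essential)
        reduced_now = true;
      }
      owner[piv] = (int)p;
      if (reduced_now) colstore[(int)p] = col;
      paired_birth[piv] = 1;
      is_death[p] = 1;
      cleared[piv] = 1;
      double b = simp[ord[piv]].diam, de = simp[s].diam;
      if (de > b && dd - 1 <= max_dim) {
        births.push_back(b);
        deaths.push_back(de);
        out_dim.push_back(dd - 1);
      }
    }
  }

  for (size_t p = 0; p < total; ++p) {
    int s = ord[p];
    if (simp[s].dim <= max_dim && !paired_birth[p] && !is_death[p]) {
      births.push_back(simp[s].diam);
      deaths.push_back(R_PosInf);
      out_dim.push_back(simp[s].dim);
    }
  }

  NumericMatrix res(out_dim.size(), 3);
  for (size_t r = 0; r < out_dim.size(); ++r) {
    res(r, 0) = out_dim[r];
    res(r, 1) = births[r];
    res(r, 2) = deaths[r];
  }
  colnames(res) = CharacterVector::create("dimension", "birth", "death");
  return res;
}
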