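#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Persistence pairing by left-to-right column reduction over Z/2 with the
// twist (clearing) optimization: dimensions are processed top-down and a cell
// paired as a birth is never reduced itself. Columns hold sorted facet
// positions in filtration order, so the pivot is the column's last entry.

static void sym_diff(std::vector<int>& a, const std::vector<int>& b,
                     std::vector<int>& tmp) {
  tmp.clear();
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(tmp));
  a.swap(tmp);
}

struct ReductionResult {
  std::vector<std::pair<int, int> > pairs;  // (birth position, death position)
  std::vector<int> essential;               // positions of never-dying cells
};

static ReductionResult twist_reduce(const std::vector<std::vector<int> >& boundary,
                                    const std::vector<int>& dim,
                                    int top_dim) {
  const int n = (int) boundary.size();
  std::vector<int> pivot_owner(n, -1);
  std::vector<char> cleared(n, 0);  // paired as a birth by a higher column
  std::vector<char> is_zero(n, 0);  // column reduced to zero (positive cell)
  std::vector<std::vector<int> > reduced(n);
  ReductionResult res;
  std::vector<int> col, tmp;
  for (int d = top_dim; d >= 1; --d) {
    for (int pos = 0; pos < n; ++pos) {
      if (dim[pos] != d || cleared[pos]) continue;
      col = boundary[pos];
      while (!col.empty()) {
        int piv = col.back();
        int other = pivot_owner[piv];
        if (other < 0) break;
        sym_diff(col, reduced[other], tmp);
      }
      if (!col.empty()) {
        int piv = col.back();
        pivot_owner[piv] = pos;
        reduced[pos] = col;
        res.pairs.push_back(std::make_pair(piv, pos));
        cleared[piv] = 1;
      } else {
        is_zero[pos] = 1;
      }
    }
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int pos = 0; pos < n; ++pos) {
    if (cleared[pos]) continue;
    if (dim[pos] <= 2 && (dim[pos] == 0 || is_zero[pos]))
      res.essential.push_back(pos);
  }
  return res;
}

static NumericMatrix pack_pairs(const ReductionResult& res,
                                const std::vector<double>& value,
                                const std::vector<int>& dim) {
  std::vector<double> out;  // triples (dim, birth, death)
  for (size_t i = 0; i < res.pairs.size(); ++i) {
    int b = res.pairs[i].first, dth = res.pairs[i].second;
    if (value[b] == value[dth]) continue;  // zero persistence, discard
    out.push_back((double) dim[b]);
    out.push_back(value[b]);
    out.push_back(value[dth]);
  }
  for (size_t i = 0; i < res.essential.size(); ++i) {
    int b = res.essential[i];
    out.push_back((double) dim[b]);
    out.push_back(value[b]);
    out.push_back(R_PosInf);
  }
  int m = (int)(out.size() / 3);
  NumericMatrix mat(m, 3);
  for (int i = 0; i < m; ++i) {
    mat(i, 0) = out[3 * i];
    mat(i, 1) = out[3 * i + 1];
    mat(i, 2) = out[3 * i + 2];
  }
  return mat;
}

// ---------------------------------------------------------------------------
// Cubical sublevel persistence, V-construction: voxels are vertices of the
// complex; a higher cell enters at the maximum of its vertices. Cells live on
// the extended (2nx-1) x (2ny-1) x (2nz-1) grid where a coordinate's parity
// encodes the cell type (odd = spanning). Voxels at +Inf (and incident cells)
// are excluded from the complex.

// [[Rcpp::export]]
NumericMatrix cubical_pairs_cpp(NumericVector vals, IntegerVector shape) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int ex = 2 * nx - 1, ey = 2 * ny - 1, ez = 2 * nz - 1;
  const long long ntot = (long long) ex * ey * ez;
  std::vector<double> cval(ntot);
  std::vector<int> cdim(ntot);
  long long n_fin = 0;
  for (int z = 0; z < ez; ++z)
    for (int y = 0; y < ey; ++y)
      for (int x = 0; x < ex; ++x) {
        long long id = x + (long long) ex * (y + (long long) ey * z);
        cdim[id] = (x & 1) + (y & 1) + (z & 1);
        double v = R_NegInf;
        for (int dz = 0; dz <= (z & 1); ++dz)
          for (int dy = 0; dy <= (y & 1); ++dy)
            for (int dx = 0; dx <= (x & 1); ++dx) {
              double vv = vals[(x / 2 + dx) +
                               (long long) nx * ((y / 2 + dy) +
                               (long long) ny * (z / 2 + dz))];
              if (vv > v) v = vv;
            }
        cval[id] = v;
        if (R_finite(v)) ++n_fin;
      }
  if (n_fin == 0) stop("grid has no finite values");
  std::vector<long long> cells;
  cells.reserve(n_fin);
  for (long long id = 0; id < ntot; ++id)
    if (R_finite(cval[id])) cells.push_back(id);
  std::stable_sort(cells.begin(), cells.end(),
                   [&](long long a, long long b) {
                     if (cval[a] != cval[b]) return cval[a] < cval[b];
                     if (cdim[a] != cdim[b]) return cdim[a] < cdim[b];
                     return a < b;
                   });
  std::vector<int> posof(ntot, -1);
  for (size_t p = 0; p < cells.size(); ++p) posof[cells[p]] = (int) p;
  const int n = (int) cells.size();
  std::vector<std::vector<int> > boundary(n);
  std::vector<int> dim(n);
  std::vector<double> value(n);
  for (int p = 0; p < n; ++p) {
    long long id = cells[p];
    int x = (int)(id % ex);
    int y = (int)((id / ex) % ey);
    int z = (int)(id / ((long long) ex * ey));
    dim[p] = cdim[id];
    value[p] = cval[id];
    std::vector<int>& bd = boundary[p];
    if (x & 1) { bd.push_back(posof[id - 1]); bd.push_back(posof[id + 1]); }
    if (y & 1) { bd.push_back(posof[id - ex]); bd.push_back(posof[id + ex]); }
    if (z & 1) {
      bd.push_back(posof[id - (long long) ex * ey]);
      bd.push_back(posof[id + (long long) ex * ey]);
    }
    std::sort(bd.begin(), bd.end());
  }
  ReductionResult res = twist_reduce(boundary, dim, 3);
  return pack_pairs(res, value, dim);
}

// ---------------------------------------------------------------------------
// Vietoris-Rips persistence up to dimension 2 (simplices to dimension 3).
// Simplex filtration value = diameter; lexicographic combinadic rank is the
// deterministic tie-break and the facet lookup key.

static inline long long choose2(long long m) { return m < 2 ? 0 : m * (m - 1) / 2; }
static inline long long choose3(long long m) { return m < 3 ? 0 : m * (m - 1) * (m - 2) / 6; }

// [[Rcpp::export]]
NumericMatrix rips_pairs_cpp(NumericMatrix pts, double threshold) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  if (n > 170) stop("too many points for explicit Rips enumeration (max 170); subsample first");
  std::vector<double> D((size_t) n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < pts.ncol(); ++c) {
        double d = pts(i, c) - pts(j, c);
        s += d * d;
      }
      double dd = std::sqrt(s);
      D[i + (size_t) n * j] = dd;
      D[j + (size_t) n * i] = dd;
    }
  auto dist = [&](int i, int j) -> double { return D[i + (size_t) n * j]; };
  auto rank2 = [&](long long i, long long j) -> long long {
    return choose2(n) - choose2(n - i) + (j - i - 1);
  };
  auto rank3 = [&](long long i, long long j, long long k) -> long long {
    return choose3(n) - choose3(n - i) + choose2(n - i - 1) - choose2(n - j) +
           (k - j - 1);
  };
  // enumerate simplices: (value, dim, rank)
  struct Cell { double v; int d; long long r; };
  std::vector<Cell> cells;
  for (int i = 0; i < n; ++i) cells.push_back(Cell{0.0, 0, i});
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = dist(i, j);
      if (v <= threshold) cells.push_back(Cell{v, 1, rank2(i, j)});
    }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double v = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (v <= threshold) cells.push_back(Cell{v, 2, rank3(i, j, k)});
      }
    }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double dijk = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (dijk > threshold) continue;
        for (int l = k + 1; l < n; ++l) {
          double v = std::max(dijk, std::max(dist(i, l),
                       std::max(dist(j, l), dist(k, l))));
          if (v <= threshold)
            cells.push_back(Cell{v, 3,
              ((rank3(i, j, k) * n) + l)});  // rank used only as tie-break
        }
      }
    }
  std::stable_sort(cells.begin(), cells.end(), [](const Cell& a, const Cell& b) {
    if (a.v != b.v) return a.v < b.v;
    if (a.d != b.d) return a.d < b.d;
    return a.r < b.r;
  });
  const int m = (int) cells.size();
  std::vector<int> vert_pos(n, -1);
  std::vector<int> edge_pos(choose2(n), -1);
  std::vector<int> tri_pos(choose3(n), -1);
  for (int p = 0; p < m; ++p) {
    if (cells[p].d == 0) vert_pos[cells[p].r] = p;
    else if (cells[p].d == 1) edge_pos[cells[p].r] = p;
    else if (cells[p].d == 2) tri_pos[cells[p].r] = p;
  }
  // recover vertex indices from ranks for boundary construction
  std::vector<std::vector<int> > boundary(m);
  std::vector<int> dim(m);
  std::vector<double> value(m);
  // invert rank2/rank3 by re-enumeration (cheap, same loops)
  std::vector<std::array<int, 2> > edge_of(choose2(n));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) edge_of[rank2(i, j)] = {i, j};
  std::vector<std::array<int, 3> > tri_of(choose3(n));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k = j + 1; k < n; ++k) tri_of[rank3(i, j, k)] = {i, j, k};
  for (int p = 0; p < m; ++p) {
    dim[p] = cells[p].d;
    value[p] = cells[p].v;
    std::vector<int>& bd = boundary[p];
    if (cells[p].d == 1) {
      std::array<int, 2> e = edge_of[cells[p].r];
      bd.push_back(vert_pos[e[0]]);
      bd.push_back(vert_pos[e[1]]);
    } else if (cells[p].d == 2) {
      std::array<int, 3> t = tri_of[cells[p].r];
      bd.push_back(edge_pos[rank2(t[0], t[1])]);
      bd.push_back(edge_pos[rank2(t[0], t[2])]);
      bd.push_back(edge_pos[rank2(t[1], t[2])]);
    } else if (cells[p].d == 3) {
      long long r3 = cells[p].r / n;
      int l = (int)(cells[p].r % n);
      std::array<int, 3> t = tri_of[r3];
      bd.push_back(tri_pos[rank3(t[0], t[1], t[2])]);
      bd.push_back(tri_pos[rank3(t[0], t[1], l)]);
      bd.push_back(tri_pos[rank3(t[0], t[2], l)]);
      bd.push_back(tri_pos[rank3(t[1], t[2], l)]);
    }
    std::sort(bd.begin(), bd.end());
  }
  ReductionResult res = twist_reduce(boundary, dim, 3);
  return pack_pairs(res, value, dim);
}

// ---------------------------------------------------------------------------
// 6-connected component labeling of a binary 3D grid (breadth-first search).

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector v, IntegerVector shape) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const long long n = (long long) nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long long> stack;
  int next = 0;
  const long long strides[3] = {1, nx, (long long) nx * ny};
  for (long long s = 0; s < n; ++s) {
    if (!v[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long long cur = stack.back();
      stack.pop_back();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((long long) nx * ny));
      const int coord[3] = {cx, cy, cz};
      const int lim[3] = {nx, ny, nz};
      for (int a = 0; a < 3; ++a) {
        for (int d = -1; d <= 1; d += 2) {
          int c = coord[a] + d;
          if (c < 0 || c >= lim[a]) continue;
          long long nb = cur + d * strides[a];
          if (v[nb] && lab[nb] == 0) {
            lab[nb] = next;
            stack.push_back(nb);
          }
        }
      }
    }
  }
  lab.attr("dim") = shape;
  return lab;
}

// ---------------------------------------------------------------------------
// Farthest-point subsampling: greedily add the point maximizing the minimum
// distance to the selected set (ties to the lowest index). Returns 1-based
// indices; deterministic given the start index.

// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int m, int start) {
  const int n = pts.nrow();
  if (m >= n) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  std::vector<double> mind(n, R_PosInf);
  IntegerVector sel(m);
  int cur = start - 1;
  sel[0] = cur + 1;
  for (int step = 1; step < m; ++step) {
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < pts.ncol(); ++c) {
        double d = pts(i, c) - pts(cur, c);
        s += d * d;
      }
      double dd = std::sqrt(s);
      if (dd < mind[i]) mind[i] = dd;
      if (mind[i] > bestd) { bestd = mind[i]; best = i; }
    }
    cur = best;
    sel[step] = cur + 1;
  }
  return sel;
}
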