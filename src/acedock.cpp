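#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lattice points are addressed as origin + spacing * (i, j, k), 0-based.
// Labels: 0 = empty, 1 = surface, 2 = interior.

static inline long long packKey(int x, int y, int z) {
  // coordinates are small (|.| < 2^20) for any realistic structure
  const long long off = 1LL << 20;
  return ((x + off) << 42) | ((y + off) << 21) | (z + off);
}

// Label every lattice point of the grid (origin, dims, spacing):
// protein iff within `radius` (inclusive) of any atom; protein points with all
// six axis neighbours protein are interior, the rest surface; points outside
// the box count as empty neighbours.
// [[Rcpp::export]]
IntegerVector cpp_label_grid(NumericMatrix coords, NumericVector origin,
                             IntegerVector dims, double spacing, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int npt = nx * ny * nz;
  std::vector<char> protein(npt, 0);
  const double r2 = radius * radius;
  const int reach = (int)std::floor(radius / spacing + 1e-9);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    // lattice index window around the atom
    int i0 = (int)std::ceil((ax - radius - origin[0]) / spacing - 1e-9);
    int i1 = (int)std::floor((ax + radius - origin[0]) / spacing + 1e-9);
    int j0 = (int)std::ceil((ay - radius - origin[1]) / spacing - 1e-9);
    int j1 = (int)std::floor((ay + radius - origin[1]) / spacing + 1e-9);
    int k0 = (int)std::ceil((az - radius - origin[2]) / spacing - 1e-9);
    int k1 = (int)std::floor((az + radius - origin[2]) / spacing + 1e-9);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    (void)reach;
    for (int i = i0; i <= i1; ++i) {
      const double dx = origin[0] + spacing * i - ax;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + spacing * j - ay;
        const double dxy2 = dx * dx + dy * dy;
        if (dxy2 > r2 + 1e-9) continue;
        for (int k = k0; k <= k1; ++k) {
          const double dz = origin[2] + spacing * k - az;
          if (dxy2 + dz * dz <= r2 + 1e-9)
            protein[(i * ny + j) * nz + k] = 1;
        }
      }
    }
  }
  IntegerVector labels(npt);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        const int idx = (i * ny + j) * nz + k;
        if (!protein[idx]) { labels[idx] = 0; continue; }
        bool interior =
          i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1 &&
          protein[((i - 1) * ny + j) * nz + k] && protein[((i + 1) * ny + j) * nz + k] &&
          protein[(i * ny + (j - 1)) * nz + k] && protein[(i * ny + (j + 1)) * nz + k] &&
          protein[(i * ny + j) * nz + (k - 1)] && protein[(i * ny + j) * nz + (k + 1)];
        labels[idx] = interior ? 2 : 1;
      }
  return labels;
}

// Interior lattice points of a structure on the unit integer lattice
// (spacing 1), as absolute integer coordinates. The box is the atom bounding
// box padded by radius + 1 so no protein point touches the box face.
// [[Rcpp::export]]
IntegerMatrix cpp_interior_points(NumericMatrix coords, double radius) {
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int a = 0; a < coords.nrow(); ++a)
    for (int d = 0; d < 3; ++d) {
      if (coords(a, d) < mn[d]) mn[d] = coords(a, d);
      if (coords(a, d) > mx[d]) mx[d] = coords(a, d);
    }
  const int margin = (int)std::ceil(radius) + 1;
  int o[3], dims[3];
  for (int d = 0; d < 3; ++d) {
    o[d] = (int)std::floor(mn[d]) - margin;
    dims[d] = (int)std::ceil(mx[d]) + margin - o[d] + 1;
  }
  NumericVector org = NumericVector::create(o[0], o[1], o[2]);
  IntegerVector dm = IntegerVector::create(dims[0], dims[1], dims[2]);
  IntegerVector lab = cpp_label_grid(coords, org, dm, 1.0, radius);
  std::vector<int> pts;
  for (int i = 0; i < dims[0]; ++i)
    for (int j = 0; j < dims[1]; ++j)
      for (int k = 0; k < dims[2]; ++k)
        if (lab[(i * dims[1] + j) * dims[2] + k] == 2) {
          pts.push_back(o[0] + i); pts.push_back(o[1] + j); pts.push_back(o[2] + k);
        }
  const int n = (int)pts.size() / 3;
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    out(r, 0) = pts[3 * r]; out(r, 1) = pts[3 * r + 1]; out(r, 2) = pts[3 * r + 2];
  }
  return out;
}

// ---- cell-list contact search ------------------------------------------

struct CellList {
  double cell;
  double org[3];
  int dims[3];
  std::vector<std::vector<int>> bins;
  void build(const NumericMatrix& c, double cutoff) {
    cell = cutoff;
    for (int d = 0; d < 3; ++d) { org[d] = R_PosInf; }
    double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int a = 0; a < c.nrow(); ++a)
      for (int d = 0; d < 3; ++d) {
        if (c(a, d) < org[d]) org[d] = c(a, d);
        if (c(a, d) > mx[d]) mx[d] = c(a, d);
      }
    for (int d = 0; d < 3; ++d)
      dims[d] = std::max(1, (int)std::floor((mx[d] - org[d]) / cell) + 1);
    bins.assign((size_t)dims[0] * dims[1] * dims[2], {});
    for (int a = 0; a < c.nrow(); ++a) {
      int ix = std::min(dims[0] - 1, (int)std::floor((c(a, 0) - org[0]) / cell));
      int iy = std::min(dims[1] - 1, (int)std::floor((c(a, 1) - org[1]) / cell));
      int iz = std::min(dims[2] - 1, (int)std::floor((c(a, 2) - org[2]) / cell));
      bins[((size_t)ix * dims[1] + iy) * dims[2] + iz].push_back(a);
    }
  }
  template <class F>
  void neighbours(double x, double y, double z, F&& f) const {
    int ix = (int)std::floor((x - org[0]) / cell);
    int iy = (int)std::floor((y - org[1]) / cell);
    int iz = (int)std::floor((z - org[2]) / cell);
    for (int dx = -1; dx <= 1; ++dx) {
      int jx = ix + dx; if (jx < 0 || jx >= dims[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy; if (jy < 0 || jy >= dims[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int jz = iz + dz; if (jz < 0 || jz >= dims[2]) continue;
          for (int b : bins[((size_t)jx * dims[1] + jy) * dims[2] + jz]) f(b);
        }
      }
    }
  }
};

// All cross pairs (i from c1, j from c2) with Euclidean distance <= cutoff,
// ordered by (i, j). Cell-list accelerated; agrees exactly with the
// quadratic double loop.
// [[Rcpp::export]]
List cpp_contacts(NumericMatrix c1, NumericMatrix c2, double cutoff) {
  CellList cl; cl.build(c2, cutoff);
  const double cut2 = cutoff * cutoff;
  std::vector<int> ii, jj; std::vector<double> dd;
  for (int a = 0; a < c1.nrow(); ++a) {
    const double x = c1(a, 0), y = c1(a, 1), z = c1(a, 2);
    std::vector<int> hits;
    cl.neighbours(x, y, z, [&](int b) {
      const double dx = c2(b, 0) - x, dy = c2(b, 1) - y, dz = c2(b, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= cut2) hits.push_back(b);
    });
    std::sort(hits.begin(), hits.end());
    for (int b : hits) {
      const double dx = c2(b, 0) - x, dy = c2(b, 1) - y, dz = c2(b, 2) - z;
      ii.push_back(a + 1); jj.push_back(b + 1);
      dd.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["dist"] = wrap(dd));
}

// ACE score: sum of table[t1, t2] over cross pairs within cutoff; untyped
// atoms (type < 0) contribute nothing.
// [[Rcpp::export]]
double cpp_ace_score(NumericMatrix c1, IntegerVector t1,
                     NumericMatrix c2, IntegerVector t2,
                     NumericMatrix table, double cutoff) {
  if (c1.nrow() == 0 || c2.nrow() == 0) return 0.0;
  CellList cl; cl.build(c2, cutoff);
  const double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int a = 0; a < c1.nrow(); ++a) {
    if (t1[a] < 0) continue;
    const double x = c1(a, 0), y = c1(a, 1), z = c1(a, 2);
    cl.neighbours(x, y, z, [&](int b) {
      if (t2[b] < 0) return;
      const double dx = c2(b, 0) - x, dy = c2(b, 1) - y, dz = c2(b, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= cut2) e += table(t1[a], t2[b]);
    });
  }
  return e;
}

// ---- minimising Smith-Waterman with best-first masked extraction --------

// H(p,q) = min(0, H(p-1,q-1)+T[ta_p,tb_q], H(p-1,q)+gap, H(p,q-1)+gap),
// cells on used rows/columns forced to 0. Repeatedly extract the most
// negative segment (ties: smallest (p, q)), mask its rows and columns, stop
// when the best remaining score > x. Traceback prefers diagonal, then the
// A-gap (up), then the B-gap (left) move. Columns: (A index | 0, B index | 0).
// [[Rcpp::export]]
List cpp_sw_extract(IntegerVector ta, IntegerVector tb, NumericMatrix table,
                    double gap, double x) {
  const int n = ta.size(), m = tb.size();
  std::vector<char> usedA(n + 1, 0), usedB(m + 1, 0);
  std::vector<double> H((size_t)(n + 1) * (m + 1));
  auto at = [&](int p, int q) -> double& { return H[(size_t)p * (m + 1) + q]; };
  List out;
  const double INF = R_PosInf;
  for (int iter = 0; iter < n + m + 2; ++iter) {
    // fill
    for (int q = 0; q <= m; ++q) at(0, q) = 0.0;
    for (int p = 1; p <= n; ++p) {
      at(p, 0) = 0.0;
      for (int q = 1; q <= m; ++q) {
        if (usedA[p] || usedB[q]) { at(p, q) = 0.0; continue; }
        double best = 0.0;
        const double diag = (ta[p - 1] >= 0 && tb[q - 1] >= 0)
          ? at(p - 1, q - 1) + table(ta[p - 1], tb[q - 1]) : INF;
        if (diag < best) best = diag;
        const double up = at(p - 1, q) + gap;
        if (up < best) best = up;
        const double left = at(p, q - 1) + gap;
        if (left < best) best = left;
        at(p, q) = best;
      }
    }
    // best cell, ties to smallest (p, q)
    double bestVal = 0.0; int bp = -1, bq = -1;
    for (int p = 1; p <= n; ++p)
      for (int q = 1; q <= m; ++q)
        if (at(p, q) < bestVal - 1e-12) { bestVal = at(p, q); bp = p; bq = q; }
    if (bp < 0 || bestVal > x) break;
    // traceback
    std::vector<std::pair<int, int>> cols;
    int p = bp, q = bq;
    while (p > 0 && q > 0 && at(p, q) < -1e-12 && !usedA[p] && !usedB[q]) {
      const double h = at(p, q);
      const double diag = (ta[p - 1] >= 0 && tb[q - 1] >= 0)
        ? at(p - 1, q - 1) + table(ta[p - 1], tb[q - 1]) : INF;
      if (std::abs(diag - h) < 1e-9) { cols.push_back({p, q}); --p; --q; continue; }
      if (std::abs(at(p - 1, q) + gap - h) < 1e-9) { cols.push_back({p, 0}); --p; continue; }
      if (std::abs(at(p, q - 1) + gap - h) < 1e-9) { cols.push_back({0, q}); --q; continue; }
      break;  // numerical dead end; should not happen
    }
    std::reverse(cols.begin(), cols.end());
    if (cols.empty()) break;
    IntegerMatrix cm((int)cols.size(), 2);
    for (int r = 0; r < (int)cols.size(); ++r) {
      cm(r, 0) = cols[r].first; cm(r, 1) = cols[r].second;
      if (cols[r].first > 0) usedA[cols[r].first] = 1;
      if (cols[r].second > 0) usedB[cols[r].second] = 1;
    }
    out.push_back(List::create(_["columns"] = cm, _["score"] = bestVal));
  }
  return out;
}

// ---- pose scan ----------------------------------------------------------

static inline void rodrigues(const double u[3], double ang, double R[9]) {
  const double c = std::cos(ang), s = std::sin(ang), t = 1.0 - c;
  R[0] = c + u[0] * u[0] * t;        R[1] = u[0] * u[1] * t - u[2] * s; R[2] = u[0] * u[2] * t + u[1] * s;
  R[3] = u[1] * u[0] * t + u[2] * s; R[4] = c + u[1] * u[1] * t;        R[5] = u[1] * u[2] * t - u[0] * s;
  R[6] = u[2] * u[0] * t - u[1] * s; R[7] = u[2] * u[1] * t + u[0] * s; R[8] = c + u[2] * u[2] * t;
}

// Scan all candidate poses for one anchor combination. For anchor placement
// i (row of P/Q, with precomputed base transform R0/t0 mapping a_i -> p and
// the a_i->a_j direction onto p->q) and rotation k about the p->q axis, the
// posed coordinates are x' = Rk (R0 x + t0 - p) + p. The clash test counts
// the posed A's interior points on the unit integer lattice against the
// fixed B's cached interior set (Bint, XB precomputed); ACE is evaluated for
// clash-free poses only, over the selected score atoms.
// Returns one row per pose: [pair, rot, clash, X, XA, ace].
// [[Rcpp::export]]
NumericMatrix cpp_pose_scan(NumericMatrix Acoords,
                            NumericMatrix baseRot, NumericMatrix baseTrans,
                            NumericMatrix P, NumericMatrix Q,
                            int nrot, double stepDeg,
                            IntegerMatrix Bint, double theta, double radius,
                            IntegerVector scoreA, IntegerVector typesA,
                            NumericMatrix Bscore, IntegerVector typesB,
                            NumericMatrix table, double cutoff) {
  const int nA = Acoords.nrow(), npair = P.nrow();
  const int XB = Bint.nrow();
  std::unordered_set<long long> bset;
  bset.reserve((size_t)XB * 2 + 1);
  for (int r = 0; r < XB; ++r) bset.insert(packKey(Bint(r, 0), Bint(r, 1), Bint(r, 2)));
  CellList cl;
  const bool haveB = Bscore.nrow() > 0;
  if (haveB) cl.build(Bscore, cutoff);
  const double cut2 = cutoff * cutoff;

  NumericMatrix out((size_t)npair * nrot, 6);
  std::vector<double> px(nA), py(nA), pz(nA);   // after base transform
  std::vector<double> qx(nA), qy(nA), qz(nA);   // after rotation
  int row = 0;
  for (int i = 0; i < npair; ++i) {
    const double p0 = P(i, 0), p1 = P(i, 1), p2 = P(i, 2);
    double u[3] = {Q(i, 0) - p0, Q(i, 1) - p1, Q(i, 2) - p2};
    const double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    u[0] /= un; u[1] /= un; u[2] /= un;
    for (int a = 0; a < nA; ++a) {
      const double x = Acoords(a, 0), y = Acoords(a, 1), z = Acoords(a, 2);
      px[a] = baseRot(i, 0) * x + baseRot(i, 1) * y + baseRot(i, 2) * z + baseTrans(i, 0) - p0;
      py[a] = baseRot(i, 3) * x + baseRot(i, 4) * y + baseRot(i, 5) * z + baseTrans(i, 1) - p1;
      pz[a] = baseRot(i, 6) * x + baseRot(i, 7) * y + baseRot(i, 8) * z + baseTrans(i, 2) - p2;
    }
    for (int k = 0; k < nrot; ++k) {
      double R[9];
      rodrigues(u, k * stepDeg * M_PI / 180.0, R);
      double mn[3] = {R_PosInf, R_PosInf, R_PosInf}, mx[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int a = 0; a < nA; ++a) {
        qx[a] = R[0] * px[a] + R[1] * py[a] + R[2] * pz[a] + p0;
        qy[a] = R[3] * px[a] + R[4] * py[a] + R[5] * pz[a] + p1;
        qz[a] = R[6] * px[a] + R[7] * py[a] + R[8] * pz[a] + p2;
        if (qx[a] < mn[0]) mn[0] = qx[a]; if (qx[a] > mx[0]) mx[0] = qx[a];
        if (qy[a] < mn[1]) mn[1] = qy[a]; if (qy[a] > mx[1]) mx[1] = qy[a];
        if (qz[a] < mn[2]) mn[2] = qz[a]; if (qz[a] > mx[2]) mx[2] = qz[a];
      }
      // interior points of posed A on the unit lattice
      const int margin = (int)std::ceil(radius) + 1;
      int o[3], dims[3];
      for (int d = 0; d < 3; ++d) {
        o[d] = (int)std::floor(mn[d]) - margin;
        dims[d] = (int)std::ceil(mx[d]) + margin - o[d] + 1;
      }
      const int ny = dims[1], nz = dims[2];
      std::vector<char> prot((size_t)dims[0] * ny * nz, 0);
      const double r2 = radius * radius;
      for (int a = 0; a < nA; ++a) {
        int i0 = (int)std::ceil(qx[a] - radius - o[0] - 1e-9);
        int i1 = (int)std::floor(qx[a] + radius - o[0] + 1e-9);
        int j0 = (int)std::ceil(qy[a] - radius - o[1] - 1e-9);
        int j1 = (int)std::floor(qy[a] + radius - o[1] + 1e-9);
        int k0 = (int)std::ceil(qz[a] - radius - o[2] - 1e-9);
        int k1 = (int)std::floor(qz[a] + radius - o[2] + 1e-9);
        for (int ii = i0; ii <= i1; ++ii) {
          const double dx = o[0] + ii - qx[a];
          for (int jj = j0; jj <= j1; ++jj) {
            const double dy = o[1] + jj - qy[a];
            const double d2 = dx * dx + dy * dy;
            if (d2 > r2 + 1e-9) continue;
            for (int kk = k0; kk <= k1; ++kk) {
              const double dz = o[2] + kk - qz[a];
              if (d2 + dz * dz <= r2 + 1e-9)
                prot[((size_t)ii * ny + jj) * nz + kk] = 1;
            }
          }
        }
      }
      int XA = 0, X = 0;
      for (int ii = 1; ii < dims[0] - 1; ++ii)
        for (int jj = 1; jj < ny - 1; ++jj)
          for (int kk = 1; kk < nz - 1; ++kk) {
            const size_t idx = ((size_t)ii * ny + jj) * nz + kk;
            if (!prot[idx]) continue;
            if (prot[idx - (size_t)ny * nz] && prot[idx + (size_t)ny * nz] &&
                prot[idx - nz] && prot[idx + nz] && prot[idx - 1] && prot[idx + 1]) {
              ++XA;
              if (bset.count(packKey(o[0] + ii, o[1] + jj, o[2] + kk))) ++X;
            }
          }
      const int mint = std::min(XA, XB);
      const bool clash = X > theta * mint;
      double ace = NA_REAL;
      if (!clash && haveB) {
        ace = 0.0;
        for (int s = 0; s < scoreA.size(); ++s) {
          const int a = scoreA[s] - 1;
          if (typesA[a] < 0) continue;
          const double x = qx[a], y = qy[a], z = qz[a];
          cl.neighbours(x, y, z, [&](int b) {
            if (typesB[b] < 0) return;
            const double dx = Bscore(b, 0) - x, dy = Bscore(b, 1) - y, dz = Bscore(b, 2) - z;
            if (dx * dx + dy * dy + dz * dz <= cut2) ace += table(typesA[a], typesB[b]);
          });
        }
      }
      out(row, 0) = i + 1; out(row, 1) = k; out(row, 2) = clash ? 1 : 0;
      out(row, 3) = X; out(row, 4) = XA; out(row, 5) = ace;
      ++row;
    }
  }
  return out;
}
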