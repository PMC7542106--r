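#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <unordered_set>
#include <vector>

#include "geometry.h"
#include "xoshiro.h"

using namespace Rcpp;

// Block fields are integer arrays of dims (nx+2, ny+2, nz+2): interior at
// local array coordinates 1..n, one-voxel halo at 0 and n+1.  The global
// 0-based coordinate of local (i,j,k) is (ox+i-1, oy+j-1, oz+k-1).
// Checkerboard colors are computed from global coordinates so the coloring
// is consistent across block boundaries.

namespace {

const int D6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};

struct Ctx {
  int* F;
  int mx, my, mz;        // array dims (interior + 2)
  int nx, ny, nz;        // interior dims
  int ox, oy, oz;        // global offset of interior
  std::unordered_map<int, int> slot;  // cellID -> index into per-cell vectors
  const int* type;                    // per cell: type index (0-based)
  const double *v, *s, *v0, *s0;      // per cell committed state / targets
  const double *lamv, *lams;          // per type
  const double* A;                    // ntype x ntype adhesion, column-major
  int ntype;
  const int *solid, *liquid;          // per type flags
  int wall, metric;                   // metric: 0 side counting, 1 marching
  double T;
};

inline int& fat(Ctx& c, int i, int j, int k) {
  return c.F[i + c.mx * (j + c.my * k)];
}

inline int slot_of(Ctx& c, int id) {
  std::unordered_map<int, int>::const_iterator it = c.slot.find(id);
  if (it == c.slot.end()) stop("internal consistency error: cellID %d has no record in this block", id);
  return it->second;
}

struct Delta {
  double dE, dE_vol, dE_surf, dE_adh;
  double ds_old, ds_new;  // surface change under the configured metric
  bool valid;
};

// Marching-cubes surface change of `cell` when the center voxel of the
// 3x3x3 neighborhood nb flips to newid.  nb is indexed (dx+1)+3*((dy+1)+3*(dz+1)).
double march_ds(const int* nb, int cell, int newid, const mcgeom::Tables& t) {
  double d = 0.0;
  for (int cz = 0; cz < 2; ++cz)
    for (int cy = 0; cy < 2; ++cy)
      for (int cx = 0; cx < 2; ++cx) {
        int cfg0 = 0, cfg1 = 0;
        for (int c = 0; c < 8; ++c) {
          int vx = cx - 1 + (c & 1), vy = cy - 1 + ((c >> 1) & 1), vz = cz - 1 + ((c >> 2) & 1);
          bool ctr = (vx == 0 && vy == 0 && vz == 0);
          int idv = nb[(vx + 1) + 3 * ((vy + 1) + 3 * (vz + 1))];
          if (idv == cell) cfg0 |= (1 << c);
          if (ctr ? (newid == cell) : (idv == cell)) cfg1 |= (1 << c);
        }
        d += t.area3[cfg1] - t.area3[cfg0];
      }
  return d;
}

// Energy difference of copying `newid` onto interior voxel (i,j,k).
Delta eval_attempt(Ctx& c, int i, int j, int k, int newid) {
  Delta r;
  r.dE = r.dE_vol = r.dE_surf = r.dE_adh = r.ds_old = r.ds_new = 0.0;
  r.valid = false;
  int old = fat(c, i, j, k);
  if (old == newid || old == c.wall || newid == c.wall) return r;
  int so = slot_of(c, old), sn = slot_of(c, newid);
  int told = c.type[so], tnew = c.type[sn];
  if (c.solid[told] || c.solid[tnew]) return r;

  int nb[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[(dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1))] = fat(c, i + dx, j + dy, k + dz);

  // side-counting surface deltas from the six faces
  int n_old = 0, n_new = 0, n_wall = 0;
  for (int a = 0; a < 6; ++a) {
    int q = (D6[a][0] + 1) + 3 * ((D6[a][1] + 1) + 3 * (D6[a][2] + 1));
    int idv = nb[q];
    if (idv == c.wall) { ++n_wall; continue; }
    if (idv == old) ++n_old;
    if (idv == newid) ++n_new;
  }
  double ds_old_side = (double)n_old - (6 - n_wall - n_old);
  double ds_new_side = (double)(6 - n_wall - n_new) - n_new;

  const mcgeom::Tables& t = mcgeom::tables();
  double ds_old_m = 0.0, ds_new_m = 0.0;
  if (c.metric == 1) {
    ds_old_m = march_ds(nb, old, newid, t);
    ds_new_m = march_ds(nb, newid, newid, t);
  }
  r.ds_old = (c.metric == 1) ? ds_old_m : ds_old_side;
  r.ds_new = (c.metric == 1) ? ds_new_m : ds_new_side;

  // adhesion: exact face bookkeeping under side counting; under the marching
  // metric the pairwise side-count change is scaled by the local ratio of
  // marching to side-count boundary change (documented approximation)
  double dea = 0.0;
  for (int a = 0; a < 6; ++a) {
    int q = (D6[a][0] + 1) + 3 * ((D6[a][1] + 1) + 3 * (D6[a][2] + 1));
    int idv = nb[q];
    if (idv == c.wall) continue;
    int tn = c.type[slot_of(c, idv)];
    if (idv != newid) dea += c.A[tnew + c.ntype * tn];
    if (idv != old) dea -= c.A[told + c.ntype * tn];
  }
  if (c.metric == 1) {
    double denom = std::fabs(ds_old_side) + std::fabs(ds_new_side);
    double numer = std::fabs(ds_old_m) + std::fabs(ds_new_m);
    dea *= (denom > 0.0) ? (numer / denom) : 1.0;
  }

  double dev = 0.0, des = 0.0;
  if (!c.liquid[told] && !c.solid[told]) {
    double vv = c.v[so], tv = c.v0[so];
    dev += c.lamv[told] * ((vv - 1 - tv) * (vv - 1 - tv) - (vv - tv) * (vv - tv));
    double ss = c.s[so], ts = c.s0[so];
    des += c.lams[told] * ((ss + r.ds_old - ts) * (ss + r.ds_old - ts) - (ss - ts) * (ss - ts));
  }
  if (!c.liquid[tnew] && !c.solid[tnew]) {
    double vv = c.v[sn], tv = c.v0[sn];
    dev += c.lamv[tnew] * ((vv + 1 - tv) * (vv + 1 - tv) - (vv - tv) * (vv - tv));
    double ss = c.s[sn], ts = c.s0[sn];
    des += c.lams[tnew] * ((ss + r.ds_new - ts) * (ss + r.ds_new - ts) - (ss - ts) * (ss - ts));
  }

  r.dE_vol = dev;
  r.dE_surf = des;
  r.dE_adh = dea;
  r.dE = dev + des + dea;
  r.valid = true;
  return r;
}

// First selected index of the visitor walk: stationary-delay (renewal)
// distribution P(k) proportional to (2m-1-k), k = 0..2m-2, which makes every
// index selected with probability exactly 1/m.
long long stationary_delay(bcrng::Stream& g, int m) {
  if (m <= 1) return 0;
  int M = 2 * m - 1;
  double u = bcrng::runif01(g) * ((double)m * M);
  double cum = 0.0;
  for (int k = 0; k < M; ++k) {
    cum += (double)(M - k);
    if (u < cum) return k;
  }
  return M - 1;
}

struct SweepOut {
  double attempts, accepts;
};

SweepOut sweep_block(Ctx& c, bcrng::Stream& g, int color, int n_colors, int stencil,
                     int mean_step, double* dv, double* ds, double* dcx, double* dcy,
                     double* dcz) {
  SweepOut out;
  out.attempts = out.accepts = 0.0;

  // enumerate the active color class of the interior, ordered by the linear
  // array index (x fastest)
  std::vector<int> xs, ys, zs;       // 8-color factorised coordinates
  std::vector<long long> explicit_idx;  // fallback for the 2-color scheme
  long long n_active = 0;
  bool factorised = false;
  if (n_colors == 8) {
    int px = color & 1, py = (color >> 1) & 1, pz = (color >> 2) & 1;
    for (int i = 1; i <= c.nx; ++i)
      if (((c.ox + i - 1) & 1) == px) xs.push_back(i);
    for (int j = 1; j <= c.ny; ++j)
      if (((c.oy + j - 1) & 1) == py) ys.push_back(j);
    for (int k = 1; k <= c.nz; ++k)
      if (((c.oz + k - 1) & 1) == pz) zs.push_back(k);
    n_active = (long long)xs.size() * ys.size() * zs.size();
    factorised = true;
  } else {
    for (int k = 1; k <= c.nz; ++k)
      for (int j = 1; j <= c.ny; ++j)
        for (int i = 1; i <= c.nx; ++i) {
          int par = ((c.ox + i - 1) + (c.oy + j - 1) + (c.oz + k - 1)) & 1;
          if (par == color) explicit_idx.push_back(((long long)k << 40) | ((long long)j << 20) | i);
        }
    n_active = explicit_idx.size();
  }
  if (n_active == 0) return out;

  int ndirs = (stencil == 27) ? 26 : 6;
  int M = 2 * mean_step - 1;

  long long pos = stationary_delay(g, mean_step);
  while (pos < n_active) {
    int i, j, k;
    if (factorised) {
      long long cx = (long long)xs.size(), cy = (long long)ys.size();
      i = xs[pos % cx];
      j = ys[(pos / cx) % cy];
      k = zs[pos / (cx * cy)];
    } else {
      long long enc = explicit_idx[pos];
      i = (int)(enc & 0xFFFFF);
      j = (int)((enc >> 20) & 0xFFFFF);
      k = (int)(enc >> 40);
    }

    // pick a source neighbor uniformly from the stencil
    int d = bcrng::runif_int(g, ndirs);
    int dx, dy, dz;
    if (stencil == 27) {
      int e = d >= 13 ? d + 1 : d;  // skip the center of the 3x3x3 cube
      dx = e % 3 - 1;
      dy = (e / 3) % 3 - 1;
      dz = e / 9 - 1;
    } else {
      dx = D6[d][0];
      dy = D6[d][1];
      dz = D6[d][2];
    }
    int newid = fat(c, i + dx, j + dy, k + dz);
    int old = fat(c, i, j, k);
    bool consider = !(newid == old || newid == c.wall || old == c.wall);
    if (consider) {
      Delta r = eval_attempt(c, i, j, k, newid);
      if (r.valid) {
        out.attempts += 1;
        bool acc = (r.dE <= 0.0) || (bcrng::runif01(g) < std::exp(-r.dE / c.T));
        if (acc) {
          out.accepts += 1;
          fat(c, i, j, k) = newid;
          int so = slot_of(c, old), sn = slot_of(c, newid);
          dv[so] -= 1;
          dv[sn] += 1;
          ds[so] += r.ds_old;
          ds[sn] += r.ds_new;
          double gx = c.ox + i - 1, gy = c.oy + j - 1, gz = c.oz + k - 1;
          dcx[so] -= gx; dcy[so] -= gy; dcz[so] -= gz;
          dcx[sn] += gx; dcy[sn] += gy; dcz[sn] += gz;
        }
      }
    }
    pos += 1 + bcrng::runif_int(g, M);
  }
  return out;
}

Ctx make_ctx(IntegerVector field, IntegerVector interior, IntegerVector origin,
             IntegerVector ids, IntegerVector type, NumericVector v, NumericVector s,
             NumericVector v0, NumericVector s0, NumericVector lamv, NumericVector lams,
             NumericMatrix A, IntegerVector type_solid, IntegerVector type_liquid,
             int wall_id, int metric, double temperature) {
  Ctx c;
  c.F = INTEGER(field);
  c.nx = interior[0];
  c.ny = interior[1];
  c.nz = interior[2];
  c.mx = c.nx + 2;
  c.my = c.ny + 2;
  c.mz = c.nz + 2;
  c.ox = origin[0];
  c.oy = origin[1];
  c.oz = origin[2];
  for (int q = 0; q < ids.size(); ++q) c.slot[ids[q]] = q;
  c.type = INTEGER(type);
  c.v = REAL(v);
  c.s = REAL(s);
  c.v0 = REAL(v0);
  c.s0 = REAL(s0);
  c.lamv = REAL(lamv);
  c.lams = REAL(lams);
  c.A = REAL(A);
  c.ntype = A.nrow();
  c.solid = INTEGER(type_solid);
  c.liquid = INTEGER(type_liquid);
  c.wall = wall_id;
  c.metric = metric;
  c.T = temperature;
  return c;
}

void halo_sync_impl(List fields, IntegerVector interior, IntegerVector grid, int wall_id) {
  int nx = interior[0], ny = interior[1], nz = interior[2];
  int mx = nx + 2, my = ny + 2, mz = nz + 2;
  int gx = grid[0], gy = grid[1], gz = grid[2];
  std::vector<int*> F(fields.size());
  for (int b = 0; b < fields.size(); ++b) F[b] = INTEGER((SEXP)fields[b]);
  for (int bk = 0; bk < gz; ++bk)
    for (int bj = 0; bj < gy; ++bj)
      for (int bi = 0; bi < gx; ++bi) {
        int b = bi + gx * (bj + gy * bk);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int ni = bi + dx, nj = bj + dy, nk = bk + dz;
              bool outside = ni < 0 || nj < 0 || nk < 0 || ni >= gx || nj >= gy || nk >= gz;
              int nb = outside ? -1 : ni + gx * (nj + gy * nk);
              int i0 = dx == -1 ? 0 : (dx == 1 ? mx - 1 : 1);
              int i1 = dx == 0 ? nx : i0;
              if (dx == 0) i0 = 1;
              int j0 = dy == -1 ? 0 : (dy == 1 ? my - 1 : 1);
              int j1 = dy == 0 ? ny : j0;
              if (dy == 0) j0 = 1;
              int k0 = dz == -1 ? 0 : (dz == 1 ? mz - 1 : 1);
              int k1 = dz == 0 ? nz : k0;
              if (dz == 0) k0 = 1;
              for (int k = k0; k <= k1; ++k)
                for (int j = j0; j <= j1; ++j)
                  for (int i = i0; i <= i1; ++i) {
                    int val;
                    if (outside) {
                      val = wall_id;
                    } else {
                      // halo coordinate -> owning neighbor's interior coordinate
                      int si = dx == -1 ? nx : (dx == 1 ? 1 : i);
                      int sj = dy == -1 ? ny : (dy == 1 ? 1 : j);
                      int sk = dz == -1 ? nz : (dz == 1 ? 1 : k);
                      val = F[nb][si + mx * (sj + my * sk)];
                    }
                    F[b][i + mx * (j + my * k)] = val;
                  }
            }
      }
}

inline void add_id(std::vector<int>& v, int x) {
  for (size_t q = 0; q < v.size(); ++q)
    if (v[q] == x) return;
  v.push_back(x);
}

List presence_of(IntegerVector field, IntegerVector interior, int wall_id) {
  int nx = interior[0], ny = interior[1], nz = interior[2];
  int mx = nx + 2, my = ny + 2, mz = nz + 2;
  const int* F = INTEGER(field);
  std::vector<int> in_int, in_halo;
  // distinct-id collection with a run-length shortcut (fields are dominated
  // by long runs of the same id) and linear lookup (few distinct ids)
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j) {
      const int* row = F + mx * (j + my * k);
      bool interior_row = k >= 1 && k <= nz && j >= 1 && j <= ny;
      if (interior_row) {
        int last = wall_id;
        if (row[0] != wall_id) add_id(in_halo, row[0]);
        if (row[mx - 1] != wall_id) add_id(in_halo, row[mx - 1]);
        for (int i = 1; i <= nx; ++i) {
          int v = row[i];
          if (v == last || v == wall_id) { last = v; continue; }
          add_id(in_int, v);
          last = v;
        }
      } else {
        int last = wall_id;
        for (int i = 0; i < mx; ++i) {
          int v = row[i];
          if (v == last || v == wall_id) { last = v; continue; }
          add_id(in_halo, v);
          last = v;
        }
      }
    }
  std::sort(in_int.begin(), in_int.end());
  std::sort(in_halo.begin(), in_halo.end());
  return List::create(Named("interior") = IntegerVector(in_int.begin(), in_int.end()),
                      Named("halo") = IntegerVector(in_halo.begin(), in_halo.end()));
}

}  // namespace

// [[Rcpp::export]]
void cpp_halo_sync(List fields, IntegerVector interior, IntegerVector grid, int wall_id) {
  halo_sync_impl(fields, interior, grid, wall_id);
}

// [[Rcpp::export]]
List cpp_block_presence(IntegerVector field, IntegerVector interior, int wall_id) {
  return presence_of(field, interior, wall_id);
}

// One Monte Carlo sweep of the active color over every block (serial stand-in
// for the concurrent per-rank sweeps), followed optionally by the halo
// exchange and a presence scan.  Fields and RNG states are modified in place.
// [[Rcpp::export]]
List cpp_run_mcs(List fields, IntegerMatrix origins, IntegerVector interior,
                 IntegerVector grid, int n_colors, int color, int stencil, int metric,
                 int mean_step, double temperature, int wall_id, List ids_list,
                 List type_list, List v_list, List s_list, List v0_list, List s0_list,
                 NumericVector lamv, NumericVector lams, NumericMatrix adhesion,
                 IntegerVector type_solid, IntegerVector type_liquid, List rng_states,
                 bool do_halo, bool do_presence) {
  int B = fields.size();
  List res(B);
  for (int b = 0; b < B; ++b) {
    IntegerVector field = fields[b];
    IntegerVector ids = ids_list[b];
    Ctx c = make_ctx(field, interior, origins(b, _), ids, type_list[b], v_list[b],
                     s_list[b], v0_list[b], s0_list[b], lamv, lams, adhesion,
                     type_solid, type_liquid, wall_id, metric, temperature);
    RawVector st = rng_states[b];
    bcrng::Stream g;
    bcrng::load_stream(g, RAW(st));
    int n = ids.size();
    NumericVector dv(n), ds(n), dcx(n), dcy(n), dcz(n);
    SweepOut sw = sweep_block(c, g, color, n_colors, stencil, mean_step, REAL(dv),
                              REAL(ds), REAL(dcx), REAL(dcy), REAL(dcz));
    bcrng::save_stream(g, RAW(st));
    res[b] = List::create(Named("dv") = dv, Named("ds") = ds, Named("dcx") = dcx,
                          Named("dcy") = dcy, Named("dcz") = dcz,
                          Named("attempts") = sw.attempts, Named("accepts") = sw.accepts);
  }
  if (do_halo) halo_sync_impl(fields, interior, grid, wall_id);
  if (do_presence) {
    List pres(B);
    for (int b = 0; b < B; ++b) pres[b] = presence_of(fields[b], interior, wall_id);
    return List::create(Named("deltas") = res, Named("presence") = pres);
  }
  return List::create(Named("deltas") = res);
}

// Energy difference of a single copy attempt on a plain (un-blocked) global
// label field; the array boundary acts as wall.  Voxel is 0-based.
// [[Rcpp::export]]
List cpp_attempt_delta(IntegerVector field, IntegerVector voxel, int new_id,
                       IntegerVector ids, IntegerVector type, NumericVector v,
                       NumericVector s, NumericVector v0, NumericVector s0,
                       NumericVector lamv, NumericVector lams, NumericMatrix adhesion,
                       IntegerVector type_solid, IntegerVector type_liquid, int wall_id,
                       int metric, double temperature) {
  IntegerVector dm = field.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  IntegerVector padded((nx + 2) * (ny + 2) * (nz + 2), wall_id);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        padded[(i + 1) + (nx + 2) * ((j + 1) + (ny + 2) * (k + 1))] =
            field[i + nx * (j + ny * k)];
  IntegerVector interior = IntegerVector::create(nx, ny, nz);
  IntegerVector origin = IntegerVector::create(0, 0, 0);
  Ctx c = make_ctx(padded, interior, origin, ids, type, v, s, v0, s0, lamv, lams,
                   adhesion, type_solid, type_liquid, wall_id, metric, temperature);
  Delta r = eval_attempt(c, voxel[0] + 1, voxel[1] + 1, voxel[2] + 1, new_id);
  return List::create(Named("valid") = r.valid, Named("dE") = r.dE,
                      Named("dE_vol") = r.dE_vol, Named("dE_surf") = r.dE_surf,
                      Named("dE_adh") = r.dE_adh, Named("ds_old") = r.ds_old,
                      Named("ds_new") = r.ds_new);
}

// Force a set of voxel flips on one block with exact delta bookkeeping (used
// by the sanity action, cell deletion and event execution).  rows of voxels:
// local interior coordinates (1..n) plus the new id.
// [[Rcpp::export]]
List cpp_apply_flips(IntegerVector field, IntegerMatrix voxels, IntegerVector origin,
                     IntegerVector interior, IntegerVector ids, IntegerVector type,
                     NumericVector v, NumericVector s, NumericVector v0, NumericVector s0,
                     NumericVector lamv, NumericVector lams, NumericMatrix adhesion,
                     IntegerVector type_solid, IntegerVector type_liquid, int wall_id,
                     int metric) {
  Ctx c = make_ctx(field, interior, origin, ids, type, v, s, v0, s0, lamv, lams,
                   adhesion, type_solid, type_liquid, wall_id, metric, 1.0);
  int n = ids.size();
  NumericVector dv(n), ds(n), dcx(n), dcy(n), dcz(n);
  for (int r = 0; r < voxels.nrow(); ++r) {
    int i = voxels(r, 0), j = voxels(r, 1), k = voxels(r, 2), newid = voxels(r, 3);
    int old = fat(c, i, j, k);
    if (old == newid) continue;
    Delta d = eval_attempt(c, i, j, k, newid);
    if (!d.valid) stop("cannot force flip at (%d,%d,%d)", i, j, k);
    fat(c, i, j, k) = newid;
    int so = slot_of(c, old), sn = slot_of(c, newid);
    dv[so] -= 1;
    dv[sn] += 1;
    ds[so] += d.ds_old;
    ds[sn] += d.ds_new;
    double gx = c.ox + i - 1, gy = c.oy + j - 1, gz = c.oz + k - 1;
    dcx[so] -= gx; dcy[so] -= gy; dcz[so] -= gz;
    dcx[sn] += gx; dcy[sn] += gy; dcz[sn] += gz;
  }
  return List::create(Named("dv") = dv, Named("ds") = ds, Named("dcx") = dcx,
                      Named("dcy") = dcy, Named("dcz") = dcz);
}

// Interior voxels of a block whose 6-neighborhood holds no voxel of the same
// cell (detached single voxels).  Liquid and wall are never candidates.
// Returns a matrix of rows (i, j, k, id) in local interior coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_sanity_candidates(IntegerVector field, IntegerVector interior,
                                    int wall_id) {
  int nx = interior[0], ny = interior[1], nz = interior[2];
  int mx = nx + 2, my = ny + 2;
  const int* F = INTEGER(field);
  std::vector<int> rows;
  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i) {
        int v = F[i + mx * (j + my * k)];
        if (v == 0 || v == wall_id) continue;
        bool attached = false;
        for (int a = 0; a < 6 && !attached; ++a) {
          int q = (i + D6[a][0]) + mx * ((j + D6[a][1]) + my * (k + D6[a][2]));
          if (F[q] == v) attached = true;
        }
        if (!attached) {
          rows.push_back(i);
          rows.push_back(j);
          rows.push_back(k);
          rows.push_back(v);
        }
      }
  int n = rows.size() / 4;
  IntegerMatrix out(n, 4);
  for (int r = 0; r < n; ++r)
    for (int c2 = 0; c2 < 4; ++c2) out(r, c2) = rows[4 * r + c2];
  return out;
}

// Visitor-pattern index sequence over an active set of given length, exposed
// for statistical tests; consumes the given block stream.
// [[Rcpp::export]]
IntegerVector cpp_visitor_positions(int active_count, int mean_step, RawVector state) {
  bcrng::Stream g;
  bcrng::load_stream(g, RAW(state));
  std::vector<int> out;
  int M = 2 * mean_step - 1;
  long long pos = stationary_delay(g, mean_step);
  while (pos < active_count) {
    out.push_back((int)pos);
    pos += 1 + bcrng::runif_int(g, M);
  }
  bcrng::save_stream(g, RAW(state));
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
RawVector cpp_rng_seed(double base_seed, int stream_id) {
  bcrng::Stream g;
  bcrng::seed_stream(g, (uint64_t)base_seed, (uint64_t)stream_id);
  RawVector st(32);
  bcrng::save_stream(g, RAW(st));
  return st;
}

// [[Rcpp::export]]
NumericVector cpp_rng_runif(RawVector state, int n) {
  bcrng::Stream g;
  bcrng::load_stream(g, RAW(state));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bcrng::runif01(g);
  bcrng::save_stream(g, RAW(state));
  return out;
}
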