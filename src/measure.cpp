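#include <Rcpp.h>

#include <map>
#include <utility>

#include "geometry.h"

using namespace Rcpp;

// Field measurement on plain 3D integer label arrays (R column-major,
// dims d1 x d2 x d3).  Voxels outside the array count as wall for side
// counting (no face contribution) and as background (0) for marching cubes.

static inline int fget(const int* f, int d1, int d2, int d3, int x, int y, int z) {
  return f[x + d1 * (y + d2 * z)];
}

// [[Rcpp::export]]
double cpp_side_surface(IntegerVector field, int id, int wall_id) {
  IntegerVector dm = field.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int* f = INTEGER(field);
  long long faces = 0;
  const int dx[3] = {1, 0, 0}, dy[3] = {0, 1, 0}, dz[3] = {0, 0, 1};
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int v = fget(f, d1, d2, d3, x, y, z);
        for (int a = 0; a < 3; ++a) {
          int xx = x + dx[a], yy = y + dy[a], zz = z + dz[a];
          if (xx >= d1 || yy >= d2 || zz >= d3) continue;  // face to implicit wall
          int w = fget(f, d1, d2, d3, xx, yy, zz);
          if (v == w) continue;
          if (v == wall_id || w == wall_id) continue;
          if (v == id || w == id) ++faces;
        }
      }
  return (double)faces;
}

// [[Rcpp::export]]
double cpp_march_surface(IntegerVector field, int id) {
  IntegerVector dm = field.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int* f = INTEGER(field);
  const mcgeom::Tables& t = mcgeom::tables();
  double area = 0.0;
  for (int z = -1; z < d3; ++z)
    for (int y = -1; y < d2; ++y)
      for (int x = -1; x < d1; ++x) {
        int cfg = 0;
        for (int c = 0; c < 8; ++c) {
          int xx = x + (c & 1), yy = y + ((c >> 1) & 1), zz = z + ((c >> 2) & 1);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= d1 || yy >= d2 || zz >= d3) continue;
          if (fget(f, d1, d2, d3, xx, yy, zz) == id) cfg |= (1 << c);
        }
        area += t.area3[cfg];
      }
  return area;
}

// [[Rcpp::export]]
double cpp_march_volume(IntegerVector field, int id) {
  IntegerVector dm = field.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int* f = INTEGER(field);
  const mcgeom::Tables& t = mcgeom::tables();
  double vol = 0.0;
  for (int z = -1; z < d3; ++z)
    for (int y = -1; y < d2; ++y)
      for (int x = -1; x < d1; ++x) {
        int cfg = 0;
        for (int c = 0; c < 8; ++c) {
          int xx = x + (c & 1), yy = y + ((c >> 1) & 1), zz = z + ((c >> 2) & 1);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= d1 || yy >= d2 || zz >= d3) continue;
          if (fget(f, d1, d2, d3, xx, yy, zz) == id) cfg |= (1 << c);
        }
        vol += t.vol3[cfg];
      }
  return vol;
}

// [[Rcpp::export]]
double cpp_march_perimeter2d(IntegerMatrix img, int id) {
  int d1 = img.nrow(), d2 = img.ncol();
  const mcgeom::Tables& t = mcgeom::tables();
  double len = 0.0;
  for (int y = -1; y < d2; ++y)
    for (int x = -1; x < d1; ++x) {
      int cfg = 0;
      // corner bits: 0 (0,0), 1 (1,0), 2 (1,1), 3 (0,1)
      const int cx[4] = {0, 1, 1, 0}, cy[4] = {0, 0, 1, 1};
      for (int c = 0; c < 4; ++c) {
        int xx = x + cx[c], yy = y + cy[c];
        if (xx < 0 || yy < 0 || xx >= d1 || yy >= d2) continue;
        if (img(xx, yy) == id) cfg |= (1 << c);
      }
      len += t.perim2[cfg];
    }
  return len;
}

// [[Rcpp::export]]
double cpp_side_perimeter2d(IntegerMatrix img, int id, int wall_id) {
  int d1 = img.nrow(), d2 = img.ncol();
  long long edges = 0;
  for (int y = 0; y < d2; ++y)
    for (int x = 0; x < d1; ++x) {
      int v = img(x, y);
      if (x + 1 < d1) {
        int w = img(x + 1, y);
        if (v != w && v != wall_id && w != wall_id && (v == id || w == id)) ++edges;
      }
      if (y + 1 < d2) {
        int w = img(x, y + 1);
        if (v != w && v != wall_id && w != wall_id && (v == id || w == id)) ++edges;
      }
    }
  return (double)edges;
}

// Pairwise shared surfaces (side counting) over a label field.  Faces to the
// wall are not counted; the background/liquid (id 0) participates as a
// compartment.  Returns a data.frame (i, j, surface) with i < j.
// [[Rcpp::export]]
DataFrame cpp_shared_surfaces(IntegerVector field, int wall_id) {
  IntegerVector dm = field.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int* f = INTEGER(field);
  std::map<std::pair<int, int>, long long> acc;
  const int dx[3] = {1, 0, 0}, dy[3] = {0, 1, 0}, dz[3] = {0, 0, 1};
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int v = fget(f, d1, d2, d3, x, y, z);
        if (v == wall_id) continue;
        for (int a = 0; a < 3; ++a) {
          int xx = x + dx[a], yy = y + dy[a], zz = z + dz[a];
          if (xx >= d1 || yy >= d2 || zz >= d3) continue;
          int w = fget(f, d1, d2, d3, xx, yy, zz);
          if (w == wall_id || v == w) continue;
          std::pair<int, int> key = v < w ? std::make_pair(v, w) : std::make_pair(w, v);
          acc[key] += 1;
        }
      }
  int n = acc.size();
  IntegerVector ci(n), cj(n);
  NumericVector cs(n);
  int k = 0;
  for (std::map<std::pair<int, int>, long long>::const_iterator it = acc.begin();
       it != acc.end(); ++it, ++k) {
    ci[k] = it->first.first;
    cj[k] = it->first.second;
    cs[k] = (double)it->second;
  }
  return DataFrame::create(Named("i") = ci, Named("j") = cj, Named("surface") = cs);
}

// [[Rcpp::export]]
NumericVector cpp_mc_area_table() {
  const mcgeom::Tables& t = mcgeom::tables();
  return NumericVector(t.area3, t.area3 + 256);
}

// [[Rcpp::export]]
NumericVector cpp_mc_volume_table() {
  const mcgeom::Tables& t = mcgeom::tables();
  return NumericVector(t.vol3, t.vol3 + 256);
}
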