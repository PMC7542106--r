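#include "geometry.h"

#include <cmath>
#include <cstring>
#include <vector>

namespace mcgeom {

namespace {

// Cube corner i has coordinates (i&1, (i>>1)&1, (i>>2)&1).
const int CX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

// Face corner cycles, counter-clockwise as seen from outside the cube.
const int FACES[6][4] = {
    {0, 4, 6, 2},  // x = 0
    {1, 3, 7, 5},  // x = 1
    {0, 1, 5, 4},  // y = 0
    {2, 6, 7, 3},  // y = 1
    {0, 2, 3, 1},  // z = 0
    {4, 5, 7, 6},  // z = 1
};

struct P3 {
  double x, y, z;
};

inline P3 corner(int c) { return P3{(double)CX[c], (double)CY[c], (double)CZ[c]}; }

inline P3 mid(int a, int b) {
  return P3{0.5 * (CX[a] + CX[b]), 0.5 * (CY[a] + CY[b]), 0.5 * (CZ[a] + CZ[b])};
}

inline P3 sub(P3 a, P3 b) { return P3{a.x - b.x, a.y - b.y, a.z - b.z}; }
inline P3 cross(P3 a, P3 b) {
  return P3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(P3 a, P3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(P3 a) { return std::sqrt(dot(a, a)); }
// Signed volume of tetrahedron (origin, a, b, c) times 6.
inline double det3(P3 a, P3 b, P3 c) { return dot(a, cross(b, c)); }

// Edge bookkeeping: 12 cube edges indexed 0..11 via a corner-pair lookup.
struct EdgeMap {
  int idx[8][8];
  int ca[12], cb[12];
  EdgeMap() {
    std::memset(idx, -1, sizeof(idx));
    int n = 0;
    for (int a = 0; a < 8; ++a)
      for (int b = a + 1; b < 8; ++b) {
        int d = a ^ b;
        if (d == 1 || d == 2 || d == 4) {  // differ in exactly one coordinate
          idx[a][b] = idx[b][a] = n;
          ca[n] = a;
          cb[n] = b;
          ++n;
        }
      }
  }
};

// Oriented cut segments and the inside polygon for one face, for the 16
// combinations of its four cyclic corners.  Orientation: the boundary of the
// inside region is traversed counter-clockwise as seen from outside the cube
// (inside region on the left), so chained segments close into loops whose
// fan caps, taken in reverse, complete an outward-oriented closed surface.
void face_case(const int q[4], int cfg,  // cfg bit i = corner i of the cube inside
               const EdgeMap& em,
               std::vector<std::pair<int, int> >& segs,   // (from_edge, to_edge)
               std::vector<std::vector<P3> >& polys) {    // inside polygon(s)
  bool b[4];
  int count = 0;
  for (int i = 0; i < 4; ++i) {
    b[i] = (cfg >> q[i]) & 1;
    count += b[i];
  }
  if (count == 0) return;
  if (count == 4) {
    std::vector<P3> poly;
    for (int i = 0; i < 4; ++i) poly.push_back(corner(q[i]));
    polys.push_back(poly);
    return;
  }
  if (count == 2 && b[0] == b[2]) {  // diagonal pair: "inside wins" hexagon
    int a = b[0] ? 0 : 1;            // rotate so inside corners are a, a+2
    int c0 = q[a], c1 = q[(a + 1) % 4], c2 = q[(a + 2) % 4], c3 = q[(a + 3) % 4];
    segs.push_back({em.idx[c0][c1], em.idx[c1][c2]});
    segs.push_back({em.idx[c2][c3], em.idx[c3][c0]});
    std::vector<P3> poly;
    poly.push_back(corner(c0));
    poly.push_back(mid(c0, c1));
    poly.push_back(mid(c1, c2));
    poly.push_back(corner(c2));
    poly.push_back(mid(c2, c3));
    poly.push_back(mid(c3, c0));
    polys.push_back(poly);
    return;
  }
  for (int r = 0; r < 4; ++r) {
    int c0 = q[r], c1 = q[(r + 1) % 4], c2 = q[(r + 2) % 4], c3 = q[(r + 3) % 4];
    bool a0 = b[r], a1 = b[(r + 1) % 4], a2 = b[(r + 2) % 4], a3 = b[(r + 3) % 4];
    if (count == 1 && a0) {
      segs.push_back({em.idx[c0][c1], em.idx[c3][c0]});
      std::vector<P3> poly;
      poly.push_back(corner(c0));
      poly.push_back(mid(c0, c1));
      poly.push_back(mid(c3, c0));
      polys.push_back(poly);
      return;
    }
    if (count == 2 && a0 && a1) {
      segs.push_back({em.idx[c1][c2], em.idx[c3][c0]});
      std::vector<P3> poly;
      poly.push_back(corner(c0));
      poly.push_back(corner(c1));
      poly.push_back(mid(c1, c2));
      poly.push_back(mid(c3, c0));
      polys.push_back(poly);
      return;
    }
    if (count == 3 && a0 && a1 && a2 && !a3) {
      segs.push_back({em.idx[c2][c3], em.idx[c3][c0]});
      std::vector<P3> poly;
      poly.push_back(corner(c0));
      poly.push_back(corner(c1));
      poly.push_back(corner(c2));
      poly.push_back(mid(c2, c3));
      poly.push_back(mid(c3, c0));
      polys.push_back(poly);
      return;
    }
  }
}

void build3(Tables& t) {
  EdgeMap em;
  for (int cfg = 0; cfg < 256; ++cfg) {
    std::vector<std::pair<int, int> > segs;
    std::vector<std::vector<P3> > polys;
    for (int f = 0; f < 6; ++f) face_case(FACES[f], cfg, em, segs, polys);

    double vol = 0.0;
    for (size_t p = 0; p < polys.size(); ++p) {  // inside patches of cube faces
      const std::vector<P3>& poly = polys[p];
      for (size_t i = 1; i + 1 < poly.size(); ++i)
        vol += det3(poly[0], poly[i], poly[i + 1]);
    }

    // Chain segments into loops (each cut edge has exactly one outgoing and
    // one incoming segment).
    int out[12];
    bool used[12];
    for (int e = 0; e < 12; ++e) {
      out[e] = -1;
      used[e] = false;
    }
    for (size_t s = 0; s < segs.size(); ++s) out[segs[s].first] = segs[s].second;

    double area = 0.0;
    for (int e0 = 0; e0 < 12; ++e0) {
      if (out[e0] < 0 || used[e0]) continue;
      std::vector<P3> loop;
      int e = e0;
      do {
        used[e] = true;
        loop.push_back(mid(em.ca[e], em.cb[e]));
        e = out[e];
      } while (e != e0);
      P3 c{0, 0, 0};
      for (size_t i = 0; i < loop.size(); ++i) {
        c.x += loop[i].x;
        c.y += loop[i].y;
        c.z += loop[i].z;
      }
      c.x /= loop.size();
      c.y /= loop.size();
      c.z /= loop.size();
      size_t n = loop.size();
      for (size_t i = 0; i < n; ++i) {
        P3 a = loop[i], b = loop[(i + 1) % n];
        area += 0.5 * norm(cross(sub(a, c), sub(b, c)));
        // cap triangles traverse the loop in reverse to close the inside
        // region with outward orientation
        vol += det3(c, b, a);
      }
    }
    t.area3[cfg] = area;
    t.vol3[cfg] = vol / 6.0;
  }
}

void build2(Tables& t) {
  // Square corners c: bit0 (0,0), bit1 (1,0), bit2 (1,1), bit3 (0,1),
  // cyclic order 0-1-2-3.
  const double mx[4] = {0.5, 1.0, 0.5, 0.0};  // midpoint of edge (i, i+1)
  const double my[4] = {0.0, 0.5, 1.0, 0.5};
  const double SQ2H = std::sqrt(2.0) / 2.0;
  for (int cfg = 0; cfg < 16; ++cfg) {
    bool b[4];
    int count = 0;
    for (int i = 0; i < 4; ++i) {
      b[i] = (cfg >> i) & 1;
      count += b[i];
    }
    double len = 0.0;
    if (count == 1 || count == 3) {
      len = SQ2H;  // one corner cut
    } else if (count == 2) {
      if (b[0] == b[2]) {
        len = 2.0 * SQ2H;  // diagonal, inside wins: two cuts
      } else {
        // adjacent pair: straight cut between opposite edge midpoints
        int r = -1;
        for (int i = 0; i < 4; ++i)
          if (b[i] && b[(i + 1) % 4]) r = i;
        double dx = mx[(r + 1) % 4] - mx[(r + 3) % 4];
        double dy = my[(r + 1) % 4] - my[(r + 3) % 4];
        len = std::sqrt(dx * dx + dy * dy);
      }
    }
    t.perim2[cfg] = len;
  }
}

}  // namespace

const Tables& tables() {
  static Tables t;
  static bool built = false;
  if (!built) {
    build3(t);
    build2(t);
    built = true;
  }
  return t;
}

}  // namespace mcgeom
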