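#ifndef BLOCKCPM_GEOMETRY_H
#define BLOCKCPM_GEOMETRY_H

// Marching-cubes / marching-squares geometry for binary (0/1) corner fields
// at iso-level 0.5 with midpoint interpolation.  Tables are constructed at
// first use by tracing oriented marching-squares segments on the six cube
// faces into closed loops; each loop is fan-triangulated from its centroid.
// The saddle ("ambiguous") cases are resolved by connecting the inside
// corners ("inside wins"), applied uniformly in the 2D face rule, which makes
// the global surface closed and consistently oriented, so enclosed volumes
// follow from the divergence theorem.

namespace mcgeom {

struct Tables {
  double area3[256];   // iso-surface area inside one unit cube per corner config
  double vol3[256];    // enclosed (inside) volume within one unit cube
  double perim2[16];   // iso-contour length inside one unit square (2D)
};

const Tables& tables();

}  // namespace mcgeom

#endif
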