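# lattice_core: field storage, checkerboard coloring, block geometry, halos.

#' Reserved wall cell identifier
#'
#' The simulation domain is padded by a one-voxel layer of immutable wall
#' voxels.  Wall voxels are never copy sources or targets and contribute no
#' adhesion energy or shared surface.
#'
#' @return The integer id used for wall voxels.
#' @export
cpm_wall_id <- function() .Machine$integer.max

#' Checkerboard coloring scheme
#'
#' Voxels are partitioned into disjoint color classes so that simultaneous
#' updates of one class never read another update's writes: 2 colors suffice
#' for the 7-point (face-neighbor) stencil, 8 colors for the full 27-point
#' stencil (and for the marching-cubes surface metric, whose incremental
#' update reads the whole 3x3x3 neighborhood).
#'
#' @param n_colors 2 or 8.
#' @param stencil 7 or 27 (copy-source neighborhood).
#' @return An object of class `cpm_checkerboard`.
#' @export
checkerboard <- function(n_colors = 8, stencil = 27) {
  if (!n_colors %in% c(2, 8)) {
    stop("configuration error: n_colors must be 2 or 8")
  }
  if (!stencil %in% c(7, 27)) {
    stop("configuration error: stencil must be 7 or 27")
  }
  if (n_colors == 2 && stencil == 27) {
    stop("configuration error: the 27-point stencil requires the 8-colored checkerboard")
  }
  structure(list(n_colors = as.integer(n_colors), stencil = as.integer(stencil)),
            class = "cpm_checkerboard")
}

#' Checkerboard color of a voxel
#'
#' Colors are computed from global 0-based coordinates, so the coloring is
#' consistent across block boundaries.
#'
#' @param voxel Integer triple (0-based global coordinates), or a matrix with
#'   one voxel per row.
#' @param scheme A [checkerboard()] scheme.
#' @return Integer color index in `0:(n_colors-1)`.
#' @export
color_of <- function(voxel, scheme) {
  if (!inherits(scheme, "cpm_checkerboard")) {
    stop("configuration error: unknown checkerboard scheme")
  }
  m <- if (is.matrix(voxel)) voxel else matrix(voxel, nrow = 1)
  if (scheme$n_colors == 2) {
    as.integer((m[, 1] + m[, 2] + m[, 3]) %% 2)
  } else {
    as.integer(m[, 1] %% 2 + 2 * (m[, 2] %% 2) + 4 * (m[, 3] %% 2))
  }
}

#' Interior voxels of one color class
#'
#' @param dims Interior extent of the block (integer triple).
#' @param color Color index.
#' @param scheme A [checkerboard()] scheme.
#' @param origin Global 0-based coordinate of the block's first interior voxel.
#' @return Matrix of 0-based block-local voxel coordinates, one per row,
#'   ordered by the linear array index (x fastest); the union over all colors
#'   is exactly the interior, pairwise disjoint.
#' @export
active_voxels <- function(dims, color, scheme, origin = c(0L, 0L, 0L)) {
  if (color < 0 || color >= scheme$n_colors) {
    stop("configuration error: invalid color for the scheme")
  }
  g <- expand.grid(x = seq_len(dims[1]) - 1L, y = seq_len(dims[2]) - 1L,
                   z = seq_len(dims[3]) - 1L)
  gg <- cbind(g$x + origin[1], g$y + origin[2], g$z + origin[3])
  keep <- color_of(gg, scheme) == color
  unname(as.matrix(g[keep, , drop = FALSE]))
}

#' Block decomposition of the simulation domain
#'
#' Blocks tile the interior exactly; every block's field carries a one-voxel
#' halo that overlaps the neighbors' interiors (or the wall padding at the
#' domain border).
#'
#' @param domain_size Interior extent of the whole domain (integer triple).
#' @param block_grid Number of blocks per dimension (integer triple).
#' @return An object of class `cpm_layout` with elements `grid`, `shape`
#'   (interior voxels per block), `origins` (one global 0-based origin per
#'   block, blocks ordered x-fastest) and `n_blocks`.
#' @export
block_layout <- function(domain_size, block_grid = c(1L, 1L, 1L)) {
  domain_size <- as.integer(domain_size)
  block_grid <- as.integer(block_grid)
  if (any(domain_size %% block_grid != 0)) {
    stop("configuration error: domain.size must be divisible by domain.blocks")
  }
  shape <- domain_size %/% block_grid
  idx <- expand.grid(bx = seq_len(block_grid[1]) - 1L, by = seq_len(block_grid[2]) - 1L,
                     bz = seq_len(block_grid[3]) - 1L)
  origins <- cbind(idx$bx * shape[1], idx$by * shape[2], idx$bz * shape[3])
  structure(list(grid = block_grid, shape = shape,
                 origins = matrix(as.integer(origins), ncol = 3),
                 n_blocks = prod(block_grid)),
            class = "cpm_layout")
}

# block grid coordinates (0-based) of block b (1-based index)
block_grid_coords <- function(layout, b) {
  b0 <- b - 1L
  gx <- layout$grid[1]; gy <- layout$grid[2]
  c(b0 %% gx, (b0 %/% gx) %% gy, b0 %/% (gx * gy))
}

# 1-based indices of the up-to-26 neighbor blocks of b, with direction labels
block_neighbors <- function(layout, b) {
  bc <- block_grid_coords(layout, b)
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- bc + c(dx, dy, dz)
    if (any(nb < 0) || any(nb >= layout$grid)) next
    idx <- 1L + nb[1] + layout$grid[1] * (nb[2] + layout$grid[2] * nb[3])
    out[[length(out) + 1L]] <- list(index = idx, dir = c(dx, dy, dz))
  }
  out
}

# Allocate empty block fields (liquid interior, wall-consistent halos).
make_blocks <- function(layout, wall_id = cpm_wall_id()) {
  sh <- layout$shape
  blocks <- lapply(seq_len(layout$n_blocks), function(b) {
    array(0L, dim = sh + 2L)
  })
  cpp_halo_sync(blocks, as.integer(sh), as.integer(layout$grid), wall_id)
  blocks
}

#' Refresh all block halos from the owning neighbors
#'
#' Every halo voxel is set to the corresponding interior voxel of the owning
#' neighbor block; halos at the domain border hold the wall sentinel.  Fields
#' are updated in place.
#'
#' @param blocks List of block field arrays (interior + 1-voxel halo).
#' @param layout A [block_layout()].
#' @param wall_id Wall sentinel id.
#' @return The block list, invisibly.
#' @export
halo_sync <- function(blocks, layout, wall_id = cpm_wall_id()) {
  cpp_halo_sync(blocks, as.integer(layout$shape), as.integer(layout$grid), wall_id)
  invisible(blocks)
}

#' Reassemble the global field from block interiors
#'
#' @param blocks List of block field arrays.
#' @param layout A [block_layout()].
#' @return Integer array of the full domain.
#' @export
reassemble_field <- function(blocks, layout) {
  sh <- layout$shape
  field <- array(0L, dim = layout$grid * sh)
  for (b in seq_len(layout$n_blocks)) {
    o <- layout$origins[b, ]
    field[o[1] + seq_len(sh[1]), o[2] + seq_len(sh[2]), o[3] + seq_len(sh[3])] <-
      blocks[[b]][1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])]
  }
  field
}

# Split a global field into halo-padded blocks (halos synced).
blocks_from_field <- function(field, layout, wall_id = cpm_wall_id()) {
  sh <- layout$shape
  blocks <- lapply(seq_len(layout$n_blocks), function(b) {
    o <- layout$origins[b, ]
    blk <- array(0L, dim = sh + 2L)
    blk[1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])] <-
      field[o[1] + seq_len(sh[1]), o[2] + seq_len(sh[2]), o[3] + seq_len(sh[3])]
    blk
  })
  cpp_halo_sync(blocks, as.integer(sh), as.integer(layout$grid), wall_id)
  blocks
}
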