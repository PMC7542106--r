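# surface_metrics: surface and volume measurement of labeled lattices.

#' Side-counting (Manhattan) surface of a cell
#'
#' Counts lattice faces (pixel edges in 2D) between voxels of the given cell
#' and voxels of any other id.  Faces to wall voxels and to the implicit wall
#' outside the array are not counted.
#'
#' @param field 3D integer label array, or an integer matrix for the 2D case.
#' @param cell_id Cell identifier (absent ids give 0).
#' @param wall_id Wall sentinel id.
#' @return Number of exposed faces (edges in 2D).
#' @export
side_count_surface <- function(field, cell_id, wall_id = cpm_wall_id()) {
  if (is.matrix(field)) {
    cpp_side_perimeter2d(field, as.integer(cell_id), wall_id)
  } else {
    cpp_side_surface(field, as.integer(cell_id), wall_id)
  }
}

#' Marching-cubes (marching-squares in 2D) surface of a cell
#'
#' Computes the area (length in 2D) of the 0.5 iso-surface of the cell's
#' binary indicator: corners holding the cell's id are set to 1, all other
#' ids (other cells, liquid, wall) to 0.  Each voxel contributes to eight
#' marching cubes (four squares in 2D); crossings lie at edge midpoints.
#' Ambiguous (saddle) configurations are resolved by connecting the inside
#' corners ("inside wins").
#'
#' @inheritParams side_count_surface
#' @return Iso-surface area (iso-contour length in 2D).
#' @export
marching_surface <- function(field, cell_id, wall_id = cpm_wall_id()) {
  if (is.matrix(field)) {
    cpp_march_perimeter2d(field, as.integer(cell_id))
  } else {
    cpp_march_surface(field, as.integer(cell_id))
  }
}

#' Cell volume
#'
#' @inheritParams side_count_surface
#' @param method `"count"` (number of voxels) or `"marching"` (volume
#'   enclosed by the 0.5 iso-surface of the cell indicator).
#' @return Cell volume; 0 for an absent id.
#' @export
cell_volume <- function(field, cell_id, method = c("count", "marching")) {
  method <- match.arg(method)
  if (method == "count") {
    sum(field == as.integer(cell_id))
  } else {
    cpp_march_volume(field, as.integer(cell_id))
  }
}

#' Surface change of a single-voxel flip
#'
#' Computes, for every cell whose surface changes when the voxel is flipped
#' from `old_id` to `new_id`, the exact surface difference under the chosen
#' metric.  Only the two involved cells can change (cells at Chebyshev
#' distance greater than one are unaffected; for uninvolved neighbors the
#' boundary "to a different id" is unchanged).
#'
#' @param field 3D integer label array.
#' @param voxel 0-based voxel coordinate triple.
#' @param old_id,new_id Ids before and after the flip (`field` must hold
#'   `old_id` at `voxel`).
#' @param metric `"side"` or `"marching"`.
#' @param wall_id Wall sentinel id.
#' @return Named numeric vector of surface deltas, one entry per affected
#'   cell id (liquid excluded).
#' @export
local_surface_delta <- function(field, voxel, old_id, new_id,
                                metric = c("side", "marching"),
                                wall_id = cpm_wall_id()) {
  metric <- match.arg(metric)
  old_id <- as.integer(old_id); new_id <- as.integer(new_id)
  stopifnot(field[voxel[1] + 1, voxel[2] + 1, voxel[3] + 1] == old_id,
            old_id != new_id)
  ids <- c(old_id, new_id)
  meas <- function(id) {
    if (metric == "side") cpp_side_surface(field, id, wall_id)
    else cpp_march_surface(field, id)
  }
  before <- vapply(ids, meas, numeric(1))
  field[voxel[1] + 1, voxel[2] + 1, voxel[3] + 1] <- new_id
  after <- vapply(ids, meas, numeric(1))
  out <- after - before
  names(out) <- as.character(ids)
  out[names(out) != "0"]
}

#' Pairwise shared surfaces
#'
#' Shared surfaces are always measured by side counting (face counting), even
#' when the energy uses the marching metric: the marching iso-surface cannot
#' be unambiguously attributed to a specific neighbor pair.  The liquid
#' compartment (id 0) participates; faces to wall voxels do not.
#'
#' @param field 3D integer label array.
#' @param wall_id Wall sentinel id.
#' @return A data.frame with columns `i`, `j` (`i < j`) and `surface`; pairs
#'   with no contact are absent.
#' @export
shared_surfaces <- function(field, wall_id = cpm_wall_id()) {
  cpp_shared_surfaces(field, wall_id)
}
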