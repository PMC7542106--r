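# hamiltonian: energy terms, copy-attempt energy differences, Metropolis rule.

#' Volume-constraint energy difference
#'
#' The volume term penalises deviation of a cell's volume from its effective
#' target quadratically: `E_V = lambda_V * (v - V0)^2`.  This evaluates the
#' change when the cell's volume changes by `dV` from its current committed
#' value.
#'
#' @param v Current committed cell volume.
#' @param dV Proposed volume change.
#' @param V0 Effective target volume of the cell.
#' @param lambda_V Volume coupling strength (>= 0).
#' @return Energy difference.
#' @export
volume_term_delta <- function(v, dV, V0, lambda_V) {
  lambda_V * ((v + dV - V0)^2 - (v - V0)^2)
}

#' Surface-constraint energy difference
#'
#' As [volume_term_delta()], for the surface term
#' `E_S = lambda_S * (s - S0)^2`.
#'
#' @param s Current committed cell surface.
#' @param dS Proposed surface change.
#' @param S0 Effective target surface of the cell.
#' @param lambda_S Surface coupling strength (>= 0).
#' @return Energy difference.
#' @export
surface_term_delta <- function(s, dS, S0, lambda_S) {
  lambda_S * ((s + dS - S0)^2 - (s - S0)^2)
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change with probability 1 if `dE < 0` and with
#' probability `exp(-dE / temperature)` otherwise; `dE = 0` is always
#' accepted.
#'
#' @param dE Energy difference(s) of the attempted change.
#' @param temperature Simulation temperature (> 0, energy units).
#' @param u Uniform(0,1) draws, one per element of `dE`; defaults to
#'   `runif()`.
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(dE, temperature, u = stats::runif(length(dE))) {
  if (temperature <= 0) {
    stop("configuration error: temperature must be positive")
  }
  dE <= 0 | u < exp(-dE / temperature)
}

# Assemble the per-cell / per-type vectors cpp_attempt_delta() expects.
# cells: data.frame(id, type, v, s, v0, s0); type by name into `types`.
attempt_args <- function(cells, types) {
  ti <- match(cells$type, types$name)
  if (anyNA(ti)) {
    stop("configuration error: unknown cell type ", cells$type[which(is.na(ti))[1]])
  }
  list(ids = as.integer(cells$id), type = as.integer(ti - 1L),
       v = as.numeric(cells$v), s = as.numeric(cells$s),
       v0 = as.numeric(cells$v0), s0 = as.numeric(cells$s0),
       lamv = as.numeric(types$lambda_V), lams = as.numeric(types$lambda_S),
       A = types$adhesion,
       solid = as.integer(types$is_solid), liquid = as.integer(types$is_liquid))
}

#' Energy difference of a copy attempt
#'
#' Evaluates the full Hamiltonian difference of copying `new_id` onto a voxel
#' of a plain (un-blocked) label field: quadratic volume and surface
#' constraints plus adhesion, using the committed per-cell state supplied in
#' `cells`.  The array boundary acts as wall.  Under the marching metric the
#' adhesion term scales the exact side-counted pairwise changes by the local
#' ratio of marching to side-count boundary change (the iso-surface itself is
#' not pairwise attributable).
#'
#' @param field 3D integer label array.
#' @param voxel 0-based voxel coordinates.
#' @param new_id Proposed id (must differ from the current id at `voxel`).
#' @param cells data.frame with columns `id`, `type` (type name), `v`, `s`,
#'   `v0`, `s0`: one row per cell present (include liquid, id 0).
#' @param types A [cell_types()] table.
#' @param metric `"side"` or `"marching"`.
#' @param temperature Simulation temperature.
#' @param wall_id Wall sentinel id.
#' @return List with `dE`, the components `dE_vol`, `dE_surf`, `dE_adh`, the
#'   surface deltas `dS` and volume deltas `dV` (named by cell id), and
#'   `valid` (FALSE when the attempt is forbidden: same id, wall, or a solid
#'   cell involved).
#' @export
total_delta_e <- function(field, voxel, new_id, cells, types,
                          metric = c("side", "marching"), temperature = 1,
                          wall_id = cpm_wall_id()) {
  metric <- match.arg(metric)
  a <- attempt_args(cells, types)
  r <- cpp_attempt_delta(field, as.integer(voxel), as.integer(new_id), a$ids,
                         a$type, a$v, a$s, a$v0, a$s0, a$lamv, a$lams, a$A,
                         a$solid, a$liquid, wall_id,
                         if (metric == "marching") 1L else 0L, temperature)
  old_id <- field[voxel[1] + 1, voxel[2] + 1, voxel[3] + 1]
  dS <- c(r$ds_old, r$ds_new)
  dV <- c(-1, 1)
  names(dS) <- names(dV) <- as.character(c(old_id, new_id))
  list(dE = r$dE, dE_vol = r$dE_vol, dE_surf = r$dE_surf, dE_adh = r$dE_adh,
       dS = dS, dV = dV, valid = r$valid)
}

#' Adhesion energy difference of a copy attempt
#'
#' The adhesion contribution alone: pairwise shared-surface changes weighted
#' by the adhesion coupling matrix, same-cell pairs contributing nothing.
#'
#' @inheritParams total_delta_e
#' @return Numeric energy difference (0 for forbidden attempts).
#' @export
adhesion_delta <- function(field, voxel, new_id, cells, types,
                           metric = c("side", "marching"),
                           wall_id = cpm_wall_id()) {
  metric <- match.arg(metric)
  r <- total_delta_e(field, voxel, new_id, cells, types, metric = metric,
                     temperature = 1, wall_id = wall_id)
  r$dE_adh
}
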