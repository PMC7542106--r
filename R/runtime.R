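# block_runtime: oversize detection, Message-of-Death propagation, sanity
# action, consistency audits.

#' Detect oversized cells from directional ACD reports
#'
#' A cell whose interior presence is reported from two opposite axis
#' neighbors of the same block must span at least three blocks along that
#' axis, violating the constraint that a cell be smaller than the block edge
#' per dimension.  Diagonal-only presence never triggers detection.
#'
#' @param received List of received reports, each
#'   `list(dir = c(dx, dy, dz), ids = <interior-present cell ids>)`.
#' @return Integer vector of cell ids for which a Message of Death must be
#'   issued (possibly empty).
#' @export
detect_oversize <- function(received) {
  axis_ids <- function(d) {
    hits <- Filter(function(m) identical(as.integer(m$dir), as.integer(d)), received)
    unique(unlist(lapply(hits, function(m) m$ids)))
  }
  out <- integer(0)
  for (a in 1:3) {
    minus <- plus <- c(0L, 0L, 0L)
    minus[a] <- -1L; plus[a] <- 1L
    out <- c(out, intersect(axis_ids(minus), axis_ids(plus)))
  }
  setdiff(sort(unique(out)), 0L)
}

#' Blocks reached by a Message of Death
#'
#' A MoD is forwarded for two commits over the 26-neighbor block topology:
#' after the second step exactly the 5x5x5 block neighborhood of the origin
#' (clipped at the domain edge) has received it, and all receiving blocks
#' delete the cell in the same commit.
#'
#' @param layout A [block_layout()].
#' @param origin 1-based index of the originating block.
#' @return Sorted 1-based indices of all receiving blocks (origin included).
#' @export
propagate_mod <- function(layout, origin) {
  oc <- block_grid_coords(layout, origin)
  out <- integer(0)
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2) {
    nb <- oc + c(dx, dy, dz)
    if (any(nb < 0) || any(nb >= layout$grid)) next
    out <- c(out, 1L + nb[1] + layout$grid[1] * (nb[2] + layout$grid[2] * nb[3]))
  }
  sort(unique(out))
}

#' Sanity action: clean detached single voxels
#'
#' Any voxel whose 6-neighborhood contains no voxel of the same cell is
#' replaced by liquid, with exact volume/surface/center-of-mass bookkeeping
#' folded into every block's records.  Optionally (config `sanity.radius`)
#' voxels farther than a fixed radius from the cell's center of mass are
#' cleaned as well.  Solid cells are never touched.
#'
#' @param sim A [cpm_sim()] environment.
#' @return Number of voxels cleaned, invisibly.
#' @export
sanity_sweep <- function(sim) {
  sh <- as.integer(sim$layout$shape)
  cleaned <- 0L
  for (b in seq_len(sim$layout$n_blocks)) {
    rows <- NULL
    if (sim$cfg$sanity$single_voxel) {
      cand <- cpp_sanity_candidates(sim$blocks[[b]], sh, sim$wall)
      if (nrow(cand)) {
        rec <- sim$recs[[b]]
        ti <- rec$type[match(cand[, 4], rec$ids)]
        keep <- !sim$types$is_solid[ti]
        cand <- cand[keep, , drop = FALSE]
        if (nrow(cand)) rows <- cbind(cand[, 1:3, drop = FALSE], 0L)
      }
    }
    if (!is.null(sim$cfg$sanity$radius)) {
      rec <- sim$recs[[b]]
      blk <- sim$blocks[[b]]
      o <- sim$layout$origins[b, ]
      for (q in seq_along(rec$ids)) {
        id <- rec$ids[q]
        ti <- rec$type[q]
        if (id == 0L || sim$types$is_solid[ti] || rec$v[q] <= 0) next
        com <- c(rec$cx[q], rec$cy[q], rec$cz[q]) / rec$v[q]
        w <- which(blk[1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])] == id,
                   arr.ind = TRUE)
        if (!nrow(w)) next
        g <- sweep(w - 1L, 2, -o)  # global coords
        d2 <- rowSums((g - matrix(com, nrow(g), 3, byrow = TRUE))^2)
        far <- d2 > sim$cfg$sanity$radius^2
        if (any(far)) rows <- rbind(rows, cbind(unname(w[far, , drop = FALSE]), 0L))
      }
    }
    if (!is.null(rows) && nrow(rows)) {
      rows <- unique(rows)
      rec <- sim$recs[[b]]
      d <- cpp_apply_flips(sim$blocks[[b]], rows, sim$layout$origins[b, ], sh,
                           rec$ids, rec$type - 1L, rec$v, rec$s, rec$v0, rec$s0,
                           sim$lamv, sim$lams, sim$adhesion, sim$type_solid,
                           sim$type_liquid, sim$wall, sim$metric)
      for (q in which(d$dv != 0 | d$ds != 0)) {
        if (rec$ids[q] == 0L) next
        apply_cell_delta_global(sim, rec$ids[q], d$dv[q], d$ds[q], d$dcx[q],
                                d$dcy[q], d$dcz[q])
      }
      cleaned <- cleaned + nrow(rows)
      halo_sync(sim$blocks, sim$layout, sim$wall)
    }
  }
  sim$stats$cleaned <- sim$stats$cleaned + cleaned
  invisible(cleaned)
}

#' Consistency audit of a running simulation
#'
#' Verifies, against the reassembled global field: (i) every block holding a
#' cell reports identical ACD values; (ii) ACD volume, surface and
#' center-of-mass sums equal a fresh measurement; (iii) voxel conservation
#' (cell volumes + liquid voxels fill the domain exactly); (iv) every halo
#' voxel equals the owning neighbor's interior voxel.
#'
#' @param sim A [cpm_sim()] environment.
#' @param tol Numeric tolerance for float comparisons.
#' @return A list with `ok` and a data.frame `violations`
#'   (`mcs`, `cell`, `what`).
#' @export
audit_consistency <- function(sim, tol = 1e-6) {
  bad <- list()
  note <- function(cell, what) bad[[length(bad) + 1L]] <<- list(mcs = sim$mcs, cell = cell, what = what)
  field <- reassemble_field(sim$blocks, sim$layout)
  reg <- cell_registry(sim)

  # (i) cross-block agreement
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    m <- match(rec$ids, reg$ids)
    for (q in seq_along(rec$ids)) {
      if (rec$ids[q] == 0L) next
      i <- m[q]
      if (abs(rec$v[q] - reg$v[i]) > tol || abs(rec$s[q] - reg$s[i]) > tol ||
          abs(rec$cx[q] - reg$cx[i]) > tol) {
        note(rec$ids[q], sprintf("block %d disagrees with registry", b))
      }
    }
  }
  # (ii) ACD vs fresh measurement
  for (i in seq_along(reg$ids)) {
    id <- reg$ids[i]
    v <- sum(field == id)
    s <- if (sim$metric == 1) cpp_march_surface(field, id)
         else cpp_side_surface(field, id, sim$wall)
    if (abs(reg$v[i] - v) > tol) note(id, sprintf("volume %g != recount %g", reg$v[i], v))
    if (abs(reg$s[i] - s) > tol) note(id, sprintf("surface %g != remeasure %g", reg$s[i], s))
    if (v > 0) {
      w <- which(field == id, arr.ind = TRUE) - 1L
      if (abs(reg$cx[i] - sum(w[, 1])) > tol || abs(reg$cy[i] - sum(w[, 2])) > tol ||
          abs(reg$cz[i] - sum(w[, 3])) > tol) {
        note(id, "center-of-mass sums differ from field")
      }
    }
  }
  # (iii) voxel conservation
  if (sum(reg$v) != sum(field != 0L & field != sim$wall)) note(NA, "voxel conservation violated")
  if (length(field) != prod(sim$cfg$domain$size)) note(NA, "domain size mismatch")
  # (iv) halos
  sh <- sim$layout$shape
  padded <- array(sim$wall, dim = dim(field) + 2L)
  padded[1 + seq_len(dim(field)[1]), 1 + seq_len(dim(field)[2]), 1 + seq_len(dim(field)[3])] <- field
  for (b in seq_len(sim$layout$n_blocks)) {
    o <- sim$layout$origins[b, ]
    expect <- padded[o[1] + seq_len(sh[1] + 2), o[2] + seq_len(sh[2] + 2), o[3] + seq_len(sh[3] + 2)]
    if (!identical(as.integer(expect), as.integer(sim$blocks[[b]]))) {
      note(NA, sprintf("halo of block %d stale", b))
    }
  }
  viol <- if (length(bad)) {
    data.frame(mcs = vapply(bad, `[[`, numeric(1), "mcs"),
               cell = vapply(bad, function(x) as.numeric(x$cell %||% NA), numeric(1)),
               what = vapply(bad, `[[`, character(1), "what"))
  } else {
    data.frame(mcs = numeric(0), cell = numeric(0), what = character(0))
  }
  list(ok = nrow(viol) == 0L, violations = viol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

audit_commit <- function(sim) {
  rep <- audit_consistency(sim)
  if (!rep$ok) {
    sim$audit_violations[[length(sim$audit_violations) + 1L]] <- rep$violations
  }
  invisible(rep$ok)
}
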