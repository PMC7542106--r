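# signal_transport: surface-mediated diffusion on the cell contact graph,
# relative/absolute decay, constant suppliers.

#' Signal flux between contacting cells
#'
#' For every contacting pair the flux is the arithmetic mean of the two
#' surface fractions of the shared surface, scaled by the type-pair
#' diffusion constant and the concentration difference:
#' `J_ij = (S_ij/S_i + S_ij/S_j) * D[t_i, t_j] * (sigma_j - sigma_i)`.
#' The flux is added to one cell's delta and subtracted from the other's;
#' constant suppliers receive no change.
#'
#' @param shared data.frame (`i`, `j`, `surface`) of pairwise shared
#'   surfaces (side counting), as from [shared_surfaces()].
#' @param surface Named vector of total cell surfaces `S_i` (side counting),
#'   indexed by cell id.
#' @param sigma Named vector of signal concentrations, indexed by cell id.
#' @param type Named integer vector of type indices, indexed by cell id.
#' @param D Type-pair diffusion matrix.
#' @param constant Logical per-type vector of constant-supplier flags.
#' @return Named vector of concentration changes, aligned with `sigma`.
#' @export
diffuse_flux <- function(shared, surface, sigma, type, D, constant = NULL) {
  d <- stats::setNames(numeric(length(sigma)), names(sigma))
  if (!nrow(shared)) return(d)
  ii <- as.character(shared$i)
  jj <- as.character(shared$j)
  Si <- surface[ii]
  Sj <- surface[jj]
  if (any(Si <= 0) || any(Sj <= 0)) {
    stop("internal error: zero total surface with nonzero shared surface")
  }
  f <- (shared$surface / Si + shared$surface / Sj) * D[cbind(type[ii], type[jj])]
  J <- f * (sigma[jj] - sigma[ii])
  for (k in seq_along(J)) {
    d[ii[k]] <- d[ii[k]] + J[k]
    d[jj[k]] <- d[jj[k]] - J[k]
  }
  if (!is.null(constant)) d[constant[type[names(d)]]] <- 0
  d
}

#' Signal decay
#'
#' Applies the per-type relative factor and absolute subtraction, clamped at
#' zero: `sigma <- max(0, d * sigma - a)`.
#'
#' @param sigma Signal values.
#' @param rel Relative decay factor(s) `d`.
#' @param abs_ Absolute decay `a`.
#' @return Updated values.
#' @export
decay_signals <- function(sigma, rel = 1, abs_ = 0) {
  pmax(0, rel * sigma - abs_)
}

#' Two-cell equilibration demonstration
#'
#' Runs the closed two-cell flux recurrence: both concentrations converge to
#' the flux-weighted common mean, the gap shrinking geometrically with the
#' per-step factor `1 - 2*(S12/S1 + S12/S2)*D` for symmetric cells.
#'
#' @param S1,S2 Total surfaces of the two cells.
#' @param S12 Shared surface.
#' @param D Diffusion constant of the type pair.
#' @param sigma0 Initial concentrations (length 2).
#' @param steps Number of update steps.
#' @param constant Optional index (1 or 2) of a constant supplier.
#' @return Matrix `steps+1` x 2 of the concentration time series.
#' @export
equilibrate_demo <- function(S1, S2, S12, D, sigma0 = c(0, 1), steps = 50,
                             constant = NULL) {
  out <- matrix(0, steps + 1, 2)
  out[1, ] <- sigma0
  f <- (S12 / S1 + S12 / S2) * D
  s <- sigma0
  for (t in seq_len(steps)) {
    J <- f * (s[2] - s[1])
    d <- c(J, -J)
    if (!is.null(constant)) d[constant] <- 0
    s <- s + d
    out[t + 1, ] <- s
  }
  out
}

# ---- engine-internal actions -----------------------------------------------

diffusion_action <- function(sim) {
  if (sim$nchan == 0 || all(sim$types$diffusion == 0)) return(invisible(sim))
  field <- reassemble_field(sim$blocks, sim$layout)
  shared <- cpp_shared_surfaces(field, sim$wall)
  if (!nrow(shared)) return(invisible(sim))
  reg <- cell_registry(sim)
  ids <- c(0L, reg$ids)
  type <- stats::setNames(c(sim$liquid_type, reg$type), as.character(ids))
  surface <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (k in seq_len(nrow(shared))) {
    surface[as.character(shared$i[k])] <- surface[as.character(shared$i[k])] + shared$surface[k]
    surface[as.character(shared$j[k])] <- surface[as.character(shared$j[k])] + shared$surface[k]
  }
  sig <- cbind(sim$liquid_sig, if (length(reg$ids)) reg$sig else NULL)
  # explicit-update stability: sub-divide the step if any pair coupling is
  # too strong for a contraction
  fmax <- max((shared$surface / pmax(surface[as.character(shared$i)], 1e-12) +
               shared$surface / pmax(surface[as.character(shared$j)], 1e-12)) *
              sim$types$diffusion[cbind(type[as.character(shared$i)],
                                        type[as.character(shared$j)])])
  nsub <- max(1L, ceiling(fmax / 0.5))
  Dsub <- sim$types$diffusion / nsub
  const <- sim$types$constant_signal
  for (ch in seq_len(sim$nchan)) {
    sg <- stats::setNames(sig[ch, ], as.character(ids))
    for (it in seq_len(nsub)) {
      sg <- sg + diffuse_flux(shared, surface, sg, type, Dsub, constant = const)
    }
    sig[ch, ] <- sg
  }
  if (!const[sim$liquid_type]) sim$liquid_sig <- sig[, 1]
  for (i in seq_along(reg$ids)) {
    if (!const[reg$type[i]]) set_cell_signals(sim, reg$ids[i], sig[, i + 1])
  }
  invisible(sim)
}

decay_action <- function(sim) {
  if (sim$nchan == 0) return(invisible(sim))
  t <- sim$types
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    for (q in seq_along(rec$ids)) {
      ti <- rec$type[q]
      if (t$constant_signal[ti]) next
      rec$sig[, q] <- decay_signals(rec$sig[, q], t$decay_rel[, ti], t$decay_abs[, ti])
    }
    sim$recs[[b]] <- rec
  }
  if (!t$constant_signal[sim$liquid_type]) {
    sim$liquid_sig <- decay_signals(sim$liquid_sig, t$decay_rel[, sim$liquid_type],
                                    t$decay_abs[, sim$liquid_type])
  }
  invisible(sim)
}
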