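# cell_agents: agent-based single-cell events with the two-step
# determination / execution protocol.  Rates are evaluated once per full
# color cycle, in the block owning the cell's center of mass; execution
# happens one cycle later, simultaneously in all blocks holding the cell.

#' Division check for one cell
#'
#' Fires with probability `rate` if and only if the cell's volume exceeds
#' 0.9 of its effective target, its age is at least the minimum division
#' age, and every configured signal channel lies inside its division window.
#' On firing, a division plane with uniformly random orientation through the
#' center of mass is drawn and the daughter type is chosen by
#' [mutate_type()].
#'
#' @param cell List with `type` (type index), `v`, `v0` (effective target),
#'   `age` (in cycles), `sig` (signal vector), `com` (continuous center of
#'   mass).
#' @param types A [cell_types()] table.
#' @param u Uniform draw for the rate gate (injectable for testing).
#' @return `NULL`, or an event list `(kind = "divide", normal, point,
#'   daughter_type)`.
#' @export
check_division <- function(cell, types, u = stats::runif(1)) {
  t <- cell$type
  if (types$excluded_from_division[t] || types$div_rate[t] <= 0) return(NULL)
  if (cell$v <= 0.9 * cell$v0) return(NULL)
  if (cell$age < types$div_min_age[t]) return(NULL)
  if (length(cell$sig)) {
    if (any(cell$sig < types$div_sig_min[, t]) || any(cell$sig > types$div_sig_max[, t])) {
      return(NULL)
    }
  }
  if (u >= types$div_rate[t]) return(NULL)
  n <- stats::rnorm(3)
  n <- n / sqrt(sum(n^2))
  list(kind = "divide", normal = n, point = cell$com,
       daughter_type = mutate_type(t, types))
}

#' Mutation draw at division
#'
#' With probability `mutation_rate` the daughter type is drawn from the
#' mother type's row of the mutation transition matrix; otherwise the
#' daughter inherits the mother's type.
#'
#' @param mother_type Type index.
#' @param types A [cell_types()] table.
#' @param u Uniform draw for the mutation gate.
#' @return Type index of the daughter.
#' @export
mutate_type <- function(mother_type, types, u = stats::runif(1)) {
  if (u >= types$mut_rate[mother_type]) return(mother_type)
  sample.int(length(types$name), 1L, prob = types$mutation[mother_type, ])
}

#' Death check for one cell
#'
#' Fires with probability `rate` when the cell is starved (every configured
#' signal channel inside its death window, e.g. nutrient below the death
#' threshold) and old enough; additionally fires with the reduced background
#' rate `rate/1000` regardless of the signal gate (natural cell death; the
#' age gate still applies).
#'
#' @inheritParams check_division
#' @param u Two uniform draws (starvation path, background path).
#' @return `NULL` or an event list `(kind = "die")`.
#' @export
check_death <- function(cell, types, u = stats::runif(2)) {
  t <- cell$type
  if (types$death_rate[t] <= 0) return(NULL)
  if (cell$age < types$death_min_age[t]) return(NULL)
  starved <- TRUE
  if (length(cell$sig)) {
    starved <- all(cell$sig >= types$death_sig_min[, t]) &&
      all(cell$sig <= types$death_sig_max[, t]) &&
      any(is.finite(types$death_sig_min[, t]) | is.finite(types$death_sig_max[, t]))
  } else {
    starved <- FALSE
  }
  if (starved && u[1] < types$death_rate[t]) return(list(kind = "die"))
  if (u[2] < types$death_rate[t] / 1000) return(list(kind = "die"))
  NULL
}

#' Per-cycle change of the effective targets
#'
#' Non-apoptotic cells grow (or shrink) their effective target volume and
#' surface at the constant per-cycle rate of their type.  Apoptotic cells
#' instead follow the linear shrinking law `V0_eff = max(0, V0 - chi * age)`
#' with the target surface scaled as `(V0_eff / V0)^(2/3) * S0`, keeping the
#' shrinking cell compact.
#'
#' @param targets List with `v0`, `s0` (current effective targets).
#' @param type Type index of the cell.
#' @param types A [cell_types()] table.
#' @param age Cell age in cycles (used for apoptotic types).
#' @param apoptotic Is the cell of an apoptotic type?
#' @return Updated list `(v0, s0)`.
#' @export
apply_size_change <- function(targets, type, types, age = 0, apoptotic = FALSE) {
  if (apoptotic) {
    V0 <- types$V0[type]
    v0 <- max(0, V0 - types$death_chi[type] * age)
    s0 <- if (V0 > 0) types$S0[type] * (v0 / V0)^(2 / 3) else 0
    list(v0 = v0, s0 = s0)
  } else {
    list(v0 = targets$v0 + types$size_change_V[type],
         s0 = targets$s0 + types$size_change_S[type])
  }
}

# ---- engine-internal event drivers -----------------------------------------

determine_events <- function(sim) {
  reg <- cell_registry(sim)
  nc <- n_colors(sim)
  cyc <- current_cycle(sim)
  for (i in seq_along(reg$ids)) {
    id <- reg$ids[i]
    t <- reg$type[i]
    if (reg$v[i] <= 0) next
    if (sim$types$is_liquid[t] || sim$types$is_solid[t] || sim$is_apoptotic[t]) next
    if (!is.null(reg$pending[[i]])) next
    comv <- com_voxel(reg$cx[i], reg$cy[i], reg$cz[i], reg$v[i], sim$cfg$domain$size)
    b <- owner_block(sim, comv)
    cell <- list(type = t, v = reg$v[i], v0 = reg$v0[i],
                 age = (sim$mcs - reg$birth[i]) / nc,
                 sig = if (sim$nchan) reg$sig[, i] else numeric(0),
                 com = c(reg$cx[i], reg$cy[i], reg$cz[i]) / reg$v[i])
    ev <- check_division(cell, sim$types)
    if (!is.null(ev)) {
      sim$next_daughter[b] <- sim$next_daughter[b] + 1L
      ev$daughter_id <- 1000000L * b + sim$next_daughter[b]
      ev$det_cycle <- cyc
    } else {
      ev <- check_death(cell, sim$types)
      if (!is.null(ev)) ev$det_cycle <- cyc
    }
    if (!is.null(ev)) {
      rec <- sim$recs[[b]]
      q <- match(id, rec$ids)
      if (!is.na(q)) {
        rec$pending[[q]] <- ev
        sim$recs[[b]] <- rec
      }
    }
  }
  invisible(sim)
}

execute_events <- function(sim) {
  reg <- cell_registry(sim)
  cyc <- current_cycle(sim)
  for (i in seq_along(reg$ids)) {
    ev <- reg$pending[[i]]
    if (is.null(ev) || ev$det_cycle >= cyc) next
    if (ev$kind == "divide") {
      execute_division(sim, reg$ids[i])
    } else if (ev$kind == "die") {
      execute_death(sim, reg$ids[i])
    }
  }
  invisible(sim)
}

#' Execute a determined division
#'
#' Splits the cell along the plane fixed at determination time: voxels with
#' non-negative signed distance keep the mother id, the rest receive a fresh
#' globally unique id (allocated from the determining block's range).  Both
#' daughters are re-measured from the field, their age is reset to zero and
#' the mother's signal content is split in proportion to the daughter
#' volumes.  A plane that leaves one side empty aborts the division.
#'
#' @param sim A [cpm_sim()] environment.
#' @param cell_id Id of a cell holding a pending division event.
#' @return Invisibly, `c(mother, daughter)` ids, or `NULL` if aborted.
#' @export
execute_division <- function(sim, cell_id) {
  reg <- cell_registry(sim)
  i <- match(cell_id, reg$ids)
  ev <- reg$pending[[i]]
  if (is.null(ev) || ev$kind != "divide") stop("no pending division for cell ", cell_id)
  sh <- sim$layout$shape
  moved <- vector("list", sim$layout$n_blocks)
  n_keep <- 0L
  n_move <- 0L
  for (b in seq_len(sim$layout$n_blocks)) {
    interior <- sim$blocks[[b]][1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])]
    w <- which(interior == cell_id, arr.ind = TRUE)
    if (!nrow(w)) next
    g <- sweep(w - 1L, 2, -sim$layout$origins[b, ])
    side <- (g - matrix(ev$point, nrow(g), 3, byrow = TRUE)) %*% ev$normal >= 0
    moved[[b]] <- w[!side, , drop = FALSE]
    n_keep <- n_keep + sum(side)
    n_move <- n_move + sum(!side)
  }
  clear_pending(sim, cell_id)
  if (n_keep == 0L || n_move == 0L) {
    sim$stats$aborted_divisions <- sim$stats$aborted_divisions + 1L
    return(invisible(NULL))
  }
  for (b in seq_len(sim$layout$n_blocks)) {
    w <- moved[[b]]
    if (is.null(w) || !nrow(w)) next
    idx <- cbind(w[, 1] + 1L, w[, 2] + 1L, w[, 3] + 1L)
    sim$blocks[[b]][idx] <- ev$daughter_id
  }
  halo_sync(sim$blocks, sim$layout, sim$wall)
  t <- sim$types
  for (spec in list(list(id = cell_id, type = reg$type[i], share = NA),
                    list(id = ev$daughter_id, type = ev$daughter_type, share = NA))) {
    remeasure_cell(sim, spec$id, spec$type, birth = sim$mcs)
  }
  # split the mother's signal content in proportion to volume
  if (sim$nchan) {
    vm <- cell_field_volume(sim, cell_id)
    vd <- cell_field_volume(sim, ev$daughter_id)
    sig <- reg$sig[, i] * c(vm, vd)[1] / (vm + vd)
    sigd <- reg$sig[, i] * vd / (vm + vd)
    set_cell_signals(sim, cell_id, sig)
    set_cell_signals(sim, ev$daughter_id, sigd)
  }
  sim$stats$births <- sim$stats$births + 1L
  invisible(c(cell_id, ev$daughter_id))
}

#' Execute a determined death
#'
#' Switches the cell to its type's apoptotic type with age reset; from then
#' on its effective target volume shrinks linearly (see
#' [apply_size_change()]) until the cell vanishes and its record is removed
#' everywhere.  Types without an apoptotic type are deleted outright.
#'
#' @inheritParams execute_division
#' @return `sim`, invisibly.
#' @export
execute_death <- function(sim, cell_id) {
  reg <- cell_registry(sim)
  i <- match(cell_id, reg$ids)
  t <- reg$type[i]
  at <- sim$types$apoptotic_type[t]
  clear_pending(sim, cell_id)
  if (at == 0L) {
    delete_cells(sim, cell_id)
    return(invisible(sim))
  }
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    q <- match(cell_id, rec$ids)
    if (!is.na(q)) {
      rec$type[q] <- at
      rec$birth[q] <- sim$mcs
      rec$v0[q] <- sim$types$V0[at]
      rec$s0[q] <- sim$types$S0[at]
      sim$recs[[b]] <- rec
    }
  }
  invisible(sim)
}

clear_pending <- function(sim, cell_id) {
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    q <- match(cell_id, rec$ids)
    if (!is.na(q) && !is.null(rec$pending[[q]])) {
      rec$pending[q] <- list(NULL)
      sim$recs[[b]] <- rec
    }
  }
}

cell_field_volume <- function(sim, id) {
  sh <- sim$layout$shape
  v <- 0L
  for (b in seq_len(sim$layout$n_blocks)) {
    v <- v + sum(sim$blocks[[b]][1 + seq_len(sh[1]), 1 + seq_len(sh[2]),
                                 1 + seq_len(sh[3])] == id)
  }
  v
}

set_cell_signals <- function(sim, id, sig) {
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    q <- match(id, rec$ids)
    if (!is.na(q)) {
      rec$sig[, q] <- sig
      sim$recs[[b]] <- rec
    }
  }
}

# Measure a cell from the reassembled field and install/update its record in
# every block where it has presence (used after event execution).
remeasure_cell <- function(sim, id, type, birth) {
  field <- reassemble_field(sim$blocks, sim$layout)
  v <- sum(field == id)
  s <- if (sim$metric == 1) cpp_march_surface(field, id)
       else cpp_side_surface(field, id, sim$wall)
  w <- which(field == id, arr.ind = TRUE) - 1L
  cx <- sum(w[, 1]); cy <- sum(w[, 2]); cz <- sum(w[, 3])
  t <- sim$types
  for (b in seq_len(sim$layout$n_blocks)) {
    pres <- cpp_block_presence(sim$blocks[[b]], as.integer(sim$layout$shape), sim$wall)
    present <- id %in% c(pres$interior, pres$halo)
    rec <- sim$recs[[b]]
    q <- match(id, rec$ids)
    if (present && is.na(q)) {
      rec$ids <- c(rec$ids, id)
      rec$type <- c(rec$type, type)
      rec$birth <- c(rec$birth, birth)
      rec$v <- c(rec$v, v); rec$s <- c(rec$s, s)
      rec$cx <- c(rec$cx, cx); rec$cy <- c(rec$cy, cy); rec$cz <- c(rec$cz, cz)
      rec$v0 <- c(rec$v0, t$V0[type]); rec$s0 <- c(rec$s0, t$S0[type])
      rec$sig <- cbind(rec$sig, t$start_signal[, type])
      rec$pending <- c(rec$pending, list(NULL))
      sim$recs[[b]] <- rec
    } else if (!is.na(q)) {
      rec$type[q] <- type
      rec$birth[q] <- birth
      rec$v[q] <- v; rec$s[q] <- s
      rec$cx[q] <- cx; rec$cy[q] <- cy; rec$cz[q] <- cz
      rec$v0[q] <- t$V0[type]; rec$s0[q] <- t$S0[type]
      if (!present) {
        sim$recs[[b]] <- subset_record(rec, rec$ids != id)
      } else {
        sim$recs[[b]] <- rec
      }
    }
  }
}

size_change_action <- function(sim) {
  nc <- n_colors(sim)
  gone <- integer(0)
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    for (q in seq_along(rec$ids)) {
      t <- rec$type[q]
      if (rec$ids[q] == 0L || sim$types$is_liquid[t] || sim$types$is_solid[t]) next
      if (sim$is_apoptotic[t]) {
        age <- (sim$mcs - rec$birth[q]) / nc
        tg <- apply_size_change(list(v0 = rec$v0[q], s0 = rec$s0[q]), t, sim$types,
                                age = age, apoptotic = TRUE)
        rec$v0[q] <- tg$v0; rec$s0[q] <- tg$s0
        if (rec$v[q] <= 0) gone <- c(gone, rec$ids[q])
      } else if (sim$types$size_change_V[t] != 0 || sim$types$size_change_S[t] != 0) {
        tg <- apply_size_change(list(v0 = rec$v0[q], s0 = rec$s0[q]), t, sim$types)
        rec$v0[q] <- tg$v0; rec$s0[q] <- tg$s0
      }
    }
    sim$recs[[b]] <- rec
  }
  if (length(gone)) delete_cells(sim, unique(gone))
  invisible(sim)
}
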