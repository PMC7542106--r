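# sweep_engine + simulation state: Monte Carlo sweeps, per-MCS commits,
# the per-cycle action schedule.

#' Visitor-pattern sample positions
#'
#' Linear traversal of the active color with random jump widths: jumps are
#' i.i.d. uniform on `{1, ..., 2*mean_step - 1}` (mean `mean_step`), and the
#' first selected index is drawn from the stationary-delay distribution of
#' the renewal process, so every index is selected with probability exactly
#' `1/mean_step`.
#'
#' @param active_count Length of the active-voxel sequence.
#' @param mean_step Mean jump width (>= 1); `1` visits every index.
#' @return Strictly increasing 0-based indices into the active-voxel order.
#' @export
visitor_positions <- function(active_count, mean_step) {
  if (mean_step < 1) stop("configuration error: mean_step must be >= 1")
  if (mean_step == 1) return(seq_len(active_count) - 1L)
  M <- 2L * mean_step - 1L
  # stationary delay: P(k) proportional to (2m-1-k), k = 0..2m-2
  w <- (M:1)
  pos <- sample.int(M, 1L, prob = w) - 1L
  out <- integer(0)
  while (pos < active_count) {
    out <- c(out, pos)
    pos <- pos + sample.int(M, 1L)
  }
  out
}

new_record_set <- function(nchan) {
  list(ids = 0L, type = 1L, birth = 0, v = 0, s = 0, cx = 0, cy = 0, cz = 0,
       v0 = 0, s0 = 0, sig = matrix(0, nchan, 1), pending = list(NULL))
}

#' Create a simulation from a configuration
#'
#' Builds the block fields from the configured placements, measures every
#' cell (volume by the configured method, surface under the configured
#' metric), seeds the per-block RNG streams and replicates the per-cell
#' records (ACD) into every block where the cell has voxels or halo
#' presence.
#'
#' @param config A [cpm_config()] object (or a plain list accepted by it).
#' @param seed Optional integer overriding `domain.seed` from the config.
#' @return A simulation environment of class `cpm_sim`.
#' @export
cpm_sim <- function(config, seed = NULL) {
  if (!inherits(config, "cpm_config")) config <- cpm_config(config)
  sim <- new.env(parent = emptyenv())
  sim$cfg <- config
  sim$types <- config$types
  sim$wall <- cpm_wall_id()
  sim$layout <- block_layout(config$domain$size, config$domain$blocks)
  sim$scheme <- config$scheme
  sim$metric <- if (config$domain$metric == "marching") 1L else 0L
  sim$volume_method <- config$domain$volume_method
  sim$mean_step <- config$domain$mean_step
  sim$temperature <- config$domain$temperature
  sim$seed <- if (is.null(seed)) config$domain$seed else as.integer(seed)
  sim$mcs <- 0L
  sim$nchan <- length(config$signals)
  sim$liquid_type <- which(config$types$is_liquid)
  sim$is_apoptotic <- seq_along(config$types$name) %in%
    config$types$apoptotic_type[config$types$apoptotic_type > 0]
  sim$lamv <- as.numeric(config$types$lambda_V)
  sim$lams <- as.numeric(config$types$lambda_S)
  sim$type_solid <- as.integer(config$types$is_solid)
  sim$type_liquid <- as.integer(config$types$is_liquid)
  sim$adhesion <- config$types$adhesion
  sim$rng <- lapply(seq_len(sim$layout$n_blocks), function(b) {
    cpp_rng_seed(sim$seed, b - 1L)
  })
  sim$mods <- rep(list(list()), sim$layout$n_blocks)
  sim$nbrs <- lapply(seq_len(sim$layout$n_blocks), function(b) {
    vapply(block_neighbors(sim$layout, b), function(x) x$index, integer(1))
  })
  # per block: the six axis-aligned neighbor indices (-x,+x,-y,+y,-z,+z), NA at edges
  sim$axis_nbrs <- lapply(seq_len(sim$layout$n_blocks), function(b) {
    nb <- block_neighbors(sim$layout, b)
    out <- rep(NA_integer_, 6)
    dirs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
    for (x in nb) {
      for (q in 1:6) if (identical(as.integer(x$dir), as.integer(dirs[[q]]))) out[q] <- x$index
    }
    out
  })
  sim$next_daughter <- rep(0L, sim$layout$n_blocks)
  sim$audit <- FALSE
  sim$audit_violations <- list()
  sim$skip_exchange_once <- FALSE
  sim$stats <- list(attempts = 0, accepts = 0, cleaned = 0, births = 0, deaths = 0,
                    aborted_divisions = 0)

  init <- init_field(config, sim$layout)
  sim$blocks <- blocks_from_field(init$field, sim$layout, sim$wall)
  sim$init_ids <- init$ids

  # global measurement of the initial cells, then per-block replication
  global <- init$field
  n <- length(init$ids)
  t <- config$types
  reg <- list(ids = init$ids, type = init$type, birth = rep(0, n),
              v = numeric(n), s = numeric(n),
              cx = numeric(n), cy = numeric(n), cz = numeric(n),
              v0 = t$V0[init$type], s0 = t$S0[init$type],
              sig = t$start_signal[, init$type, drop = FALSE],
              pending = rep(list(NULL), n))
  for (i in seq_len(n)) {
    id <- init$ids[i]
    reg$v[i] <- sum(global == id)
    reg$s[i] <- if (sim$metric == 1) cpp_march_surface(global, id)
                else cpp_side_surface(global, id, sim$wall)
    w <- which(global == id, arr.ind = TRUE) - 1L
    reg$cx[i] <- sum(w[, 1]); reg$cy[i] <- sum(w[, 2]); reg$cz[i] <- sum(w[, 3])
  }
  sim$liquid_sig <- t$start_signal[, sim$liquid_type]
  sim$recs <- lapply(seq_len(sim$layout$n_blocks), function(b) {
    pres <- cpp_block_presence(sim$blocks[[b]], as.integer(sim$layout$shape), sim$wall)
    need <- setdiff(sort(unique(c(pres$interior, pres$halo))), 0L)
    rec <- new_record_set(sim$nchan)
    rec$type[1] <- sim$liquid_type
    if (length(need)) {
      m <- match(need, reg$ids)
      rec$ids <- c(0L, need)
      rec$type <- c(sim$liquid_type, reg$type[m])
      rec$birth <- c(0, reg$birth[m])
      rec$v <- c(0, reg$v[m]); rec$s <- c(0, reg$s[m])
      rec$cx <- c(0, reg$cx[m]); rec$cy <- c(0, reg$cy[m]); rec$cz <- c(0, reg$cz[m])
      rec$v0 <- c(0, reg$v0[m]); rec$s0 <- c(0, reg$s0[m])
      rec$sig <- cbind(sim$liquid_sig, reg$sig[, m, drop = FALSE])
      rec$pending <- rep(list(NULL), length(need) + 1L)
    }
    rec
  })
  class(sim) <- "cpm_sim"
  sim
}

n_colors <- function(sim) sim$scheme$n_colors

current_cycle <- function(sim) sim$mcs %/% n_colors(sim)

#' One Monte Carlo sweep (one color) plus its commit
#'
#' Sweeps the active checkerboard color over every block, then commits:
#' halo exchange, ACD (cell-data) exchange folding all per-block deltas into
#' the replicated absolute values, color advance.  When the commit completes
#' a full color cycle, the per-cycle actions of the configured schedule run
#' (sanity, cell events, size change, signal transport, writers).
#'
#' @param sim A [cpm_sim()] environment.
#' @return Invisibly, a list with sweep statistics (`attempts`, `accepts`).
#' @export
step_mcs <- function(sim) {
  color <- sim$mcs %% n_colors(sim)
  B <- sim$layout$n_blocks
  ids_list <- vector("list", B); type_list <- vector("list", B)
  v_list <- vector("list", B); s_list <- vector("list", B)
  v0_list <- vector("list", B); s0_list <- vector("list", B)
  for (b in seq_len(B)) {
    rec <- sim$recs[[b]]
    ids_list[[b]] <- rec$ids
    type_list[[b]] <- rec$type - 1L
    v_list[[b]] <- rec$v; s_list[[b]] <- rec$s
    v0_list[[b]] <- rec$v0; s0_list[[b]] <- rec$s0
  }
  res <- cpp_run_mcs(sim$blocks, sim$layout$origins, as.integer(sim$layout$shape),
                     as.integer(sim$layout$grid), n_colors(sim), as.integer(color),
                     as.integer(sim$scheme$stencil), sim$metric, sim$mean_step,
                     sim$temperature, sim$wall, ids_list, type_list, v_list, s_list,
                     v0_list, s0_list, sim$lamv, sim$lams, sim$adhesion,
                     sim$type_solid, sim$type_liquid, sim$rng,
                     TRUE, TRUE)
  att <- sum(vapply(res$deltas, function(d) d$attempts, numeric(1)))
  acc <- sum(vapply(res$deltas, function(d) d$accepts, numeric(1)))
  sim$stats$attempts <- sim$stats$attempts + att
  sim$stats$accepts <- sim$stats$accepts + acc
  if (isTRUE(sim$skip_exchange_once)) {
    sim$skip_exchange_once <- FALSE   # fault injection for the audit tests
  } else {
    acd_exchange(sim, res$deltas, res$presence)
  }
  sim$mcs <- sim$mcs + 1L
  if (sim$audit) audit_commit(sim)
  if (color == n_colors(sim) - 1L) run_cycle_actions(sim)
  invisible(list(attempts = att, accepts = acc))
}

#' Run whole color cycles
#'
#' @param sim A [cpm_sim()] environment.
#' @param cycles Number of full color cycles (each `n_colors` sweeps).
#' @return `sim`, invisibly.
#' @export
run_cycles <- function(sim, cycles) {
  for (i in seq_len(cycles * n_colors(sim))) step_mcs(sim)
  invisible(sim)
}

# stencil argument passed as bool above; keep engine call sites tidy
# (cpp_run_mcs takes the stencil as 27/7)

#' Cell-data (ACD) exchange
#'
#' Folds the per-block sweep deltas into the replicated per-cell absolute
#' values, exactly as a message exchange with the 26 neighbor blocks would:
#' each block's message carries its cells' committed absolutes, this sweep's
#' deltas, pending events, interior-presence flags and Message-of-Death
#' notices.  Records are created for cells newly entering a block (seeded
#' from a neighbor's absolutes plus all deltas) and dropped for cells no
#' longer in the block or halo.  Oversized cells (reported with interior
#' presence from opposite sides of an axis) trigger a Message of Death,
#' which is forwarded for two commits and then executes a simultaneous
#' deletion.
#'
#' @param sim A [cpm_sim()] environment.
#' @param deltas Per-block delta lists (`dv`, `ds`, `dcx`, `dcy`, `dcz`
#'   aligned with the block's record ids); zeros if omitted.
#' @param presence Per-block presence lists (`interior`, `halo` id vectors);
#'   recomputed if omitted.
#' @return `sim`, invisibly.
#' @export
acd_exchange <- function(sim, deltas = NULL, presence = NULL) {
  B <- sim$layout$n_blocks
  recs <- sim$recs
  nchan <- sim$nchan
  if (is.null(presence)) {
    presence <- lapply(seq_len(B), function(b) {
      cpp_block_presence(sim$blocks[[b]], as.integer(sim$layout$shape), sim$wall)
    })
  }
  if (is.null(deltas)) {
    deltas <- lapply(recs, function(rec) {
      z <- numeric(length(rec$ids))
      list(dv = z, ds = z, dcx = z, dcy = z, dcz = z)
    })
  }
  newrecs <- vector("list", B)
  newmods <- vector("list", B)
  any_mods <- any(vapply(sim$mods, length, integer(1)) > 0L)
  has_delta <- vapply(deltas, function(d) {
    any(d$dv != 0) || any(d$ds != 0) || any(d$dcx != 0) ||
      any(d$dcy != 0) || any(d$dcz != 0)
  }, logical(1))
  for (r in seq_len(B)) {
    pres <- presence[[r]]
    need <- sort.int(unique(c(0L, pres$interior, pres$halo)))
    rec <- recs[[r]]
    if (identical(need, rec$ids)) {   # common case: no entrants, no leavers
      out <- rec
      unknown <- logical(length(need))
    } else {
      k <- length(need)
      out <- list(ids = need, type = integer(k), birth = numeric(k),
                  v = numeric(k), s = numeric(k), cx = numeric(k), cy = numeric(k),
                  cz = numeric(k), v0 = numeric(k), s0 = numeric(k),
                  sig = matrix(0, nchan, k), pending = rep(list(NULL), k))
      m_own <- match(need, rec$ids)
      known <- !is.na(m_own)
      if (any(known)) {
        i <- m_own[known]
        out$type[known] <- rec$type[i]; out$birth[known] <- rec$birth[i]
        out$v[known] <- rec$v[i]; out$s[known] <- rec$s[i]
        out$cx[known] <- rec$cx[i]; out$cy[known] <- rec$cy[i]; out$cz[known] <- rec$cz[i]
        out$v0[known] <- rec$v0[i]; out$s0[known] <- rec$s0[i]
        if (nchan) out$sig[, known] <- rec$sig[, i, drop = FALSE]
        out$pending[known] <- rec$pending[i]
      }
      unknown <- !known
    }
    sender_idx <- sim$nbrs[[r]]
    for (sb in sender_idx) {
      if (!any(unknown)) break
      mrec <- recs[[sb]]
      mm <- match(need, mrec$ids)
      hit <- unknown & !is.na(mm)
      if (any(hit)) {
        i <- mm[hit]
        out$type[hit] <- mrec$type[i]; out$birth[hit] <- mrec$birth[i]
        out$v[hit] <- mrec$v[i]; out$s[hit] <- mrec$s[i]
        out$cx[hit] <- mrec$cx[i]; out$cy[hit] <- mrec$cy[i]; out$cz[hit] <- mrec$cz[i]
        out$v0[hit] <- mrec$v0[i]; out$s0[hit] <- mrec$s0[i]
        if (nchan) out$sig[, hit] <- mrec$sig[, i, drop = FALSE]
        unknown[hit] <- FALSE
      }
    }
    if (any(unknown & need != 0L)) {
      stop("internal consistency error: no ACD source for cellID ",
           need[which(unknown & need != 0L)[1]], " in block ", r)
    }
    # accumulate the deltas of every block that can hold the cell: own + 26
    for (sb in c(r, sender_idx)) {
      if (!has_delta[sb]) next
      d <- deltas[[sb]]
      mm <- match(recs[[sb]]$ids, need)
      ok <- which(!is.na(mm))
      if (length(ok)) {
        j <- mm[ok]
        out$v[j] <- out$v[j] + d$dv[ok]
        out$s[j] <- out$s[j] + d$ds[ok]
        out$cx[j] <- out$cx[j] + d$dcx[ok]
        out$cy[j] <- out$cy[j] + d$dcy[ok]
        out$cz[j] <- out$cz[j] + d$dcz[ok]
      }
    }
    # adopt pending events determined elsewhere
    for (sb in sender_idx) {
      pp <- recs[[sb]]$pending
      for (q in seq_along(pp)) {
        if (is.null(pp[[q]])) next
        j <- match(recs[[sb]]$ids[q], need)
        if (!is.na(j) && is.null(out$pending[[j]])) out$pending[[j]] <- pp[[q]]
      }
    }
    # liquid carries no tracked volume/surface
    out$v[1] <- 0; out$s[1] <- 0; out$cx[1] <- 0; out$cy[1] <- 0; out$cz[1] <- 0
    out$type[1] <- sim$liquid_type
    if (nchan) out$sig[, 1] <- sim$liquid_sig
    newrecs[[r]] <- out

    # Message-of-Death bookkeeping: opposite-side detection + forwarding
    an <- sim$axis_nbrs[[r]]
    created <- integer(0)
    for (ax in 1:3) {
      lo <- an[2 * ax - 1]; hi <- an[2 * ax]
      if (is.na(lo) || is.na(hi)) next
      pl <- presence[[lo]]$interior
      ph <- presence[[hi]]$interior
      if (length(pl) > 1L && length(ph) > 1L) {
        created <- c(created, setdiff(intersect(pl, ph), 0L))
      }
    }
    mods <- list()
    if (any_mods || length(created)) {
      dec <- function(mlist) {
        for (m in mlist) {
          if (m$hops <= 0L) next
          key <- as.character(m$id)
          h <- m$hops - 1L
          if (is.null(mods[[key]]) || mods[[key]]$hops < h) {
            mods[[key]] <- list(id = m$id, hops = h)
          }
        }
        mods
      }
      for (m in sim$mods[[r]]) {
        key <- as.character(m$id)
        mods[[key]] <- list(id = m$id, hops = m$hops - 1L)
      }
      for (sb in sender_idx) mods <- dec(sim$mods[[sb]])
      # a persisting oversize condition must not refresh an in-flight MoD,
      # otherwise the two-step countdown would never complete
      for (id in created) {
        key <- as.character(id)
        if (is.null(mods[[key]])) mods[[key]] <- list(id = id, hops = 2L)
      }
    }
    newmods[[r]] <- mods
  }
  sim$recs <- newrecs
  sim$mods <- newmods
  # the countdown is lockstep: every copy of a MoD reaches zero hops at the
  # same commit, so deletion happens simultaneously in all reachable blocks
  del <- integer(0)
  for (r in seq_len(B)) {
    for (m in sim$mods[[r]]) if (m$hops <= 0L) del <- c(del, m$id)
  }
  del <- unique(del)
  if (length(del)) {
    delete_cells(sim, del)
    for (r in seq_len(B)) {
      keep <- !vapply(sim$mods[[r]], function(m) m$id %in% del, logical(1))
      sim$mods[[r]] <- sim$mods[[r]][keep]
    }
  }
  invisible(sim)
}

# Remove cells everywhere: voxels to liquid, records and pending dropped.
delete_cells <- function(sim, ids) {
  sh <- sim$layout$shape
  for (b in seq_len(sim$layout$n_blocks)) {
    blk <- sim$blocks[[b]]
    interior <- blk[1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])]
    hit <- interior %in% ids
    if (any(hit)) {
      interior[hit] <- 0L
      sim$blocks[[b]][1 + seq_len(sh[1]), 1 + seq_len(sh[2]), 1 + seq_len(sh[3])] <- interior
    }
    rec <- sim$recs[[b]]
    keep <- !(rec$ids %in% ids)
    if (!all(keep)) sim$recs[[b]] <- subset_record(rec, keep)
  }
  halo_sync(sim$blocks, sim$layout, sim$wall)
  sim$stats$deaths <- sim$stats$deaths + length(ids)
  invisible(sim)
}

subset_record <- function(rec, keep) {
  list(ids = rec$ids[keep], type = rec$type[keep], birth = rec$birth[keep],
       v = rec$v[keep], s = rec$s[keep], cx = rec$cx[keep], cy = rec$cy[keep],
       cz = rec$cz[keep], v0 = rec$v0[keep], s0 = rec$s0[keep],
       sig = rec$sig[, keep, drop = FALSE], pending = rec$pending[keep])
}

# Apply a delta for one cell to every block holding its record.
apply_cell_delta_global <- function(sim, id, dv = 0, ds = 0, dcx = 0, dcy = 0, dcz = 0) {
  for (b in seq_len(sim$layout$n_blocks)) {
    rec <- sim$recs[[b]]
    i <- match(id, rec$ids)
    if (!is.na(i)) {
      rec$v[i] <- rec$v[i] + dv
      rec$s[i] <- rec$s[i] + ds
      rec$cx[i] <- rec$cx[i] + dcx
      rec$cy[i] <- rec$cy[i] + dcy
      rec$cz[i] <- rec$cz[i] + dcz
      sim$recs[[b]] <- rec
    }
  }
}

# Global registry: one row per live cell (union over blocks; blocks agree).
cell_registry <- function(sim) {
  ids <- sort(unique(unlist(lapply(sim$recs, function(r) r$ids))))
  ids <- setdiff(ids, 0L)
  n <- length(ids)
  reg <- list(ids = ids, type = integer(n), birth = numeric(n), v = numeric(n),
              s = numeric(n), cx = numeric(n), cy = numeric(n), cz = numeric(n),
              v0 = numeric(n), s0 = numeric(n),
              sig = matrix(0, sim$nchan, n), pending = rep(list(NULL), n))
  for (i in seq_len(n)) {
    for (b in seq_len(sim$layout$n_blocks)) {
      j <- match(ids[i], sim$recs[[b]]$ids)
      if (!is.na(j)) {
        rec <- sim$recs[[b]]
        reg$type[i] <- rec$type[j]; reg$birth[i] <- rec$birth[j]
        reg$v[i] <- rec$v[j]; reg$s[i] <- rec$s[j]
        reg$cx[i] <- rec$cx[j]; reg$cy[i] <- rec$cy[j]; reg$cz[i] <- rec$cz[j]
        reg$v0[i] <- rec$v0[j]; reg$s0[i] <- rec$s0[j]
        if (sim$nchan) reg$sig[, i] <- rec$sig[, j]
        reg$pending[i] <- rec$pending[j]
        break
      }
    }
  }
  reg
}

# Integer CoM voxel of a cell (global 0-based), NA-free for v > 0.
com_voxel <- function(cx, cy, cz, v, size) {
  p <- round(c(cx, cy, cz) / v)
  as.integer(pmin(pmax(p, 0), size - 1))
}

owner_block <- function(sim, comv) {
  sh <- sim$layout$shape
  bc <- comv %/% sh
  as.integer(1L + bc[1] + sim$layout$grid[1] * (bc[2] + sim$layout$grid[2] * bc[3]))
}

run_cycle_actions <- function(sim) {
  cyc <- current_cycle(sim)  # cycle just completed (1-based count = cyc)
  for (action in sim$cfg$schedule) {
    switch(action,
      sanity = if (cyc %% sim$cfg$sanity$every == 0) sanity_sweep(sim),
      execute_events = execute_events(sim),
      determine_events = determine_events(sim),
      size_change = size_change_action(sim),
      diffusion = diffusion_action(sim),
      decay = decay_action(sim),
      output = output_action(sim))
  }
  invisible(sim)
}
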