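# sim_io (configuration): JSON config loading, validation, type tables.

cfg_err <- function(path, msg) {
  stop("configuration error at '", path, "': ", msg, call. = FALSE)
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
int_or <- function(x, default) if (is.null(x)) default else as.integer(x)
lgl_or <- function(x, default) if (is.null(x)) default else isTRUE(x)
chr_or <- function(x, default) if (is.null(x)) default else as.character(x)

# channel-keyed map (named list) -> numeric vector over channels with default
sig_vec <- function(map, channels, default, path) {
  out <- rep(default, length(channels))
  names(out) <- channels
  if (is.null(map)) return(out)
  for (nm in names(map)) {
    if (!nm %in% channels) cfg_err(paste0(path, ".", nm), "unknown signal channel")
    out[nm] <- as.numeric(map[[nm]])
  }
  out
}

#' Normalised cell-type parameter table
#'
#' Builds the per-type parameter block (targets, couplings, adhesion and
#' diffusion matrices, signal handling, division, mutation and death rules)
#' from the `celltypes` section of a configuration.  Exactly one type must be
#' flagged `liquid` (the background medium); `solid` types take no part in
#' the Potts dynamics but adhere and pass signals.
#'
#' @param celltypes Named list of per-type parameter lists (see the shipped
#'   configuration schema in `inst/extdata/config-schema.md`).
#' @param channels Character vector of signal channel names.
#' @return An object of class `cpm_types`: parallel vectors/matrices indexed
#'   by type.
#' @export
cell_types <- function(celltypes, channels = character()) {
  if (is.null(celltypes) || length(celltypes) == 0) {
    cfg_err("celltypes", "at least one cell type is required")
  }
  nm <- names(celltypes)
  if (is.null(nm) || any(nm == "")) cfg_err("celltypes", "types must be named")
  n <- length(nm)
  nc <- length(channels)
  t <- list(
    name = nm, channels = channels,
    V0 = numeric(n), S0 = numeric(n), lambda_V = numeric(n), lambda_S = numeric(n),
    size_change_V = numeric(n), size_change_S = numeric(n),
    is_liquid = logical(n), is_solid = logical(n),
    constant_signal = logical(n),
    start_signal = matrix(0, nc, n, dimnames = list(channels, nm)),
    decay_rel = matrix(1, nc, n, dimnames = list(channels, nm)),
    decay_abs = matrix(0, nc, n, dimnames = list(channels, nm)),
    div_rate = numeric(n), div_min_age = numeric(n),
    div_sig_min = matrix(-Inf, nc, n, dimnames = list(channels, nm)),
    div_sig_max = matrix(Inf, nc, n, dimnames = list(channels, nm)),
    mut_rate = numeric(n),
    mutation = matrix(0, n, n, dimnames = list(nm, nm)),
    death_rate = numeric(n), death_min_age = numeric(n), death_chi = numeric(n),
    apoptotic_type = integer(n),
    death_sig_min = matrix(-Inf, nc, n, dimnames = list(channels, nm)),
    death_sig_max = matrix(Inf, nc, n, dimnames = list(channels, nm)),
    excluded_from_division = logical(n)
  )
  diag(t$mutation) <- 1
  adhesion_given <- FALSE
  diffusion_given <- FALSE
  A <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  D <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    ct <- celltypes[[i]]
    p <- paste0("celltypes.", nm[i])
    bad <- setdiff(names(ct), c("V0", "S0", "lambda_V", "lambda_S", "adhesion",
                                "size_change", "diffusion", "decay",
                                "constant_signal", "start_signal", "division",
                                "death", "liquid", "solid"))
    if (length(bad)) cfg_err(paste0(p, ".", bad[1]), "unknown key")
    t$V0[i] <- num_or(ct$V0, 0)
    t$S0[i] <- num_or(ct$S0, 0)
    t$lambda_V[i] <- num_or(ct$lambda_V, 0)
    t$lambda_S[i] <- num_or(ct$lambda_S, 0)
    if (t$lambda_V[i] < 0) cfg_err(paste0(p, ".lambda_V"), "must be >= 0")
    if (t$lambda_S[i] < 0) cfg_err(paste0(p, ".lambda_S"), "must be >= 0")
    t$is_liquid[i] <- lgl_or(ct$liquid, FALSE)
    t$is_solid[i] <- lgl_or(ct$solid, FALSE)
    t$constant_signal[i] <- lgl_or(ct$constant_signal, FALSE)
    t$size_change_V[i] <- num_or(ct$size_change$V0, 0)
    t$size_change_S[i] <- num_or(ct$size_change$S0, 0)
    if (nc) {
      t$start_signal[, i] <- sig_vec(ct$start_signal, channels, 0, paste0(p, ".start_signal"))
      if (!is.null(ct$decay)) {
        for (ch in names(ct$decay)) {
          if (!ch %in% channels) cfg_err(paste0(p, ".decay.", ch), "unknown signal channel")
          t$decay_rel[ch, i] <- num_or(ct$decay[[ch]]$relative, 1)
          t$decay_abs[ch, i] <- num_or(ct$decay[[ch]]$absolute, 0)
        }
      }
    }
    dv <- ct$division
    if (!is.null(dv)) {
      t$div_rate[i] <- num_or(dv$rate, 0)
      t$div_min_age[i] <- num_or(dv$min_age, 0)
      t$mut_rate[i] <- num_or(dv$mutation_rate, 0)
      t$excluded_from_division[i] <- lgl_or(dv$excluded, FALSE)
      if (nc) {
        t$div_sig_min[, i] <- sig_vec(dv$signal_min, channels, -Inf, paste0(p, ".division.signal_min"))
        t$div_sig_max[, i] <- sig_vec(dv$signal_max, channels, Inf, paste0(p, ".division.signal_max"))
      }
      if (!is.null(dv[["mutation"]])) {
        row <- rep(0, n); names(row) <- nm
        for (to in names(dv[["mutation"]])) {
          if (!to %in% nm) cfg_err(paste0(p, ".division.mutation.", to), "unknown cell type")
          row[to] <- as.numeric(dv[["mutation"]][[to]])
        }
        if (abs(sum(row) - 1) > 1e-9) {
          cfg_err(paste0(p, ".division.mutation"), "probabilities must sum to 1")
        }
        t$mutation[i, ] <- row
      }
      if (t$div_rate[i] < 0 || t$div_rate[i] > 1) cfg_err(paste0(p, ".division.rate"), "must be in [0,1]")
      if (t$mut_rate[i] < 0 || t$mut_rate[i] > 1) cfg_err(paste0(p, ".division.mutation_rate"), "must be in [0,1]")
    }
    de <- ct$death
    if (!is.null(de)) {
      t$death_rate[i] <- num_or(de$rate, 0)
      t$death_min_age[i] <- num_or(de$min_age, 0)
      t$death_chi[i] <- num_or(de$chi, 0)
      if (nc) {
        t$death_sig_min[, i] <- sig_vec(de$signal_min, channels, -Inf, paste0(p, ".death.signal_min"))
        t$death_sig_max[, i] <- sig_vec(de$signal_max, channels, Inf, paste0(p, ".death.signal_max"))
      }
      if (t$death_rate[i] < 0 || t$death_rate[i] > 1) cfg_err(paste0(p, ".death.rate"), "must be in [0,1]")
      at <- de$apoptotic_type
      if (!is.null(at)) {
        if (!at %in% nm) cfg_err(paste0(p, ".death.apoptotic_type"), "unknown cell type")
        t$apoptotic_type[i] <- match(at, nm)
      }
    }
    if (!is.null(ct$adhesion)) {
      adhesion_given <- TRUE
      for (to in names(ct$adhesion)) {
        if (!to %in% nm) cfg_err(paste0(p, ".adhesion.", to), "unknown cell type")
        A[i, to] <- as.numeric(ct$adhesion[[to]])
      }
    }
    if (!is.null(ct$diffusion)) {
      diffusion_given <- TRUE
      for (to in names(ct$diffusion)) {
        if (!to %in% nm) cfg_err(paste0(p, ".diffusion.", to), "unknown cell type")
        D[i, to] <- as.numeric(ct$diffusion[[to]])
      }
    }
  }
  if (sum(t$is_liquid) != 1) cfg_err("celltypes", "exactly one type must be flagged liquid")
  fill_sym <- function(M, what, default_all) {
    if (default_all) return(matrix(0, n, n, dimnames = dimnames(M)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (is.na(M[i, j]) && !is.na(M[j, i])) M[i, j] <- M[j, i]
    }
    lq <- which(t$is_liquid)
    if (is.na(M[lq, lq])) M[lq, lq] <- 0  # liquid is a single compartment
    diag(M)[is.na(diag(M)) & t$is_solid] <- 0
    if (anyNA(M)) {
      idx <- which(is.na(M), arr.ind = TRUE)[1, ]
      cfg_err(paste0("celltypes.", nm[idx[1]], ".", what, ".", nm[idx[2]]),
              "missing type pair")
    }
    if (any(abs(M - t(M)) > 1e-12)) cfg_err(paste0("celltypes.*.", what), "matrix must be symmetric")
    M
  }
  t$adhesion <- fill_sym(A, "adhesion", !adhesion_given)
  t$diffusion <- fill_sym(D, "diffusion", !diffusion_given)
  mu0 <- which(t$mut_rate > 0)
  for (i in mu0) {
    if (abs(sum(t$mutation[i, ]) - 1) > 1e-9) {
      cfg_err(paste0("celltypes.", nm[i], ".division.mutation"), "probabilities must sum to 1")
    }
  }
  class(t) <- "cpm_types"
  t
}

default_schedule <- c("sanity", "execute_events", "determine_events",
                      "size_change", "diffusion", "decay", "output")

#' Build and validate a simulation configuration
#'
#' Takes a configuration list (the in-memory form of the JSON configuration
#' file), fills defaults and validates it; errors name the offending key.
#'
#' @param cfg Configuration list with sections `domain`, `celltypes` and
#'   optionally `signals`, `init`, `output`, `schedule`, `sanity`.
#' @return Object of class `cpm_config`.
#' @export
cpm_config <- function(cfg) {
  if (!is.list(cfg)) cfg_err("", "configuration must be a list / JSON object")
  bad <- setdiff(names(cfg), c("domain", "celltypes", "signals", "init",
                               "output", "schedule", "sanity"))
  if (length(bad)) cfg_err(bad[1], "unknown key")
  d <- cfg$domain
  if (is.null(d$size) || length(d$size) != 3) cfg_err("domain.size", "must be an integer triple")
  out <- list()
  out$domain <- list(
    size = as.integer(unlist(d$size)),
    blocks = as.integer(unlist(if (is.null(d$blocks)) c(1, 1, 1) else d$blocks)),
    colors = int_or(d$colors, 8L),
    stencil = int_or(d$stencil, 27L),
    metric = chr_or(d$metric, "marching"),
    volume_method = chr_or(d$volume_method, "count"),
    mean_step = int_or(d$mean_step, 5L),
    temperature = num_or(d$temperature, 10),
    seed = int_or(d$seed, 1L)
  )
  if (any(out$domain$size < 1)) cfg_err("domain.size", "must be positive")
  if (length(out$domain$blocks) != 3 || any(out$domain$blocks < 1)) {
    cfg_err("domain.blocks", "must be a positive integer triple")
  }
  if (any(out$domain$size %% out$domain$blocks != 0)) {
    cfg_err("domain.blocks", "domain.size must be divisible by the block grid")
  }
  if (!out$domain$metric %in% c("side", "marching")) {
    cfg_err("domain.metric", "must be 'side' or 'marching'")
  }
  if (!out$domain$volume_method %in% c("count", "marching")) {
    cfg_err("domain.volume_method", "must be 'count' or 'marching'")
  }
  scheme <- tryCatch(checkerboard(out$domain$colors, out$domain$stencil),
                     error = function(e) cfg_err("domain.colors", conditionMessage(e)))
  if (out$domain$metric == "marching" && out$domain$colors != 8) {
    cfg_err("domain.colors", "the marching metric requires the 8-colored checkerboard (read safety)")
  }
  if (out$domain$mean_step < 1) cfg_err("domain.mean_step", "mean_step must be >= 1")
  if (out$domain$temperature <= 0) cfg_err("domain.temperature", "temperature must be positive")
  out$signals <- as.character(unlist(cfg$signals))
  out$types <- cell_types(cfg$celltypes, out$signals)
  out$scheme <- scheme
  o <- cfg$output
  out$output <- list(every = int_or(o$every, 0L), csv = lgl_or(o$csv, FALSE),
                     vti = lgl_or(o$vti, FALSE), path = chr_or(o$path, "."),
                     int64 = lgl_or(o$int64, FALSE))
  out$schedule <- if (is.null(cfg$schedule)) default_schedule else as.character(unlist(cfg$schedule))
  bad <- setdiff(out$schedule, default_schedule)
  if (length(bad)) cfg_err("schedule", paste0("unknown action '", bad[1], "'"))
  sa <- cfg$sanity
  out$sanity <- list(single_voxel = lgl_or(sa$single_voxel, TRUE),
                     radius = if (length(sa$radius)) as.numeric(sa$radius) else NULL,
                     every = int_or(sa$every, 1L))
  out$init <- validate_init(cfg$init, out)
  class(out) <- "cpm_config"
  out
}

validate_init <- function(init, out) {
  if (is.null(init)) return(list())
  block_shape <- out$domain$size %/% out$domain$blocks
  nm <- out$types$name
  for (i in seq_along(init)) {
    pl <- init[[i]]
    p <- paste0("init[", i, "]")
    if (is.null(pl$shape) || !pl$shape %in% c("single", "cube", "sphere", "fill")) {
      cfg_err(paste0(p, ".shape"), "must be 'single', 'cube', 'sphere' or 'fill'")
    }
    if (pl$shape == "fill") {
      # fill: a cubic region tiled with equal-volume cubic cells
      if (is.null(pl$cell_volume)) cfg_err(paste0(p, ".cell_volume"), "required")
      edge <- round(as.numeric(pl$cell_volume)^(1 / 3))
      if (edge^3 != as.numeric(pl$cell_volume)) {
        cfg_err(paste0(p, ".cell_volume"), "must be a perfect cube (cells are cubic tiles)")
      }
      pl$shape <- "cube"
      pl$cell_edge <- edge
    }
    if (is.null(pl$type) || !pl$type %in% nm) cfg_err(paste0(p, ".type"), "unknown cell type")
    if (out$types$is_liquid[match(pl$type, nm)]) cfg_err(paste0(p, ".type"), "cannot place liquid cells")
    extent <- switch(pl$shape,
      single = c(1, 1, 1),
      cube = {
        if (is.null(pl$corner) || length(unlist(pl$corner)) != 3) cfg_err(paste0(p, ".corner"), "required triple")
        if (is.null(pl$size)) cfg_err(paste0(p, ".size"), "required")
        rep(as.numeric(pl$size), 3)
      },
      sphere = {
        if (is.null(pl$center) || length(unlist(pl$center)) != 3) cfg_err(paste0(p, ".center"), "required triple")
        if (is.null(pl$radius)) cfg_err(paste0(p, ".radius"), "required")
        rep(2 * as.numeric(pl$radius) + 1, 3)
      })
    cell_extent <- if (!is.null(pl$cell_edge)) rep(as.numeric(pl$cell_edge), 3) else extent
    if (any(cell_extent > block_shape)) {
      cfg_err(p, "the cell size must be smaller than the block size per dimension")
    }
    # normalise list-form triples from JSON so round trips are stable
    for (key in c("position", "corner", "center")) {
      if (!is.null(pl[[key]])) pl[[key]] <- as.numeric(unlist(pl[[key]]))
    }
    for (key in c("size", "radius", "cell_edge")) {
      if (!is.null(pl[[key]])) pl[[key]] <- as.numeric(pl[[key]])
    }
    init[[i]] <- pl
  }
  init
}

#' Load a simulation configuration from a JSON file
#'
#' @param path Path to the JSON configuration.
#' @return A validated [cpm_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  cpm_config(jsonlite::read_json(path))
}

#' Write a configuration back to JSON
#'
#' `load_config()` after `save_config()` is idempotent (defaults are
#' materialised on the first load).
#'
#' @param cfg A `cpm_config` (or plain configuration list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(config_as_list(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Re-export a cpm_config as a plain list in the JSON schema shape.
config_as_list <- function(cfg) {
  if (!inherits(cfg, "cpm_config")) return(cfg)
  t <- cfg$types
  n <- length(t$name)
  celltypes <- stats::setNames(vector("list", n), t$name)
  for (i in seq_len(n)) {
    ct <- list()
    if (t$is_liquid[i]) ct$liquid <- TRUE
    if (t$is_solid[i]) ct$solid <- TRUE
    ct$V0 <- t$V0[i]; ct$S0 <- t$S0[i]
    ct$lambda_V <- t$lambda_V[i]; ct$lambda_S <- t$lambda_S[i]
    ct$adhesion <- as.list(stats::setNames(t$adhesion[i, ], t$name))
    ct$diffusion <- as.list(stats::setNames(t$diffusion[i, ], t$name))
    if (t$size_change_V[i] != 0 || t$size_change_S[i] != 0) {
      ct$size_change <- list(V0 = t$size_change_V[i], S0 = t$size_change_S[i])
    }
    if (t$constant_signal[i]) ct$constant_signal <- TRUE
    if (length(t$channels)) {
      ct$start_signal <- as.list(stats::setNames(t$start_signal[, i], t$channels))
      ct$decay <- stats::setNames(lapply(seq_along(t$channels), function(ch) {
        list(relative = t$decay_rel[ch, i], absolute = t$decay_abs[ch, i])
      }), t$channels)
    }
    div <- list(rate = t$div_rate[i], min_age = t$div_min_age[i],
                mutation_rate = t$mut_rate[i],
                excluded = t$excluded_from_division[i])
    if (length(t$channels)) {
      fin <- is.finite(t$div_sig_min[, i]); fax <- is.finite(t$div_sig_max[, i])
      if (any(fin)) div$signal_min <- as.list(stats::setNames(t$div_sig_min[fin, i], t$channels[fin]))
      if (any(fax)) div$signal_max <- as.list(stats::setNames(t$div_sig_max[fax, i], t$channels[fax]))
    }
    if (t$mut_rate[i] > 0) div$mutation <- as.list(stats::setNames(t$mutation[i, ], t$name))
    ct$division <- div
    dth <- list(rate = t$death_rate[i], min_age = t$death_min_age[i], chi = t$death_chi[i])
    if (t$apoptotic_type[i] > 0) dth$apoptotic_type <- t$name[t$apoptotic_type[i]]
    if (length(t$channels)) {
      fin <- is.finite(t$death_sig_min[, i]); fax <- is.finite(t$death_sig_max[, i])
      if (any(fin)) dth$signal_min <- as.list(stats::setNames(t$death_sig_min[fin, i], t$channels[fin]))
      if (any(fax)) dth$signal_max <- as.list(stats::setNames(t$death_sig_max[fax, i], t$channels[fax]))
    }
    ct$death <- dth
    celltypes[[i]] <- ct
  }
  list(domain = cfg$domain, signals = as.list(cfg$signals), celltypes = celltypes,
       init = cfg$init, output = cfg$output, schedule = as.list(cfg$schedule),
       sanity = cfg$sanity)
}
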