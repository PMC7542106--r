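# diagnostics: the placement-bias validation harness and consistency audits.

#' Placement-bias experiment
#'
#' Runs replicate simulations of two non-interacting cells on a 2x2x2 block
#' grid: one cell at the center of a block, the other at the common corner
#' of all eight blocks (the domain center), so that every ACD exchange path
#' is exercised.  Records per color cycle the volume and surface ratios to
#' their targets and the displacement of the integer center-of-mass voxel,
#' then summarises fluctuations and tests the two placements for
#' distributional equality (two-sample Kolmogorov-Smirnov on thinned,
#' decorrelated samples).
#'
#' The energy parameters (temperature, couplings) come from the pinned
#' `bias-test.json` configuration shipped with the package; all bias
#' conclusions (equality between placements) are parameter-free, only the
#' fluctuation magnitudes depend on the pinned values.
#'
#' @param replicates Number of replicate runs.
#' @param cycles Color cycles per replicate.
#' @param burn_in Cycles discarded before computing statistics.
#' @param block_edge Cubic block edge length (domain is twice that).
#' @param seed Base seed; replicate r uses `seed + (r-1)`.
#' @param thin Keep every `thin`-th post-burn-in cycle for the KS tests.
#' @param config_overrides Named list merged over the pinned configuration's
#'   `domain` section (e.g. `list(temperature = 30)`).
#' @param progress Print a line per replicate.
#' @return An object of class `cpm_bias_report`: per-replicate time series
#'   and the summary statistics (relative SDs in percent, mean CoM
#'   displacements, KS p-values).
#' @export
run_bias_experiment <- function(replicates = 12, cycles = 5000, burn_in = 1000,
                                block_edge = 32, seed = 1, thin = 400,
                                config_overrides = NULL, progress = FALSE) {
  cfg <- bias_config(block_edge, config_overrides)
  V0 <- cfg$types$V0[2]
  S0 <- cfg$types$S0[2]
  series <- vector("list", replicates)
  dvec <- array(NA_real_, c(replicates, cycles, 2, 3))  # displacement vectors
  for (r in seq_len(replicates)) {
    rs <- as.integer(seed + (r - 1))
    set.seed(rs)
    sim <- cpm_sim(cfg, seed = rs)
    reg0 <- cell_registry(sim)
    com0 <- lapply(1:2, function(i) {
      com_voxel(reg0$cx[i], reg0$cy[i], reg0$cz[i], reg0$v[i], sim$cfg$domain$size)
    })
    rec <- matrix(NA_real_, cycles, 6,
                  dimnames = list(NULL, c("v_center", "s_center", "d_center",
                                          "v_corner", "s_corner", "d_corner")))
    for (cyc in seq_len(cycles)) {
      run_cycles(sim, 1)
      reg <- cell_registry(sim)
      for (i in 1:2) {
        cv <- com_voxel(reg$cx[i], reg$cy[i], reg$cz[i], reg$v[i], sim$cfg$domain$size)
        dvec[r, cyc, i, ] <- cv - com0[[i]]
        rec[cyc, 3 * i - 2] <- reg$v[i] / V0
        rec[cyc, 3 * i - 1] <- reg$s[i] / S0
        rec[cyc, 3 * i] <- sqrt(sum((cv - com0[[i]])^2))
      }
    }
    series[[r]] <- rec
    if (progress) {
      message(sprintf("replicate %d/%d: acc. rate %.2f", r, replicates,
                      sim$stats$accepts / max(1, sim$stats$attempts)))
    }
  }
  post <- lapply(series, function(m) m[(burn_in + 1):cycles, , drop = FALSE])
  stat <- function(col, f) vapply(post, function(m) f(m[, col]), numeric(1))
  rel_sd <- list(
    v_center = 100 * stat("v_center", stats::sd),
    s_center = 100 * stat("s_center", stats::sd),
    v_corner = 100 * stat("v_corner", stats::sd),
    s_corner = 100 * stat("s_corner", stats::sd))
  disp <- list(center = stat("d_center", mean), corner = stat("d_corner", mean))
  # displacement of the replicate-averaged center trajectory (how an
  # ensemble-averaged movement plot reads): average the displacement vectors
  # over replicates per time point, then take the norm and the time average
  pw <- (burn_in + 1):cycles
  dbar <- apply(dvec[, pw, , , drop = FALSE], c(2, 3, 4), mean)
  ens <- apply(sqrt(apply(dbar^2, c(1, 2), sum)), 2, mean)
  keep <- seq(1, nrow(post[[1]]), by = thin)
  pool <- function(col) unlist(lapply(post, function(m) m[keep, col]))
  ks <- suppressWarnings(list(   # volumes/displacements are discrete: ties expected
    v = stats::ks.test(pool("v_center"), pool("v_corner"))$p.value,
    s = stats::ks.test(pool("s_center"), pool("s_corner"))$p.value,
    d = stats::ks.test(pool("d_center"), pool("d_corner"))$p.value))
  structure(list(
    series = series, burn_in = burn_in, cycles = cycles,
    replicates = replicates, V0 = V0, S0 = S0,
    rel_sd_volume = mean(c(rel_sd$v_center, rel_sd$v_corner)),
    rel_sd_surface = mean(c(rel_sd$s_center, rel_sd$s_corner)),
    rel_sd = rel_sd,
    mean_displacement_center = ens[1],
    mean_displacement_corner = ens[2],
    per_replicate_displacement_center = mean(disp$center),
    per_replicate_displacement_corner = mean(disp$corner),
    ks_p = ks), class = "cpm_bias_report")
}

#' @export
print.cpm_bias_report <- function(x, ...) {
  cat("Placement-bias experiment:", x$replicates, "replicates,", x$cycles,
      "cycles (burn-in", x$burn_in, ")\n")
  cat(sprintf("  relative SD of volume:  %.2f %%\n", x$rel_sd_volume))
  cat(sprintf("  relative SD of surface: %.2f %%\n", x$rel_sd_surface))
  cat(sprintf("  replicate-averaged CoM displacement: center %.3f, corner %.3f voxels\n",
              x$mean_displacement_center, x$mean_displacement_corner))
  cat(sprintf("  per-replicate CoM wander:            center %.3f, corner %.3f voxels\n",
              x$per_replicate_displacement_center, x$per_replicate_displacement_corner))
  cat(sprintf("  KS center-vs-corner p:  v %.3f, s %.3f, displacement %.3f\n",
              x$ks_p$v, x$ks_p$s, x$ks_p$d))
  invisible(x)
}

# The pinned bias-test configuration with the domain scaled to the requested
# block edge; the two 10^3 seed cells sit at a block center and at the
# domain center.
bias_config <- function(block_edge = 32, overrides = NULL) {
  path <- system.file("extdata", "bias-test.json", package = "blockcpm")
  raw <- jsonlite::read_json(path)
  for (nm in names(overrides)) raw$domain[[nm]] <- overrides[[nm]]
  edge <- as.integer(block_edge)
  raw$domain$size <- rep(2L * edge, 3)
  raw$domain$blocks <- c(2L, 2L, 2L)
  # digital balls of ~1000 voxels centered on lattice points: the integer
  # center of mass then starts exactly at the center voxel, so the reported
  # displacement is free of half-voxel rounding offsets
  half <- edge %/% 2L
  raw$init <- list(
    list(shape = "sphere", center = as.list(rep(half, 3)), radius = 6.2, type = "cell"),
    list(shape = "sphere", center = as.list(rep(edge, 3)), radius = 6.2, type = "cell"))
  cpm_config(raw)
}
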