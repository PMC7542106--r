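test_that("oversize detection uses opposite axis directions only", {
  rep_ <- function(dir, ids) list(dir = dir, ids = ids)
  # cell in left + center only: reported from -x only
  expect_length(detect_oversize(list(rep_(c(-1, 0, 0), c(7L)))), 0)
  # same cell from -x and +x: MoD
  expect_equal(detect_oversize(list(rep_(c(-1, 0, 0), c(7L)),
                                    rep_(c(1, 0, 0), c(7L, 9L)))), 7L)
  # -x and +y: different axes, no MoD
  expect_length(detect_oversize(list(rep_(c(-1, 0, 0), 7L),
                                     rep_(c(0, 1, 0), 7L))), 0)
  # diagonal-only presence never triggers
  expect_length(detect_oversize(list(rep_(c(-1, -1, 0), 7L),
                                     rep_(c(1, 1, 0), 7L))), 0)
})

test_that("MoD reach: two forwarding steps cover the clipped 5x5x5 block neighborhood", {
  lay <- block_layout(c(10, 10, 10), c(5, 5, 5))
  center <- 1L + 2L + 5L * (2L + 5L * 2L)
  expect_length(propagate_mod(lay, center), 125)
  corner <- 1L
  expect_length(propagate_mod(lay, corner), 27)
  lay3 <- block_layout(c(6, 2, 2), c(3, 1, 1))
  expect_equal(propagate_mod(lay3, 2L), c(1L, 2L, 3L))
})

test_that("an oversized cell is deleted from all blocks within two commits", {
  # 4x1x1 blocks of 4^3; paint a cell spanning three blocks by hand
  cfg <- tiny_config(domain = list(size = c(16, 4, 4), blocks = c(4, 1, 1),
                                   colors = 8, stencil = 27, metric = "side",
                                   mean_step = 1, temperature = 1e-9, seed = 1),
                     init = list(list(shape = "single", position = c(7, 2, 2),
                                      type = "cell")))
  set.seed(1)
  sim <- cpm_sim(cfg, seed = 1)
  for (b in 1:3) {
    blk <- sim$blocks[[b]]
    blk[2:5, 3, 3] <- 1L
    sim$blocks[[b]] <- blk
  }
  halo_sync(sim$blocks, sim$layout)
  # let the ACD exchange detect and countdown: detection, forward, delete
  for (k in 1:3) acd_exchange(sim)
  field <- reassemble_field(sim$blocks, sim$layout)
  expect_false(any(field == 1L))
  for (b in seq_len(sim$layout$n_blocks)) {
    expect_false(1L %in% sim$recs[[b]]$ids)
  }
})

test_that("records are replicated where the cell has presence and dropped when it leaves", {
  cfg <- tiny_config(domain = list(size = c(16, 8, 8), blocks = c(2, 1, 1),
                                   colors = 8, stencil = 27, metric = "side",
                                   mean_step = 1, temperature = 1e-9, seed = 1),
                     init = list(list(shape = "cube", corner = c(9, 2, 2), size = 4,
                                      type = "cell")))
  set.seed(1)
  sim <- cpm_sim(cfg, seed = 1)
  # cell sits fully in block 2 (x 9..12), one voxel from the interface:
  # block 1 must hold a halo record
  expect_true(1L %in% sim$recs[[2]]$ids)
  expect_false(1L %in% sim$recs[[1]]$ids)
  blk <- sim$blocks[[2]]
  blk[2, 3:6, 3:6] <- 1L   # extend to x = 9 (global 8): now in block 1's halo
  sim$blocks[[2]] <- blk
  halo_sync(sim$blocks, sim$layout)
  acd_exchange(sim)
  expect_true(1L %in% sim$recs[[1]]$ids)
  # shrink away again: record dropped at the next exchange
  blk[2, 3:6, 3:6] <- 0L
  sim$blocks[[2]] <- blk
  halo_sync(sim$blocks, sim$layout)
  acd_exchange(sim)
  expect_false(1L %in% sim$recs[[1]]$ids)
})

test_that("cross-block ACD stays identical for a block-spanning cell", {
  cfg <- tiny_config(domain = list(size = c(16, 8, 8), blocks = c(2, 1, 1),
                                   colors = 8, stencil = 27, metric = "marching",
                                   mean_step = 2, temperature = 10, seed = 6),
                     init = list(list(shape = "cube", corner = c(6, 2, 2), size = 4,
                                      type = "cell")))
  set.seed(6)
  sim <- cpm_sim(cfg, seed = 6)
  run_cycles(sim, 3)
  r1 <- sim$recs[[1]]; r2 <- sim$recs[[2]]
  i1 <- match(1L, r1$ids); i2 <- match(1L, r2$ids)
  expect_false(is.na(i1) && is.na(i2))
  if (!is.na(i1) && !is.na(i2)) {
    expect_identical(r1$v[i1], r2$v[i2])
    expect_equal(r1$s[i1], r2$s[i2], tolerance = 1e-9)
    expect_identical(r1$cx[i1], r2$cx[i2])
  }
  field <- reassemble_field(sim$blocks, sim$layout)
  expect_equal(r1$v[i1], sum(field == 1L))
})

test_that("sanity action cleans detached single voxels with exact bookkeeping", {
  cfg <- tiny_config(domain = list(size = c(8, 8, 8), blocks = c(1, 1, 1),
                                   colors = 8, stencil = 27, metric = "side",
                                   mean_step = 1, temperature = 1e-9, seed = 1),
                     init = list(list(shape = "cube", corner = c(1, 1, 1), size = 4,
                                      type = "cell")))
  set.seed(1)
  sim <- cpm_sim(cfg, seed = 1)
  # intact connected cell: nothing to clean
  expect_equal(sanity_sweep(sim), 0L)
  # detach one voxel far from the cell (with records re-measured to match)
  blk <- sim$blocks[[1]]
  blk[8, 8, 8] <- 1L
  sim$blocks[[1]] <- blk
  halo_sync(sim$blocks, sim$layout)
  blockcpm:::remeasure_cell(sim, 1L, type = 2L, birth = 0)
  v_before <- sim$recs[[1]]$v[match(1L, sim$recs[[1]]$ids)]
  expect_equal(v_before, 65)
  expect_equal(sanity_sweep(sim), 1L)
  rec <- sim$recs[[1]]
  expect_equal(rec$v[match(1L, rec$ids)], v_before - 1)
  expect_equal(audit_consistency(sim)$ok, TRUE)
  # a two-voxel detached fragment is not touched by the single-voxel rule
  blk <- sim$blocks[[1]]
  blk[8, 8, 7:8] <- 1L
  sim$blocks[[1]] <- blk
  halo_sync(sim$blocks, sim$layout)
  blockcpm:::remeasure_cell(sim, 1L, type = 2L, birth = 0)
  expect_equal(sanity_sweep(sim), 0L)
})

test_that("the audit detects a deliberately skipped exchange", {
  cfg <- tiny_config()
  set.seed(2)
  sim <- cpm_sim(cfg, seed = 2)
  run_cycles(sim, 1)
  expect_true(audit_consistency(sim)$ok)
  repeat {
    sim$skip_exchange_once <- TRUE
    out <- step_mcs(sim)
    if (out$accepts > 0) break
  }
  expect_false(audit_consistency(sim)$ok)
})
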