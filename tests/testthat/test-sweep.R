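test_that("visitor pattern: mean_step 1 visits everything, jumps stay in law", {
  set.seed(1)
  expect_equal(visitor_positions(10, 1), 0:9)
  pos <- visitor_positions(10000, 5)
  expect_true(all(diff(pos) >= 1) && all(diff(pos) <= 9))
  expect_equal(mean(diff(pos)), 5, tolerance = 0.05)
})

test_that("every index is selected with probability 1/mean_step", {
  set.seed(2)
  L <- 400L; m <- 5L; sweeps <- 20000L
  counts <- integer(L)
  for (s in seq_len(sweeps)) {
    p <- visitor_positions(L, m) + 1L
    counts[p] <- counts[p] + 1L
  }
  freq <- counts / sweeps
  expect_true(all(abs(freq - 1 / m) < 0.015))
  expect_equal(mean(freq), 1 / m, tolerance = 0.002 * 5)
  chi <- sum((counts - sweeps / m)^2 / (sweeps / m * (1 - 1 / m)))
  p_val <- stats::pchisq(chi, df = L - 1, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
})

test_that("kernel visitor stream obeys the same selection law", {
  st <- blockcpm:::cpp_rng_seed(7, 0)
  L <- 200L; m <- 4L; sweeps <- 5000L
  counts <- integer(L)
  for (s in seq_len(sweeps)) {
    p <- blockcpm:::cpp_visitor_positions(L, m, st) + 1L
    counts[p] <- counts[p] + 1L
  }
  freq <- counts / sweeps
  expect_true(all(abs(freq - 1 / m) < 0.03))
  chi <- sum((counts - sweeps / m)^2 / (sweeps / m * (1 - 1 / m)))
  expect_gt(stats::pchisq(chi, df = L - 1, lower.tail = FALSE), 0.01)
})

test_that("zero-temperature sweep at target accepts nothing", {
  cfg <- tiny_config(domain = list(size = c(8, 8, 8), blocks = c(1, 1, 1),
                                   colors = 8, stencil = 27, metric = "side",
                                   mean_step = 1, temperature = 1e-9, seed = 2))
  # the 4^3 cell is exactly at V0 = 64; surface term off, adhesion 0
  cfg$types$lambda_S[2] <- 0
  cfg$init <- list(list(shape = "cube", corner = c(2, 2, 2), size = 4, type = "cell"))
  sim <- cpm_sim(cfg)
  set.seed(1)
  out <- step_mcs(sim)
  expect_equal(out$accepts, 0)
})

test_that("fixed seed gives a bit-identical field trajectory", {
  run <- function() {
    cfg <- tiny_config()
    set.seed(11)
    sim <- cpm_sim(cfg, seed = 11)
    run_cycles(sim, 3)
    reassemble_field(sim$blocks, sim$layout)
  }
  expect_identical(run(), run())
})

test_that("a sweep only changes voxels of the active color", {
  cfg <- tiny_config(domain = list(size = c(8, 8, 8), blocks = c(1, 1, 1),
                                   colors = 8, stencil = 27, metric = "marching",
                                   mean_step = 1, temperature = 50, seed = 9),
                     init = list(list(shape = "cube", corner = c(2, 2, 2), size = 4,
                                      type = "cell")),
                     schedule = list(),  # isolate the sweeps from cycle actions
                     sanity = list(single_voxel = FALSE))
  set.seed(3)
  sim <- cpm_sim(cfg, seed = 9)
  s8 <- checkerboard(8, 27)
  for (color in 0:7) {
    before <- reassemble_field(sim$blocks, sim$layout)
    step_mcs(sim)
    after <- reassemble_field(sim$blocks, sim$layout)
    changed <- which(before != after, arr.ind = TRUE) - 1L
    if (nrow(changed)) {
      expect_true(all(color_of(changed, s8) == color))
    }
  }
})

test_that("after each commit the ACD equals a recount of the global field", {
  cfg <- tiny_config(domain = list(size = c(16, 8, 8), blocks = c(2, 1, 1),
                                   colors = 8, stencil = 27, metric = "marching",
                                   mean_step = 2, temperature = 8, seed = 4))
  set.seed(4)
  sim <- cpm_sim(cfg, seed = 4)
  sim$audit <- TRUE
  run_cycles(sim, 3)
  expect_length(sim$audit_violations, 0)
  # voxel conservation, integer-exact
  field <- reassemble_field(sim$blocks, sim$layout)
  reg <- blockcpm:::cell_registry(sim)
  expect_equal(sum(reg$v) + sum(field == 0L), prod(sim$cfg$domain$size))
})
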