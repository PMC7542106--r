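test_that("pairwise flux follows the mean-surface-fraction law", {
  types <- cell_types(list(liquid = list(liquid = TRUE),
                           a = list(diffusion = list(a = 0.1, liquid = 0))),
                      channels = "nutrient")
  shared <- data.frame(i = 1, j = 2, surface = 10)
  surface <- c("1" = 40, "2" = 50)
  sigma <- c("1" = 0, "2" = 1)
  type <- c("1" = 2L, "2" = 2L)
  d <- diffuse_flux(shared, surface, sigma, type, types$diffusion)
  expect_equal(unname(d["1"]), (10 / 40 + 10 / 50) * 0.1 * 1)  # 0.045 into cell 1
  expect_equal(unname(d["2"]), -unname(d["1"]))
  # equal concentrations: no flux
  d0 <- diffuse_flux(shared, surface, c("1" = 1, "2" = 1), type, types$diffusion)
  expect_true(all(d0 == 0))
  # zero total surface with nonzero shared surface is an internal error
  expect_error(diffuse_flux(shared, c("1" = 0, "2" = 50), sigma, type,
                            types$diffusion), "internal error")
})

test_that("closed-system diffusion conserves total signal to 1e-9", {
  types <- cell_types(list(liquid = list(liquid = TRUE),
                           a = list(diffusion = list(a = 0.05, liquid = 0))),
                      channels = "n")
  set.seed(20)
  shared <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), surface = c(4, 6, 3))
  surface <- c("1" = 20, "2" = 18, "3" = 22)
  type <- c("1" = 2L, "2" = 2L, "3" = 2L)
  sigma <- c("1" = 0.3, "2" = 1.2, "3" = 0.7)
  tot <- sum(sigma)
  for (i in 1:10000) {
    sigma <- sigma + diffuse_flux(shared, surface, sigma, type, types$diffusion)
  }
  expect_equal(sum(sigma), tot, tolerance = 1e-9 / tot)
  expect_equal(max(sigma) - min(sigma), 0, tolerance = 1e-9)
})

test_that("decay applies the relative factor and clamped absolute subtraction", {
  expect_equal(decay_signals(10, rel = 0.9), 9)
  expect_equal(decay_signals(c(1, 5, 10), rel = 1, abs_ = 0), c(1, 5, 10))
  expect_equal(decay_signals(3, rel = 0.5, abs_ = 2), 0)  # max(0, 1.5 - 2)
})

test_that("two-cell equilibration converges geometrically to the mean", {
  ts <- equilibrate_demo(S1 = 40, S2 = 40, S12 = 8, D = 0.2, sigma0 = c(0, 1),
                        steps = 200)
  expect_equal(ts[201, 1], 0.5, tolerance = 1e-9)
  expect_equal(ts[201, 2], 0.5, tolerance = 1e-9)
  gap <- abs(ts[, 2] - ts[, 1])
  factor <- 1 - 2 * (8 / 40 + 8 / 40) * 0.2
  expect_equal(gap[2:61] / gap[1:60], rep(factor, 60), tolerance = 1e-9)
  expect_true(all(diff(gap[1:100]) <= 0))
  # a constant supplier pins its level and pulls the other cell to it
  ts2 <- equilibrate_demo(S1 = 40, S2 = 40, S12 = 8, D = 0.2, sigma0 = c(0, 1),
                         steps = 400, constant = 2)
  expect_equal(ts2[401, 2], 1)
  expect_equal(ts2[401, 1], 1, tolerance = 1e-6)
})

test_that("engine diffusion keeps signals identical across blocks and bounded", {
  cfg <- cpm_config(list(
    domain = list(size = c(16, 8, 8), blocks = c(2, 1, 1), colors = 8, stencil = 27,
                  metric = "side", mean_step = 2, temperature = 3, seed = 12),
    signals = list("nutrient"),
    celltypes = list(
      liquid = list(liquid = TRUE, diffusion = list(liquid = 0)),
      vessel = list(solid = TRUE, constant_signal = TRUE,
                    start_signal = list(nutrient = 1),
                    adhesion = list(liquid = 0, vessel = 0, cell = 0),
                    diffusion = list(vessel = 0.1, cell = 0.1, liquid = 0)),
      cell = list(V0 = 64, S0 = 120, lambda_V = 1, lambda_S = 0,
                  start_signal = list(nutrient = 0),
                  adhesion = list(cell = 0, liquid = 0),
                  diffusion = list(cell = 0.1, liquid = 0))),
    init = list(
      list(shape = "cube", corner = c(5, 2, 2), size = 2, type = "vessel"),
      list(shape = "cube", corner = c(7, 2, 2), size = 4, type = "cell"))))
  set.seed(12)
  sim <- cpm_sim(cfg, seed = 12)
  run_cycles(sim, 30)
  reg <- blockcpm:::cell_registry(sim)
  cell <- match(2L, reg$ids)
  expect_gt(reg$sig[1, cell], 0)        # nutrient flowed from the supplier
  expect_lte(reg$sig[1, cell], 1 + 1e-9)  # bounded by the supplier level
  # supplier level untouched
  expect_equal(reg$sig[1, match(1L, reg$ids)], 1)
  # replicated records agree on the signal
  for (b in 1:2) {
    q <- match(2L, sim$recs[[b]]$ids)
    if (!is.na(q)) expect_equal(sim$recs[[b]]$sig[1, q], reg$sig[1, cell])
  }
  expect_true(audit_consistency(sim)$ok)
})
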