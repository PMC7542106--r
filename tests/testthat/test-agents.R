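agent_types <- function(div_rate = 0.3, mut_rate = 0, death_rate = 0.5) {
  cell_types(list(
    liquid = list(liquid = TRUE),
    a = list(V0 = 1000, S0 = 600, lambda_V = 1, lambda_S = 0,
             division = list(rate = div_rate, min_age = 2,
                             mutation_rate = mut_rate,
                             mutation = list(b = 0.5, c = 0.5),
                             signal_min = list(nutrient = 0.5)),
             death = list(rate = death_rate, min_age = 3,
                          apoptotic_type = "apo", chi = 10,
                          signal_max = list(nutrient = 0.1))),
    b = list(V0 = 1000, S0 = 600),
    c = list(V0 = 1000, S0 = 600),
    apo = list(V0 = 1000, S0 = 600, death = list(chi = 10))),
    channels = "nutrient")
}

test_that("division gates: volume threshold, age, signal window, rate", {
  t <- agent_types()
  base <- list(type = 2L, v = 950, v0 = 1000, age = 5, sig = 1, com = c(1, 2, 3))
  expect_null(check_division(modifyList(base, list(v = 890)), t, u = 0))  # V <= 0.9 V0
  expect_null(check_division(modifyList(base, list(age = 1)), t, u = 0))
  expect_null(check_division(modifyList(base, list(sig = 0.4)), t, u = 0))
  set.seed(1)
  ev <- check_division(base, t, u = 0)   # rate 0.3 > 0: always fires at u = 0
  expect_equal(ev$kind, "divide")
  expect_equal(sqrt(sum(ev$normal^2)), 1, tolerance = 1e-12)
  expect_null(check_division(base, t, u = 0.31))
  # firing frequency matches the rate
  set.seed(2)
  fired <- vapply(1:10000, function(i) !is.null(check_division(base, t)), logical(1))
  expect_equal(mean(fired), 0.3, tolerance = 0.01 / 0.3)
})

test_that("mutation draws follow the transition matrix", {
  t0 <- agent_types(mut_rate = 0)
  expect_equal(mutate_type(2L, t0, u = 0.99), 2L)
  expect_equal(mutate_type(2L, t0, u = 0), 2L)   # rate 0: never mutates
  t1 <- agent_types(mut_rate = 1)
  t1$mutation[2, ] <- c(0, 0, 1, 0, 0)           # one-hot on type b
  set.seed(3)
  expect_true(all(vapply(1:50, function(i) mutate_type(2L, t1), integer(1)) == 3L))
  th <- agent_types(mut_rate = 0.5)
  set.seed(4)
  draws <- vapply(1:10000, function(i) mutate_type(2L, th), integer(1))
  expect_equal(mean(draws == 3L), 0.25, tolerance = 0.015 / 0.25)
  expect_equal(mean(draws == 4L), 0.25, tolerance = 0.015 / 0.25)
})

test_that("death gates: starvation window, age, and the background rate/1000", {
  t <- agent_types(death_rate = 0.5)
  starved <- list(type = 2L, v = 900, v0 = 1000, age = 5, sig = 0.05, com = 1:3)
  fed <- modifyList(starved, list(sig = 0.9))
  young <- modifyList(starved, list(age = 1))
  expect_null(check_death(young, t, u = c(0, 0)))       # age gate on both paths
  expect_equal(check_death(starved, t, u = c(0, 1))$kind, "die")
  expect_null(check_death(fed, t, u = c(0, 1)))         # well-fed: main path off
  expect_equal(check_death(fed, t, u = c(0, 1e-5))$kind, "die")  # background
  set.seed(5)
  fired <- vapply(1:1e5, function(i) !is.null(check_death(fed, t)), logical(1))
  expect_equal(mean(fired), 5e-4, tolerance = 1e-4 / 5e-4)
})

test_that("effective targets: growth accumulates, apoptosis shrinks with clamping", {
  t <- cell_types(list(liquid = list(liquid = TRUE),
                       g = list(V0 = 100, S0 = 120,
                                size_change = list(V0 = 2, S0 = 1)),
                       apo = list(V0 = 1000, S0 = 1400, death = list(chi = 10))))
  tg <- list(v0 = 100, s0 = 120)
  for (i in 1:50) tg <- apply_size_change(tg, 2L, t)
  expect_equal(tg$v0, 200)   # 2 per cycle over 50 cycles
  expect_equal(tg$s0, 170)
  a50 <- apply_size_change(list(v0 = 0, s0 = 0), 3L, t, age = 50, apoptotic = TRUE)
  expect_equal(a50$v0, 500)
  expect_equal(a50$s0, 1400 * 0.5^(2 / 3))
  a200 <- apply_size_change(list(v0 = 0, s0 = 0), 3L, t, age = 200, apoptotic = TRUE)
  expect_equal(a200$v0, 0)
  expect_equal(a200$s0, 0)
})

division_sim <- function(blocks = c(1, 1, 1), size = c(8, 8, 8)) {
  cfg <- tiny_config(domain = list(size = size, blocks = blocks, colors = 8,
                                   stencil = 27, metric = "side", mean_step = 1,
                                   temperature = 1e-9, seed = 3),
                     init = list(list(shape = "cube", corner = c(2, 2, 2), size = 4,
                                      type = "cell")))
  set.seed(3)
  cpm_sim(cfg, seed = 3)
}

test_that("division splits along the determined plane and re-measures both halves", {
  sim <- division_sim()
  ev <- list(kind = "divide", det_cycle = 0, normal = c(1, 0, 0),
             point = c(3.5, 3.5, 3.5), daughter_id = 500L, daughter_type = 2L)
  rec <- sim$recs[[1]]
  rec$pending[[match(1L, rec$ids)]] <- ev
  sim$recs[[1]] <- rec
  out <- execute_division(sim, 1L)
  expect_equal(out, c(1L, 500L))
  reg <- blockcpm:::cell_registry(sim)
  expect_equal(sort(reg$ids), c(1L, 500L))
  expect_equal(sum(reg$v), 64)              # daughters partition the mother
  expect_equal(reg$v[1], 32)                # plane x >= 3.5 keeps the mother
  expect_equal(reg$birth, c(sim$mcs, sim$mcs))
  expect_true(audit_consistency(sim)$ok)
})

test_that("a block-spanning division gives the same field as the single-block oracle", {
  ev <- list(kind = "divide", det_cycle = 0, normal = c(0.6, 0.64, 0.48),
             point = c(3.4, 3.6, 3.5), daughter_id = 999L, daughter_type = 2L)
  run <- function(blocks) {
    sim <- division_sim(blocks = blocks)
    rec <- sim$recs[[1]]
    q <- match(1L, rec$ids)
    if (!is.na(q)) {
      rec$pending[[q]] <- ev
      sim$recs[[1]] <- rec
    }
    execute_division(sim, 1L)
    reassemble_field(sim$blocks, sim$layout)
  }
  expect_identical(run(c(1, 1, 1)), run(c(2, 2, 2)))
})

test_that("a division plane with an empty side aborts", {
  sim <- division_sim()
  ev <- list(kind = "divide", det_cycle = 0, normal = c(1, 0, 0),
             point = c(-10, 0, 0), daughter_id = 501L, daughter_type = 2L)
  rec <- sim$recs[[1]]
  rec$pending[[match(1L, rec$ids)]] <- ev
  sim$recs[[1]] <- rec
  expect_null(execute_division(sim, 1L))
  expect_equal(sim$stats$aborted_divisions, 1L)
  reg <- blockcpm:::cell_registry(sim)
  expect_equal(reg$ids, 1L)
})

test_that("death switches to the apoptotic type and the cell shrinks away", {
  cfg <- cpm_config(list(
    domain = list(size = c(8, 8, 8), blocks = c(1, 1, 1), colors = 8, stencil = 27,
                  metric = "side", mean_step = 1, temperature = 2, seed = 8),
    celltypes = list(
      liquid = list(liquid = TRUE),
      cell = list(V0 = 27, S0 = 54, lambda_V = 2, lambda_S = 0,
                  death = list(rate = 1, apoptotic_type = "apo")),
      apo = list(V0 = 27, S0 = 54, lambda_V = 2, lambda_S = 0,
                 death = list(chi = 5))),
    init = list(list(shape = "cube", corner = c(3, 3, 3), size = 3, type = "cell"))))
  set.seed(8)
  sim <- cpm_sim(cfg, seed = 8)
  execute_death(sim, 1L)
  reg <- blockcpm:::cell_registry(sim)
  expect_equal(sim$types$name[reg$type], "apo")
  expect_equal(reg$birth, sim$mcs)
  run_cycles(sim, 40)
  reg <- blockcpm:::cell_registry(sim)
  expect_length(reg$ids, 0)   # record removed from all blocks once V = 0
  field <- reassemble_field(sim$blocks, sim$layout)
  expect_false(any(field != 0L))
})

test_that("growth plus division sustains proliferation in a permissive medium", {
  cfg <- cpm_config(list(
    domain = list(size = c(24, 24, 24), blocks = c(1, 1, 1), colors = 8,
                  stencil = 27, metric = "side", mean_step = 2, temperature = 3,
                  seed = 10),
    celltypes = list(
      liquid = list(liquid = TRUE),
      cell = list(V0 = 60, S0 = 110, lambda_V = 1, lambda_S = 0.1,
                  division = list(rate = 0.5))),
    init = list(list(shape = "cube", corner = c(10, 10, 10), size = 4, type = "cell"))))
  set.seed(10)
  sim <- cpm_sim(cfg, seed = 10)
  n0 <- length(blockcpm:::cell_registry(sim)$ids)
  counts <- integer(0)
  for (k in 1:10) {
    run_cycles(sim, 20)
    counts <- c(counts, length(blockcpm:::cell_registry(sim)$ids))
  }
  expect_gt(counts[10], n0)
  expect_gt(counts[10], counts[1])
  expect_gt(sim$stats$births, 0)
  expect_true(audit_consistency(sim)$ok)
})
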