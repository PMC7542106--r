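test_that("quadratic constraint terms evaluate directly", {
  expect_equal(volume_term_delta(999, +1, 1000, 1), -1)
  expect_equal(volume_term_delta(1000, 0, 1000, 1), 0)
  expect_equal(volume_term_delta(1000, +1, 1000, 2), 2)
  expect_equal(surface_term_delta(1400, 0, 1400, 1), 0)
  expect_equal(surface_term_delta(1398, +2, 1400, 1), -4)
  expect_equal(surface_term_delta(1398, +2, 1400, 0), 0)
})

test_that("Metropolis rule: downhill and zero always accepted, e^-1 at dE = T", {
  expect_true(all(metropolis_accept(c(-5, -1e-12, 0), temperature = 0.01)))
  expect_true(all(metropolis_accept(rep(0, 10), temperature = 100)))
  expect_error(metropolis_accept(1, temperature = 0), "configuration error")
  set.seed(123)
  acc <- metropolis_accept(rep(2.5, 1e5), temperature = 2.5)
  expect_equal(mean(acc), exp(-1), tolerance = 0.005 / exp(-1))
  # limits: T -> Inf accepts everything, T -> 0+ rejects uphill
  expect_true(all(metropolis_accept(rep(10, 100), temperature = 1e12)))
  set.seed(5)
  expect_false(any(metropolis_accept(rep(1, 100), temperature = 1e-6)))
})

test_that("adhesion delta: new contact face costs A, bulk-interior flips are free", {
  types <- cell_types(list(
    liquid = list(liquid = TRUE),
    a = list(V0 = 0, S0 = 0, adhesion = list(liquid = 16, a = 5, b = 16)),
    b = list(V0 = 0, S0 = 0, adhesion = list(liquid = 16, b = 5))))
  f <- array(0L, c(5, 5, 5))
  f[2, 2, 2] <- 1L   # type a cell
  cells <- data.frame(id = c(0, 1, 2), type = c("liquid", "a", "b"),
                      v = c(0, 1, 0), s = c(0, 6, 0), v0 = 0, s0 = 0)
  # flip a liquid voxel next to cell 1 to id 2 (type b): creates one a-b face,
  # destroys one a-liquid face, creates five b-liquid faces
  d <- total_delta_e(f, c(2, 1, 1), 2L, cells, types, metric = "side")
  expect_equal(d$dE_adh, 16 + 5 * 16 - 16)
  # flip entirely interior to one cell's bulk
  g <- array(1L, c(3, 3, 3))
  cells2 <- data.frame(id = c(0, 1), type = c("liquid", "a"),
                       v = c(0, 27), s = c(0, 0), v0 = 0, s0 = 0)
  # no liquid anywhere: the only neighbors of the center are same-cell
  d2 <- total_delta_e(g, c(1, 1, 1), 0L, cells2, types, metric = "side")
  # turning the center to liquid creates 6 a-liquid contacts
  expect_equal(d2$dE_adh, 6 * 16)
})

test_that("incremental dE equals global Hamiltonian recompute on random states", {
  for (seed in 1:4) {
    st <- random_state(seed = seed)
    field <- st$field
    set.seed(seed + 100)
    for (rep in 1:25) {
      vox <- sample(0:4, 3, replace = TRUE)
      old <- field[vox[1] + 1, vox[2] + 1, vox[3] + 1]
      new <- sample(setdiff(0:3, old), 1)
      cells <- data.frame(id = st$cells$id, type = st$cells$type, v = st$cells$v,
                          s = st$cells$s_side, v0 = st$cells$v0, s0 = st$cells$s0)
      d <- total_delta_e(field, vox, new, cells, st$types, metric = "side")
      E0 <- oracle_energy(field, st$cells, st$types, metric = "side")
      f2 <- field
      f2[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- new
      E1 <- oracle_energy(f2, st$cells, st$types, metric = "side")
      expect_equal(d$dE, E1 - E0, tolerance = 1e-9)
      field <- f2
      st$cells$v <- vapply(st$cells$id, function(id) sum(field == id), numeric(1))
      st$cells$s_side <- vapply(st$cells$id, function(id) side_count_surface(field, id), numeric(1))
    }
  }
})

test_that("marching-metric dE matches recompute when adhesion vanishes", {
  types <- cell_types(list(
    liquid = list(liquid = TRUE),
    a = list(V0 = 20, S0 = 30, lambda_V = 1, lambda_S = 0.5,
             adhesion = list(liquid = 0, a = 0))))
  set.seed(31)
  field <- array(sample(0:2, 125, replace = TRUE), dim = c(5, 5, 5))
  cells <- data.frame(id = 0:2, type = c("liquid", "a", "a"), v0 = c(0, 20, 20),
                      s0 = c(0, 30, 30))
  for (rep in 1:25) {
    cells$v <- vapply(cells$id, function(id) sum(field == id), numeric(1))
    cells$s <- vapply(cells$id, function(id) marching_surface(field, id), numeric(1))
    vox <- sample(0:4, 3, replace = TRUE)
    old <- field[vox[1] + 1, vox[2] + 1, vox[3] + 1]
    new <- sample(setdiff(0:2, old), 1)
    d <- total_delta_e(field, vox, new, cells, types, metric = "marching")
    E0 <- oracle_energy(field, cells, types, metric = "marching")
    f2 <- field; f2[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- new
    E1 <- oracle_energy(f2, cells, types, metric = "marching")
    expect_equal(d$dE, E1 - E0, tolerance = 1e-9)
    field <- f2
  }
})

test_that("forbidden attempts are flagged: same id, wall, solid", {
  types <- cell_types(list(
    liquid = list(liquid = TRUE),
    a = list(V0 = 1, S0 = 6, adhesion = list(liquid = 0, a = 0, rock = 0)),
    rock = list(solid = TRUE, adhesion = list(rock = 0, liquid = 0))))
  f <- array(0L, c(3, 3, 3)); f[2, 2, 2] <- 1L; f[1, 2, 2] <- 5L
  cells <- data.frame(id = c(0, 1, 5), type = c("liquid", "a", "rock"),
                      v = c(0, 1, 1), s = c(0, 6, 0), v0 = c(0, 1, 0), s0 = c(0, 6, 0))
  expect_false(total_delta_e(f, c(1, 1, 1), 1L, cells, types)$valid)  # same id
  expect_false(total_delta_e(f, c(0, 1, 1), 5L, cells, types)$valid)  # solid source
  expect_false(total_delta_e(f, c(0, 1, 1), cpm_wall_id(), cells, types)$valid)
  expect_true(total_delta_e(f, c(2, 1, 1), 1L, cells, types)$valid)
})
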