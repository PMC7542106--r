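lshape2d <- function() {
  img <- matrix(0L, 5, 5)
  img[2, 2] <- 1L; img[3, 2] <- 1L; img[2, 3] <- 1L
  img
}

test_that("side counting matches hand-counted and enumerated values", {
  f <- array(0L, c(3, 3, 3)); f[2, 2, 2] <- 7L
  expect_equal(side_count_surface(f, 7), 6)
  expect_equal(side_count_surface(lshape2d(), 1), 8)
  cube <- array(0L, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- 1L
  expect_equal(side_count_surface(cube, 1), 24)
  expect_equal(side_count_surface(cube, 1), oracle_side_surface(cube, 1))
  expect_equal(side_count_surface(f, 99), 0)  # absent id
})

test_that("marching metric reproduces closed-form iso-surface values", {
  expect_equal(marching_surface(lshape2d(), 1), 2 + 3 * sqrt(2), tolerance = 1e-9)
  px <- matrix(0L, 3, 3); px[2, 2] <- 1L
  expect_equal(marching_surface(px, 1), 2 * sqrt(2), tolerance = 1e-9)
  f <- array(0L, c(3, 3, 3)); f[2, 2, 2] <- 7L
  expect_equal(marching_surface(f, 7), sqrt(3), tolerance = 1e-9)
  expect_equal(cell_volume(f, 7, "count"), 1)
  expect_equal(cell_volume(f, 7, "marching"), 1 / 6, tolerance = 1e-9)
  expect_equal(cell_volume(f, 99, "count"), 0)
  expect_equal(cell_volume(f, 99, "marching"), 0)
})

test_that("large convex bodies: side counting exact, marching below with corner cuts", {
  for (n in 2:6) {
    f <- array(0L, dim = rep(n + 2, 3))
    f[1 + seq_len(n), 1 + seq_len(n), 1 + seq_len(n)] <- 1L
    expect_equal(side_count_surface(f, 1), 6 * n^2)
    m <- marching_surface(f, 1)
    expect_lt(m, 6 * n^2)
    expect_gt(m, 6 * n^2 - 8 * n)  # cuts scale with edge length
  }
})

test_that("marching surface of a digitized ball is closer to the sphere area", {
  r <- 8; n <- 21; ctr <- 11
  ball <- array(0L, c(n, n, n))
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2
  ball[as.matrix(g[inside, ])] <- 1L
  sphere <- 4 * pi * r^2
  expect_lt(abs(marching_surface(ball, 1) - sphere),
            abs(side_count_surface(ball, 1) - sphere))
})

test_that("incremental surface deltas equal full recomputation on random fields", {
  st <- random_state(seed = 7)
  field <- st$field
  set.seed(99)
  for (rep in 1:60) {
    vox <- sample(0:4, 3, replace = TRUE)
    old <- field[vox[1] + 1, vox[2] + 1, vox[3] + 1]
    new <- sample(setdiff(0:3, old), 1)
    for (metric in c("side", "marching")) {
      d <- local_surface_delta(field, vox, old, new, metric = metric)
      # dual route: the sweep kernel's incremental evaluation
      r <- total_delta_e(field, vox, new, data.frame(
        id = st$cells$id, type = st$cells$type,
        v = st$cells$v,
        s = if (metric == "side") st$cells$s_side else st$cells$s_march,
        v0 = st$cells$v0, s0 = st$cells$s0), st$types, metric = metric)
      for (nm in names(d)) {
        expect_equal(unname(r$dS[nm]), unname(d[nm]), tolerance = 1e-9)
      }
    }
    field[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- new
    st$cells$v <- vapply(st$cells$id, function(id) sum(field == id), numeric(1))
    st$cells$s_side <- vapply(st$cells$id, function(id) side_count_surface(field, id), numeric(1))
    st$cells$s_march <- vapply(st$cells$id, function(id) marching_surface(field, id), numeric(1))
  }
})

test_that("shared surfaces are symmetric face counts, invariant under axis permutation", {
  f <- array(0L, c(4, 4, 4))
  f[2, 2, 2] <- 1L; f[3, 2, 2] <- 2L            # face-adjacent single voxels
  sh <- shared_surfaces(f)
  expect_equal(sh$surface[sh$i == 1 & sh$j == 2], 1)
  f2 <- array(0L, c(4, 4, 4))
  f2[2, 2, 2:3] <- 1L; f2[3, 2, 2:3] <- 2L      # 1x1x2 dominoes, shared 1x2 face
  sh2 <- shared_surfaces(f2)
  expect_equal(sh2$surface[sh2$i == 1 & sh2$j == 2], 2)
  f3 <- array(0L, c(4, 4, 4)); f3[2, 2, 2] <- 1L; f3[4, 4, 4] <- 2L
  sh3 <- shared_surfaces(f3)
  expect_length(sh3$surface[sh3$i == 1 & sh3$j == 2], 0)  # non-touching
  # axis permutation invariance
  sh2p <- shared_surfaces(aperm(f2, c(3, 1, 2)))
  expect_equal(sh2p[order(sh2p$i, sh2p$j), "surface"],
               sh2[order(sh2$i, sh2$j), "surface"])
})
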