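test_that("plate mesh has the prescribed structured counts and uniform Jacobians", {
  m <- make_plate()
  expect_equal(nrow(m$nodes), 22 * 22 * 3)
  expect_equal(nrow(m$elems), 21 * 21 * 2)
  dj <- ref_jacobians(m)
  expect_true(all(dj > 0))
  expect_lt(diff(range(dj)), 1e-10) # uniform grid
  expect_equal(sum(element_volumes(m)), 100 * 100 * 12, tolerance = 1e-9)
  # fibers along x, sheets along y everywhere
  expect_true(all(m$f0[, 1] == 1 & m$f0[, 2] == 0))
  expect_true(all(m$s0[, 2] == 1))
})

test_that("small plate is the large plate scaled by one tenth", {
  big <- make_plate(c(100, 100, 12), c(21, 21, 2))
  small <- make_plate(c(10, 10, 1.2), c(21, 21, 2))
  expect_equal(small$elems, big$elems)
  expect_equal(small$nodes, big$nodes * 0.1)
  expect_equal(lengths(small$sets), lengths(big$sets))
})

test_that("plate node sets pick the benchmark regions", {
  m <- make_plate()
  expect_equal(unname(m$nodes[m$sets$corner_origin, ]), c(0, 0, 0))
  expect_equal(unname(m$nodes[m$sets$corner_x, ]), c(100, 0, 0))
  expect_true(all(m$nodes[m$sets$midplane_edge, 3] == 6))
  ld <- m$nodes[m$sets$load, ]
  expect_true(all(abs(ld[, 1] - 50) <= 10 + 1e-9))
  expect_true(all(abs(ld[, 2] - 50) <= 10 + 1e-9))
})

test_that("unit cube pins exactly the rigid-body modes", {
  m <- make_cube(1, 1)
  expect_equal(nrow(m$nodes), 8)
  expect_equal(nrow(m$elems), 1)
  pins <- c(m$sets$pin_xyz, m$sets$pin_yz, m$sets$pin_z)
  expect_equal(length(unique(pins)), 3)
})

test_that("LV shell is valid, apex-probed and watertight at the apex", {
  m <- make_lv(lv_spec(target_size = 1.0))
  dj <- ref_jacobians(m)
  expect_true(all(dj > 0))
  expect_equal(m$nodes[m$sets$apex, 3], min(m$nodes[m$sets$epi, 3]))
  expect_equal(length(m$sets$stim), 7)
  expect_true(all(abs(m$nodes[m$sets$base, 3]) < 1e-9))
  # all epicardial nodes lie on the epicardial ellipsoid
  sp <- lv_spec(target_size = 1.0)
  ep <- m$nodes[m$sets$epi, ]
  r <- (ep[, 1] / sp$epi[1])^2 + (ep[, 2] / sp$epi[2])^2 + (ep[, 3] / sp$epi[3])^2
  expect_equal(r, rep(1, nrow(ep)), tolerance = 1e-10)
})

test_that("LV element count grows as the target size shrinks", {
  n <- vapply(c(1.5, 1.0, 0.7), function(h)
    nrow(make_lv(lv_spec(target_size = h))$elems), numeric(1))
  expect_true(all(diff(n) > 0))
  # between the wall-resolution clamp (quadratic) and full cubic growth
  expect_gt(n[3] / n[1], (1.5 / 0.7)^2 * 0.8)
  expect_lt(n[3] / n[1], (1.5 / 0.7)^3 * 1.2)
})

test_that("transmural helix angle interpolates linearly endo to epi", {
  sp <- lv_spec()
  expect_equal(helix_angle(0, sp), 80)
  expect_equal(helix_angle(1, sp), -70)
  expect_equal(helix_angle(0.5, sp), 5)
  d <- seq(0, 1, length.out = 11)
  expect_true(all(diff(helix_angle(d, sp)) < 0)) # monotone across the wall
})

test_that("LV fiber frames are orthonormal and right handed", {
  m <- make_lv(lv_spec(target_size = 1.0))
  expect_lt(max(abs(rowSums(m$f0^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(m$s0^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(m$f0 * m$s0))), 1e-10)
  n0 <- cbind(m$f0[, 2] * m$s0[, 3] - m$f0[, 3] * m$s0[, 2],
              m$f0[, 3] * m$s0[, 1] - m$f0[, 1] * m$s0[, 3],
              m$f0[, 1] * m$s0[, 2] - m$f0[, 2] * m$s0[, 1])
  expect_equal(m$n0, n0, tolerance = 1e-12)
})

test_that("mesh generation is deterministic", {
  a <- make_lv(lv_spec(target_size = 1.2))
  b <- make_lv(lv_spec(target_size = 1.2))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("degenerate LV wall specifications are rejected", {
  expect_error(lv_spec(endo = c(3, 3, 5), epi = c(2.5, 4, 6)), "degenerate")
})
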