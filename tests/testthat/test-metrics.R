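mk <- function(v, dims = c(2, 2, 1), spacing = c(1, 1, 1)) {
  component_mask_new(array(v, dims), spacing, "GM")
}

test_that("dice handles identity, disjoint and partial overlap", {
  a <- mk(c(TRUE, TRUE, FALSE, FALSE))
  g <- mk(c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(dice(a, a), 100)
  expect_equal(dice(a, g), 50)   # |A|=2, |G|=2, |AnG|=1
  expect_equal(dice(mk(c(TRUE, FALSE, FALSE, FALSE)),
                    mk(c(FALSE, TRUE, FALSE, FALSE))), 0)
  expect_error(dice(mk(FALSE), mk(FALSE)), "undefined")
  expect_error(dice(a, mk(TRUE, dims = c(3, 3, 1))), "shape")
})

test_that("avd matches the volume-difference formula and is one-sided", {
  dims <- c(15, 15, 1)
  a110 <- mk(c(rep(TRUE, 110), rep(FALSE, 115)), dims)
  a90 <- mk(c(rep(TRUE, 90), rep(FALSE, 135)), dims)
  g100 <- mk(c(rep(TRUE, 100), rep(FALSE, 125)), dims)
  expect_equal(avd(g100, g100), 0)
  expect_equal(avd(a110, g100), 10)
  expect_equal(avd(a90, g100), 10)   # absolute value
  # not symmetric: normalised by the reference
  expect_equal(avd(g100, a110), 100 * 10 / 110)
  expect_error(avd(a90, mk(FALSE, dims)), "empty")
})

test_that("boundary extraction follows the 6-connectivity rule", {
  m <- component_mask_new(array(FALSE, c(5, 5, 5)), c(1, 2, 3), "WM")
  m$grid[3, 3, 3] <- TRUE
  b <- extract_boundary(m)
  expect_equal(b$count, 1L)
  expect_equal(unname(b$points[1, ]), c(2 * 1, 2 * 2, 2 * 3))
  # solid 3x3x3 cube: only the centre voxel is interior
  cube <- component_mask_new(array(FALSE, c(5, 5, 5)), c(1, 1, 1), "WM")
  cube$grid[2:4, 2:4, 2:4] <- TRUE
  expect_equal(extract_boundary(cube)$count, 26L)
  # full volume: the image border counts as outside, so only the single
  # fully-interior voxel is not boundary
  full <- component_mask_new(array(TRUE, c(3, 3, 3)), c(1, 1, 1), "WM")
  expect_equal(extract_boundary(full)$count, 26L)
  expect_error(extract_boundary(mk(FALSE)), "empty")
})

test_that("boundary extraction equals the exhaustive neighbour-scan oracle", {
  for (seed in 1:6) {
    dims <- c(sample(4:9, 1), sample(4:9, 1), sample(3:7, 1))
    m <- rand_mask(dims, c(0.96, 0.96, 3), p = 0.4, seed = seed)
    got <- extract_boundary(m)
    idx <- which(oracle_boundary(m), arr.ind = TRUE)
    want <- sweep(idx - 1, 2, m$spacing, `*`)
    expect_equal(unname(got$points[order(got$points[, 1], got$points[, 2],
                                         got$points[, 3]), ]),
                 unname(want[order(want[, 1], want[, 2], want[, 3]), ]))
  }
})

test_that("directed and symmetric h95 match trivial geometry", {
  m <- component_mask_new(array(FALSE, c(3, 3, 3)), c(0.96, 0.96, 3), "WM")
  m$grid[2, 2, 1] <- TRUE
  m2 <- m
  m2$grid[] <- FALSE
  m2$grid[2, 2, 2] <- TRUE   # one voxel along z, dz = 3 mm
  a <- extract_boundary(m)
  g <- extract_boundary(m2)
  expect_equal(directed_h95(a, a), 0)
  expect_equal(directed_h95(a, g), 3.0)
  expect_equal(h95(a, g), 3.0)
  expect_equal(h95(m, m2), 3.0)  # mask (distance-transform) path
  expect_error(h95(m, component_mask_new(array(FALSE, c(3, 3, 3)),
                                         m$spacing, "WM")), "empty")
})

test_that("h95 on point sets and on masks equals the all-pairs oracle", {
  for (seed in 1:8) {
    dims <- c(sample(6:20, 1), sample(6:20, 1), sample(4:12, 1))
    sp <- c(0.96, 0.96, 3.0)
    a <- rand_mask(dims, sp, p = 0.25, seed = seed, min_true = 3)
    g <- rand_mask(dims, sp, p = 0.25, seed = seed + 100, min_true = 3)
    pa <- extract_boundary(a)
    pg <- extract_boundary(g)
    want <- oracle_directed_h95(pa$points, pg$points)
    expect_equal(directed_h95(pa, pg), want, tolerance = 1e-12)
    expect_equal(directed_h95(a, g), want, tolerance = 1e-12)
    expect_equal(h95(a, g), oracle_h95(pa$points, pg$points),
                 tolerance = 1e-12)
    # symmetry of the symmetric form
    expect_equal(h95(g, a), h95(a, g))
  }
})

test_that("h95 scales with spacing; dice and avd do not", {
  dims <- c(12, 10, 6)
  a <- rand_mask(dims, c(0.96, 0.96, 3), p = 0.3, seed = 5, min_true = 3)
  g <- rand_mask(dims, c(0.96, 0.96, 3), p = 0.3, seed = 6, min_true = 3)
  for (lam in c(0.5, 2, 3.7)) {
    a2 <- a; g2 <- g
    a2$spacing <- a$spacing * lam
    g2$spacing <- g$spacing * lam
    expect_equal(h95(a2, g2), lam * h95(a, g), tolerance = 1e-10)
    expect_equal(dice(a2, g2), dice(a, g))
    expect_equal(avd(a2, g2), avd(a, g))
  }
})

test_that("the h95 order statistic uses K = ceil(0.95 N), no interpolation", {
  # 20 source points at x = 0, 19 targets coincide, 1 target 7 mm away:
  # exactly one nonzero minimum distance; K = ceil(0.95*20) = 19 -> 0
  apts <- cbind(x = as.numeric(0:19), y = 0, z = 0)
  gpts <- apts
  gpts[20, 1] <- 19 + 7
  a <- structure(list(points = apts, count = 20L, spacing = c(1, 1, 1)),
                 class = "boundary_points")
  g <- structure(list(points = gpts, count = 20L, spacing = c(1, 1, 1)),
                 class = "boundary_points")
  expect_equal(directed_h95(a, g), 0)
  # with 10 points K = ceil(9.5) = 10: the largest minimum is selected
  # (source x=9 is 1 mm from its nearest remaining target at x=8)
  a10 <- structure(list(points = apts[1:10, ], count = 10L,
                        spacing = c(1, 1, 1)), class = "boundary_points")
  g10 <- structure(list(points = rbind(apts[1:9, ], c(9 + 5, 0, 0)),
                        count = 10L, spacing = c(1, 1, 1)),
                   class = "boundary_points")
  expect_equal(directed_h95(a10, g10), 1)
})

test_that("wml sensitivity pools lesion voxels over cases", {
  g <- array(0L, c(2, 2, 1))
  g[1, 1, 1] <- 4L; g[2, 1, 1] <- 4L          # two lesion voxels per case
  ref <- label_volume(g, c(1, 1, 1), scheme = "raw")
  hit <- array(2L, c(2, 2, 1))                 # everything WM
  miss <- hit; miss[1, 1, 1] <- 1L             # one lesion voxel called GM
  cand_all <- label_volume(hit, c(1, 1, 1), scheme = "tissue")
  cand_one <- label_volume(miss, c(1, 1, 1), scheme = "tissue")
  expect_equal(wml_sensitivity(list(cand_all), list(ref)), 100)
  cand_gm <- label_volume(array(1L, c(2, 2, 1)), c(1, 1, 1),
                          scheme = "tissue")
  expect_equal(wml_sensitivity(list(cand_gm), list(ref)), 0)
  # 3 of 4 lesion voxels labelled WM across two cases
  expect_equal(wml_sensitivity(list(cand_all, cand_one), list(ref, ref)), 75)
  none <- label_volume(array(3L, c(2, 2, 1)), c(1, 1, 1), scheme = "raw")
  expect_error(wml_sensitivity(list(cand_all), list(none)), "lesion")
})
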