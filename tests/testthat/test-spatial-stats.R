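test_that("disc-window intersection areas match polar-integration oracle", {
  w <- roi_window()
  set.seed(11)
  for (k in 1:25) {
    cx <- runif(1, 0, 1.5); cy <- runif(1, 0, 1.5)
    r <- runif(1, 0.01, 1.2)
    a <- immunospat:::disc_window_area(cx, cy, r, 1.5, 1.5)
    expect_equal(a, oracle_disc_area(cx, cy, r, 1.5, 1.5),
                 tolerance = 1e-6)
  }
  # fully interior disc: exact pi r^2
  expect_equal(immunospat:::disc_window_area(0.75, 0.75, 0.1, 1.5, 1.5),
               pi * 0.1^2, tolerance = 1e-12)
  # huge radius: whole window
  expect_equal(immunospat:::disc_window_area(0.2, 1.0, 5, 1.5, 1.5),
               2.25, tolerance = 1e-12)
})

test_that("pair correlation fluctuates around 1 under CSR", {
  p <- random_pattern(500, seed = 42)
  g <- pair_correlation(p, radius_grid())
  expect_true(all(g$values >= 0))
  expect_lt(abs(mean(g$values) - 1), 0.1)
})

test_that("pair correlation vanishes below the hard core", {
  p <- random_pattern(300, seed = 43, hard_core = 0.02)
  grid <- radius_grid()
  g <- pair_correlation(p, grid)
  below <- grid$r + grid$dr / 2 <= 0.02
  expect_true(any(below))
  expect_identical(g$values[below], rep(0, sum(below)))
})

test_that("pair correlation matches the brute-force oracle on small patterns", {
  w <- roi_window()
  # hand-placed 5-point pattern on a single-bin grid
  p <- point_pattern(c(0.1, 0.2, 0.7, 1.4, 0.9), c(0.1, 0.25, 0.8, 1.45, 0.3), w)
  grid1 <- radius_grid(dr = 0.2, r_max = 0.4)
  g <- pair_correlation(p, grid1)
  expect_equal(g$values, oracle_pcf(p, grid1), tolerance = 1e-6)

  # property: random patterns with n <= 12
  for (seed in 1:6) {
    p <- random_pattern(sample(2:12, 1), w, seed = 2000 + seed)
    grid <- radius_grid(dr = 0.05, r_max = 0.6)
    expect_equal(pair_correlation(p, grid)$values, oracle_pcf(p, grid),
                 tolerance = 1e-6)
  }
  expect_error(pair_correlation(point_pattern(0.5, 0.5, w)), "at least 2")
})

test_that("nearest-neighbour distribution matches direct enumeration", {
  w <- roi_window()
  grid <- radius_grid()

  # two points 0.1 mm apart
  p <- point_pattern(c(0.5, 0.6), c(0.5, 0.5), w)
  G <- nn_distribution(p, grid)
  expect_identical(G$values[grid$r < 0.1], rep(0, sum(grid$r < 0.1)))
  expect_identical(G$values[grid$r >= 0.1], rep(1, sum(grid$r >= 0.1)))

  # three collinear points: NN distances {0.1, 0.1, 0.2}
  p3 <- point_pattern(c(0.1, 0.2, 0.4), c(0.5, 0.5, 0.5), w)
  G3 <- nn_distribution(p3, grid)
  expect_equal(G3$values[which.min(abs(grid$r - 0.1))], 2 / 3)
  expect_equal(G3$values[which.min(abs(grid$r - 0.2))], 1)

  # square lattice: all NN distances equal the spacing (corners too)
  s <- 0.125  # exactly representable, so distances are exact
  xy <- expand.grid(x = seq(0.25, 1.25, by = s), y = seq(0.25, 1.25, by = s))
  pl <- point_pattern(xy$x, xy$y, w)
  Gl <- nn_distribution(pl, grid)
  lo <- grid$r < s - 1e-9; hi <- grid$r > s + 1e-9
  expect_identical(Gl$values[lo], rep(0, sum(lo)))
  expect_identical(Gl$values[hi], rep(1, sum(hi)))

  # oracle equivalence on small random patterns
  for (seed in 1:6) {
    p <- random_pattern(sample(2:12, 1), w, seed = 3000 + seed)
    expect_equal(nn_distribution(p, grid)$values, oracle_G(p, grid)$values,
                 tolerance = 1e-9)
  }
})

test_that("spherical contact distribution matches direct computation", {
  w <- roi_window()
  grid <- radius_grid()
  # single pattern point at the centre, 3x3 deterministic reference grid
  p <- point_pattern(0.75, 0.75, w)
  refs <- expand.grid(x = c(0.25, 0.75, 1.25), y = c(0.25, 0.75, 1.25))
  F <- spherical_contact(p, grid, reference_points = refs)
  expect_equal(F$values, oracle_F(p, refs, grid)$values, tolerance = 1e-9)

  # dense grid pattern: no empty circle larger than half a cell diagonal
  s <- 0.05
  xy <- expand.grid(x = seq(0, 1.5, by = s), y = seq(0, 1.5, by = s))
  pg <- point_pattern(xy$x, xy$y, w)
  Fg <- spherical_contact(pg, grid, seed = 5)
  bound <- s * sqrt(2) / 2 + 1e-9
  expect_true(all(Fg$values[grid$r >= bound] == 1))

  # determinism under a fixed seed
  p2 <- random_pattern(50, seed = 9)
  expect_identical(spherical_contact(p2, grid, seed = 123)$values,
                   spherical_contact(p2, grid, seed = 123)$values)
  expect_error(spherical_contact(point_pattern(numeric(0), numeric(0), w),
                                 grid), "empty")
})

test_that("J-function follows its defining ratio and domain rules", {
  grid <- radius_grid(dr = 0.1, r_max = 0.4)
  mk <- function(kind, v) immunospat:::stat_curve(kind, grid, v)

  # G identical to F gives J identically 1
  v <- c(0.2, 0.5, 0.8, 0.95)
  J <- j_function(mk("NN_CDF", v), mk("SCD_CDF", v))
  expect_equal(J$values, rep(1, 4))

  # numerator zero and simple arithmetic
  J2 <- j_function(mk("NN_CDF", c(1, 0.5, 0.2, 0)),
                   mk("SCD_CDF", c(0.5, 0.75, 0.2, 1)))
  expect_equal(J2$values[1], 0)
  expect_equal(J2$values[2], 2)
  expect_equal(J2$values[3], 1)
  expect_false(J2$defined[4])  # F = 1 -> undefined

  g2 <- radius_grid(dr = 0.1, r_max = 0.3)
  expect_error(j_function(immunospat:::stat_curve("NN_CDF", g2, c(0, 0, 0)),
                          mk("SCD_CDF", v)), "different radius grids")
  expect_error(j_function(mk("SCD_CDF", v), mk("SCD_CDF", v)), "kind")
})

test_that("CDF statistics are monotone with range in [0, 1]", {
  grid <- radius_grid()
  for (seed in 1:8) {
    p <- random_pattern(sample(5:80, 1), seed = 4000 + seed)
    G <- nn_distribution(p, grid)$values
    F <- spherical_contact(p, grid, seed = seed)$values
    for (v in list(G, F)) {
      expect_true(all(v >= 0 & v <= 1))
      expect_true(all(diff(v) >= 0))
    }
  }
})

test_that("statistics respect hard-core dispersal at small radii", {
  p <- random_pattern(200, seed = 77, hard_core = 0.02)
  grid <- radius_grid()
  below <- grid$r < 0.02
  g <- pair_correlation(p, grid)
  G <- nn_distribution(p, grid)
  F <- spherical_contact(p, grid, seed = 78)
  J <- j_function(G, F)
  expect_true(all(G$values[below] == 0))
  bins_below <- grid$r + grid$dr / 2 <= 0.02
  expect_true(all(g$values[bins_below] == 0))
  expect_true(all(J$values[below & J$defined] >= 1))
})

test_that("summary features match their definitions and oracles", {
  grid <- radius_grid()
  # F_max is the largest observed reference distance; g_max the curve peak
  p <- random_pattern(100, seed = 21, hard_core = 0.02)
  sf <- summary_features(p, grid, seed = 22)
  F <- spherical_contact(p, grid, seed = 22)
  expect_equal(sf$F_max, max(attr(F, "distances")))
  expect_equal(sf$g_max, max(pair_correlation(p, grid)$values))
  expect_gte(sf$J_min, 0)
  expect_lte(sf$J_min, 1)
  expect_equal(sf$d, pattern_density(p))

  # J_min equals an independent re-implementation on hard-core CSR at
  # the cohort density
  p2 <- random_pattern(round(333 * 2.25), seed = 31, hard_core = 0.02)
  sf2 <- summary_features(p2, grid, seed = 32)
  G2 <- nn_distribution(p2, grid)
  F2 <- spherical_contact(p2, grid, seed = 32)
  expect_equal(sf2$J_min,
               oracle_jmin(attr(G2, "distances"), attr(F2, "distances")),
               tolerance = 1e-12)
})

test_that("statistics are invariant under symmetries of the square window", {
  w <- roi_window()
  grid <- radius_grid()
  p <- random_pattern(60, w, seed = 55)
  # 90-degree rotation about the window centre
  rot <- point_pattern(p$y, w$width - p$x, w)
  expect_equal(pair_correlation(rot, grid)$values,
               pair_correlation(p, grid)$values, tolerance = 1e-10)
  expect_equal(nn_distribution(rot, grid)$values,
               nn_distribution(p, grid)$values, tolerance = 1e-12)
  # F with co-rotated reference points
  set.seed(66)
  refs <- list(x = runif(60, 0, 1.5), y = runif(60, 0, 1.5))
  refs_rot <- list(x = refs$y, y = w$width - refs$x)
  expect_equal(spherical_contact(rot, grid, reference_points = refs_rot)$values,
               spherical_contact(p, grid, reference_points = refs)$values,
               tolerance = 1e-12)
  # G depends only on pairwise distances: exact translation invariance
  shift <- point_pattern(p$x / 2 + 0.1, p$y / 2 + 0.2, w)
  base <- point_pattern(p$x / 2, p$y / 2, w)
  expect_equal(nn_distribution(shift, grid)$values,
               nn_distribution(base, grid)$values, tolerance = 1e-12)
})

test_that("curves export as tidy data frames", {
  p <- random_pattern(30, seed = 91)
  g <- pair_correlation(p, radius_grid())
  df <- as.data.frame(g)
  expect_named(df, c("kind", "r", "value"))
  expect_equal(nrow(df), length(g$r))
  expect_true(all(df$kind == "PCF"))
})
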