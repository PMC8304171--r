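test_that("mean nearest-neighbour distance matches hand computations", {
  expect_equal(mean_nn_distance(point_pattern(c(0, 3), c(0, 0), area = 10)), 3)
  # collinear points at 0, 1, 3: NN distances 1, 1, 2
  expect_equal(mean_nn_distance(point_pattern(c(0, 1, 3), c(0, 0, 0), area = 10)),
               4 / 3)
  sq <- point_pattern(c(0, 1, 0, 1), c(0, 0, 1, 1), area = 1)
  expect_equal(mean_nn_distance(sq), 1)
  expect_error(mean_nn_distance(point_pattern(1, 1, area = 1)), "two points")
})

test_that("expected random nearest-neighbour distance follows (1/2) sqrt(S/N)", {
  expect_equal(expected_random_nn(1, 4), 0.25)
  expect_equal(expected_random_nn(100, 25), 1)
  expect_equal(expected_random_nn(5.18 * 6.7, 500), 0.5 * sqrt(34.706 / 500),
               tolerance = 1e-12)
  expect_error(expected_random_nn(-1, 10), "positive")
  expect_error(expected_random_nn(1, 0), "positive")
})

test_that("Poisson nearest-neighbour density integrates to 1 with mean 1/(2 sqrt(delta))", {
  expect_equal(nn_distance_density(0, 2), 0)
  for (delta in c(0.5, 3, 14.4)) {
    total <- integrate(nn_distance_density, 0, Inf, density = delta)$value
    expect_equal(total, 1, tolerance = 1e-6)
    mu <- integrate(function(r) r * nn_distance_density(r, delta), 0, Inf)$value
    expect_equal(mu, 1 / (2 * sqrt(delta)), tolerance = 1e-6)
    # consistency with the random expectation at S = N / delta
    expect_equal(mu, expected_random_nn(100 / delta, 100), tolerance = 1e-6)
  }
  expect_error(nn_distance_density(-0.1, 1), "non-negative")
})

test_that("spatial entropy equals an O(N^2) brute-force oracle on random instances", {
  set.seed(13)
  for (n in c(5, 37, 200, 500)) {
    p <- generate_random_pattern(n)
    expect_equal(nn_distances(p), unname(oracle_nn(p$x, p$y)),
                 tolerance = 1e-12)
    expect_equal(spatial_entropy(p)$Hs,
                 oracle_spatial_entropy(p$x, p$y, p$area),
                 tolerance = 1e-12)
  }
  # clustered patterns stress the grid search with crowded cells
  cl <- generate_clustered_pattern(300, spread = 0.15, seed = 5)
  expect_equal(nn_distances(cl), unname(oracle_nn(cl$x, cl$y)),
               tolerance = 1e-12)
})

test_that("spatial entropy handles boundary cases: tiny n and duplicates", {
  sq <- point_pattern(c(0, 1, 0, 1), c(0, 0, 1, 1), area = 1)
  expect_equal(spatial_entropy(sq)$Hs, 4)     # small-n boundary effect > ceiling
  dup <- point_pattern(c(1, 1, 2), c(1, 1, 2), area = 10)
  expect_equal(nn_distances(dup)[1:2], c(0, 0))
})

test_that("Hs is invariant under rigid motion and joint rescaling", {
  set.seed(99)
  p <- generate_random_pattern(120)
  h0 <- spatial_entropy(p)$Hs
  th <- 0.7
  xr <- p$x * cos(th) - p$y * sin(th) + 5
  yr <- p$x * sin(th) + p$y * cos(th) - 2
  expect_equal(spatial_entropy(point_pattern(xr, yr, area = p$area))$Hs, h0,
               tolerance = 1e-10)
  expect_equal(spatial_entropy(point_pattern(3 * p$x, 3 * p$y,
                                             area = 9 * p$area))$Hs, h0,
               tolerance = 1e-10)
})

test_that("random patterns are reproducible and statistically uniform", {
  a <- generate_random_pattern(500, seed = 21)
  b <- generate_random_pattern(500, seed = 21)
  expect_identical(a$x, b$x); expect_identical(a$y, b$y)
  geom <- court_geometry()
  # mean x over 500 uniform draws: sd = width / sqrt(12 * 500)
  expect_lt(abs(mean(a$x) - geom$width / 2),
            3 * geom$width / sqrt(12 * 500))
})

test_that("uniform patterns give Clark-Evans ratios near 1", {
  hs <- vapply(1:100, function(i)
    spatial_entropy(generate_random_pattern(500, seed = 1000 + i))$Hs,
    numeric(1))
  expect_gt(mean(hs), 0.95)
  expect_lt(mean(hs), 1.05)
})

test_that("the triangular lattice is regular, near the ceiling, and scales as 1/sqrt(N)", {
  expect_equal(lattice_ceiling(), 2.149, tolerance = 5e-4)
  lat <- generate_lattice_pattern(1000)
  expect_gt(lat$n, 900); expect_lt(lat$n, 1100)
  d <- nn_distances(lat)
  expect_lt(diff(range(d)), 1e-9)           # all NN spacings equal
  hs <- spatial_entropy(lat)$Hs
  expect_gt(hs, 1.9); expect_lte(hs, lattice_ceiling() + 1e-9)

  lat2 <- generate_lattice_pattern(2000)
  ratio <- mean_nn_distance(lat) / mean_nn_distance(lat2)
  expect_equal(ratio, sqrt(2), tolerance = 0.02)
})

test_that("clustered patterns are clustered, and spread loosens them monotonically", {
  hs_spread <- vapply(c(0.1, 0.4, 1.0), function(s) {
    mean(vapply(1:100, function(i)
      spatial_entropy(generate_clustered_pattern(500, spread = s,
                                                 seed = 2000 + i))$Hs,
      numeric(1)))
  }, numeric(1))
  expect_lt(hs_spread[2], 1)                 # corner clusters at 0.4 m
  expect_true(all(diff(hs_spread) > 0))      # looser clusters, higher Hs
  # coincident limit: spread -> 0 drives Hs toward 0
  tight <- generate_clustered_pattern(200, spread = 1e-4, seed = 8)
  expect_lt(spatial_entropy(tight)$Hs, 0.01)
})

test_that("point patterns round-trip through CSV plus sidecar JSON", {
  p <- generate_random_pattern(50, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_point_pattern(p, f)
  q <- read_point_pattern(f)
  expect_equal(q$x, p$x, tolerance = 1e-12)
  expect_equal(q$area, p$area)
})
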