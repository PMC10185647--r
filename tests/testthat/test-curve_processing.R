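test_that("Savitzky-Golay smoothing reproduces polynomials exactly", {
  grid <- melt_grid()
  const <- melt_curve("W", "S", grid, rep(5, length(grid)))
  expect_equal(smooth_curve(const)$fluorescence, rep(5, length(grid)))
  line <- melt_curve("W", "S", grid, -2 * grid + 300)
  expect_lt(max(abs(smooth_curve(line, 11, 2)$fluorescence -
                      (-2 * grid + 300))), 1e-9)
  cubic <- melt_curve("W", "S", grid, 0.001 * (grid - 70)^3 + grid)
  expect_lt(max(abs(smooth_curve(cubic, 11, 3)$fluorescence -
                      cubic$fluorescence)), 1e-8)
})

test_that("smoothing attenuates noise around a melting transition", {
  set.seed(101)
  grid <- melt_grid()
  clean <- logistic_melt(grid)$fluorescence
  noisy <- clean + rnorm(length(grid), sd = 0.01)
  sm <- smooth_curve(melt_curve("W", "S", grid, noisy), 11, 3)$fluorescence
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(sm - clean), rms(noisy - clean))
})

test_that("smoothing parameters are validated", {
  cu <- logistic_melt()
  expect_error(smooth_curve(cu, 10, 3), "odd")
  expect_error(smooth_curve(cu, 3, 3), "poly_order")
  expect_error(smooth_curve(cu, 999, 3), "length")
})

test_that("negative derivative matches closed forms", {
  grid <- melt_grid()
  const <- melt_curve("W", "S", grid, rep(7, length(grid)))
  expect_equal(negative_derivative(const)$neg_dfdt, rep(0, length(grid)))
  ramp <- melt_curve("W", "S", grid, -grid)
  expect_equal(negative_derivative(ramp)$neg_dfdt, rep(1, length(grid)))
  # logistic: -dF/dT peaks at Tm with height A / (4 w)
  d <- negative_derivative(logistic_melt(grid, tm = 79.5, w = 0.8, A = 1))
  expect_length(d$neg_dfdt, length(grid))
  tmax <- d$temperatures[which.max(d$neg_dfdt)]
  expect_gte(tmax, 79.4); expect_lte(tmax, 79.6)
  expect_equal(max(d$neg_dfdt), 1 / (4 * 0.8), tolerance = 0.02)
})

test_that("derivative is non-negative wherever fluorescence is non-increasing", {
  set.seed(5)
  for (i in 1:5) {
    cu <- logistic_melt(tm = runif(1, 70, 85), w = runif(1, 0.4, 2))
    d <- negative_derivative(cu)
    dec <- which(diff(cu$fluorescence) <= 0)
    interior <- intersect(dec, 2:(length(cu$fluorescence) - 1))
    expect_true(all(d$neg_dfdt[interior] >= 0))
  }
})

test_that("difference curves obey identity, antisymmetry and linearity", {
  a <- logistic_melt(tm = 80.0)
  b <- logistic_melt(tm = 78.5, well = "W2", sample = "S2")
  expect_equal(difference_curve(a, a)$fluorescence,
               rep(0, length(a$temperatures)))
  expect_equal(difference_curve(a, b)$fluorescence,
               -difference_curve(b, a)$fluorescence)
  shifted <- melt_curve("W", "S", a$temperatures, a$fluorescence + 3)
  expect_equal(difference_curve(shifted, b)$fluorescence,
               difference_curve(a, b)$fluorescence + 3)
  expect_equal(difference_curve(a, b, invert = TRUE)$fluorescence,
               difference_curve(b, a)$fluorescence)
})

test_that("difference of two shifted transitions is bipolar with extrema between the Tms", {
  a <- logistic_melt(tm = 80.0)
  b <- logistic_melt(tm = 78.5, well = "W2")
  d <- difference_curve(a, b)
  # F_a > F_b everywhere (higher Tm melts later), so the difference is
  # one-signed with its extremum between the two Tms
  expect_true(all(d$fluorescence >= 0))
  t_ext <- d$temperatures[which.max(abs(d$fluorescence))]
  expect_gt(t_ext, 78.5); expect_lt(t_ext, 80.0)
  # sample - reference of equal-amplitude sigmoids with reference melting
  # later is the mirror (bipolar the other way)
  d2 <- difference_curve(b, a)
  expect_true(all(d2$fluorescence <= 0))
})

test_that("difference curve requires a shared grid", {
  a <- logistic_melt()
  b <- logistic_melt(grid = melt_grid(45, 95, 0.4), well = "W2")
  expect_error(difference_curve(a, b), "shared temperature grid")
})

test_that("peak detection finds single and mixed transitions in a window", {
  d <- negative_derivative(logistic_melt(tm = 79.5, w = 0.8))
  pk <- detect_peaks(d, c(78, 81))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$tm - 79.5), 0.2 + 1e-9)
  expect_gt(pk$height, 0)
  # two transitions, window covering only the hotter one
  d2 <- negative_derivative(two_peak_melt(tm1 = 75.5, tm2 = 79.5))
  pk2 <- detect_peaks(d2, c(78, 81))
  expect_equal(nrow(pk2), 1L)
  expect_lt(abs(pk2$tm - 79.5), 0.2 + 1e-9)
  # both in a wide window, sorted by height descending
  d3 <- negative_derivative(two_peak_melt(A1 = 2, A2 = 1))
  pk3 <- detect_peaks(d3, c(70, 85))
  expect_equal(nrow(pk3), 2L)
  expect_lt(abs(pk3$tm[1] - 75.5), 0.2 + 1e-9)
  expect_gte(pk3$height[1], pk3$height[2])
})

test_that("peak detection handles flat input and bad windows", {
  grid <- melt_grid()
  flat <- negative_derivative(melt_curve("W", "S", grid, rep(1, length(grid))))
  expect_equal(nrow(detect_peaks(flat, c(70, 90))), 0L)
  d <- negative_derivative(logistic_melt())
  expect_error(detect_peaks(d, c(96, 99)), "window")
})

test_that("peak location error stays within one grid step across widths", {
  set.seed(202)
  for (i in 1:10) {
    tm <- runif(1, 70, 85)
    w <- runif(1, 0.4, 1.5)
    d <- negative_derivative(smooth_curve(logistic_melt(tm = tm, w = w)))
    pk <- detect_peaks(d, c(tm - 3, tm + 3))
    expect_gte(nrow(pk), 1L)
    expect_lte(abs(pk$tm[1] - tm), 0.2 + 1e-9)
  }
})
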