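test_that("wrap_angle maps onto [-pi, pi) with the half-open convention", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(pi), -pi)          # boundary maps down
  expect_equal(wrap_angle(-pi), -pi)
  expect_error(wrap_angle(Inf), class = "retropop_invalid_angle")
  expect_error(wrap_angle(NA_real_), class = "retropop_invalid_angle")
})

test_that("wrap_angle is idempotent and congruent mod 2*pi", {
  withr::with_seed(11, {
    x <- runif(500, -100, 100)
    w <- wrap_angle(x)
    expect_true(all(w >= -pi & w < pi))
    expect_equal(wrap_angle(w), w)
    expect_equal(sin(w), sin(x), tolerance = 1e-9)
    expect_equal(cos(w), cos(x), tolerance = 1e-9)
  })
})

test_that("circ_dist takes the short way around and is antisymmetric", {
  expect_equal(circ_dist(pi / 4, -pi / 4), pi / 2)
  expect_equal(circ_dist(-pi + 0.1, pi - 0.1), 0.2)
  expect_equal(circ_dist(1.3, 1.3), 0)
  withr::with_seed(12, {
    a <- runif(300, -pi, pi)
    b <- runif(300, -pi, pi)
    d <- circ_dist(a, b)
    expect_true(all(abs(d) <= pi))
    keep <- abs(d) < pi - 1e-9
    expect_equal(circ_dist(b, a)[keep], -d[keep])
  })
})

test_that("feature-space conversion scales one period onto the circle", {
  col <- feature_space("color", 360)
  ori <- feature_space("orientation", 180)
  expect_equal(to_internal(90, col), pi / 2)
  expect_equal(to_internal(90, ori), -pi)    # doubled, then wrapped
  expect_equal(to_internal(0, ori), 0)
  withr::with_seed(13, {
    for (sp in list(col, ori)) {
      v <- runif(200, -sp$period_degrees / 2, sp$period_degrees / 2 - 1e-6)
      expect_equal(from_internal(to_internal(v, sp), sp), v, tolerance = 1e-12)
    }
  })
  expect_error(feature_space("x", 0))
})

test_that("circ_mean returns the resultant direction and flags degeneracy", {
  m <- circ_mean(c(0, pi / 2))
  expect_equal(m$direction, pi / 4)
  expect_equal(m$resultant_length, cos(pi / 4), tolerance = 1e-12)
  one <- circ_mean(1.1)
  expect_equal(one$direction, 1.1)
  expect_equal(one$resultant_length, 1)
  anti <- circ_mean(c(0, pi))
  expect_true(anti$degenerate)
  expect_true(is.na(anti$direction))
  wm <- circ_mean(c(0, pi / 2), weights = c(1, 0))
  expect_equal(wm$direction, 0)
  expect_error(circ_mean(numeric(0)))
  expect_error(circ_mean(c(0, 1), weights = c(0, 0)))
})

test_that("vm_pdf matches a series-evaluated oracle and normalizes", {
  expect_equal(vm_pdf(0.7, kappa = 0), 1 / (2 * pi))
  # independent oracle: exp(2) / (2*pi*I0(2)) with I0 from its power series
  expect_equal(vm_pdf(0, kappa = 2), exp(2) / (2 * pi * I0_series(2)),
               tolerance = 1e-12)
  for (k in c(0.5, 5, 50)) {
    expect_equal(circ_quad(function(x) vm_pdf(x, k)), 1, tolerance = 1e-9)
  }
  # exponent-shifted evaluation survives very large concentrations
  expect_true(is.finite(vm_pdf(0, kappa = 1e4)))
  expect_equal(vm_pdf(pi, kappa = 1e4), 0)
})

test_that("rvonmises concentrates as A(kappa) predicts and is seed-stable", {
  withr::with_seed(14, {
    th <- rvonmises(40000, 4, mu = 0.5)
    R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    expect_equal(R, besselI(4, 1) / besselI(4, 0), tolerance = 0.01)
    expect_equal(atan2(mean(sin(th)), mean(cos(th))), 0.5, tolerance = 0.02)
  })
  withr::with_seed(15, a <- rvonmises(100, 2))
  withr::with_seed(15, b <- rvonmises(100, 2))
  expect_identical(a, b)
  withr::with_seed(16, u <- rvonmises(20000, 0))
  expect_lt(sqrt(mean(cos(u))^2 + mean(sin(u))^2), 0.03)
})
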