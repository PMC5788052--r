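test_that("tuning width converts between FWHM and concentration", {
  expect_equal(fwhm_from_kappa(log(2)), pi)
  for (fw in c(0.5, 1.22, 3.0)) {
    expect_equal(fwhm_from_kappa(kappa_from_fwhm(fw)), fw, tolerance = 1e-10)
  }
  # independent oracle: bisection on fwhm_from_kappa
  target_fwhm <- 1.22
  lo <- 0.5; hi <- 50
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (fwhm_from_kappa(mid) > target_fwhm) lo <- mid else hi <- mid
  }
  expect_equal(kappa_from_fwhm(1.22), (lo + hi) / 2, tolerance = 1e-6)
  # widths below the half-max-on-circle limit hit the sentinel
  expect_equal(fwhm_from_kappa(log(2) / 2 - 0.01), 2 * pi)
  expect_error(kappa_from_fwhm(0))
  expect_error(kappa_from_fwhm(2 * pi))
})

test_that("expected_rates peak at the preferred value and sum to the Bessel limit", {
  p <- pop_params(rmax = 15, fwhm = 1.25, window = 1, n_neurons = 100)
  phi1 <- attr(expected_rates(0, p), "preferred")[1]
  lam <- expected_rates(phi1, p)
  expect_equal(lam[1], 15)                       # peak = rmax * window
  flat <- pop_params(rmax = 3, kappa = 1e-9, window = 1, n_neurons = 10)
  expect_equal(as.numeric(expected_rates(0.3, flat)), rep(3, 10),
               tolerance = 1e-8)
  lam_tot <- sum(expected_rates(0.123, p))
  bessel_limit <- 100 * 15 * exp(-p$kappa) * besselI(p$kappa, 0)
  expect_equal(lam_tot, bessel_limit, tolerance = 1e-3)
  expect_equal(pop_gain(p), bessel_limit, tolerance = 1e-12)
})

test_that("sample_spikes draws Poisson counts with the tuned means", {
  p0 <- pop_params(rmax = 0, fwhm = 1.25)
  expect_true(all(sample_spikes(0, p0, seed = 1)$counts == 0))
  p <- pop_params(rmax = 15, fwhm = 1.25, window = 0.02)
  lam_tot <- sum(expected_rates(0.4, p))
  tot <- withr::with_seed(21, {
    vapply(1:10000, function(i) sum(sample_spikes(0.4, p)$counts), numeric(1))
  })
  se <- sqrt(lam_tot / 10000)                    # Poisson variance = mean
  expect_lt(abs(mean(tot) - lam_tot), 3 * se)
  expect_identical(sample_spikes(0.4, p, seed = 7)$counts,
                   sample_spikes(0.4, p, seed = 7)$counts)
})

test_that("decode_map recovers resultant directions and flags degenerate patterns", {
  p <- pop_params(rmax = 5, fwhm = 1.5, n_neurons = 12)
  phi <- attr(expected_rates(0, p), "preferred")
  one <- list(counts = as.integer(phi == phi[3]), preferred = phi, stimulus = 0)
  expect_equal(decode_map(one, p)$estimate, phi[3])
  # one spike at 0 and one at pi/2 -> resultant at pi/4
  i0 <- which.min(abs(phi)); i90 <- which.min(abs(phi - pi / 2))
  two <- list(counts = as.integer(seq_along(phi) %in% c(i0, i90)),
              preferred = phi, stimulus = 0)
  expect_equal(decode_map(two, p)$estimate, (phi[i0] + phi[i90]) / 2)
  none <- list(counts = integer(12), preferred = phi, stimulus = 0)
  d <- decode_map(none, p, seed = 5)
  expect_true(d$degenerate)
  expect_true(d$estimate >= -pi && d$estimate < pi)
  expect_identical(decode_map(none, p, seed = 5)$estimate,
                   decode_map(none, p, seed = 5)$estimate)
})

test_that("zero-spike (degenerate) trials occur at the Poisson rate exp(-gain)", {
  p <- pop_params(rmax = 7, fwhm = 1.25)      # gain ~ 1.5: measurable zero mass
  lam <- pop_gain(p)
  n <- 20000
  zero_frac <- withr::with_seed(22, {
    lam_i <- expected_rates(0, p)
    counts <- matrix(rpois(n * length(lam_i), rep(lam_i, each = n)), nrow = n)
    mean(rowSums(counts) == 0)
  })
  se <- sqrt(exp(-lam) * (1 - exp(-lam)) / n)
  expect_lt(abs(zero_frac - exp(-lam)), 3 * se)
})
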