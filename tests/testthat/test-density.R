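test_that("predicted error densities normalize, are symmetric, and sharpen with gain", {
  sds <- vapply(c(1, 2, 5, 10, 20, 50), function(r) {
    d <- error_density(pop_params(rmax = r, fwhm = 1.25))
    step <- 2 * pi / nrow(d)
    expect_equal(sum(d$density) * step, 1, tolerance = 1e-3)
    pos <- d$density[d$error > 1e-12]
    neg <- rev(d$density[d$error < -1e-12][-1])   # mirror, dropping -pi
    expect_equal(pos, neg, tolerance = 1e-10)
    grid_circ_sd <- function(grid, dens) {
      w <- dens / sum(dens)
      sqrt(-2 * log(sqrt(sum(w * cos(grid))^2 + sum(w * sin(grid))^2)))
    }
    grid_circ_sd(d$error, d$density)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))   # circular SD strictly decreases with rmax
})

test_that("the density collapses to uniform as rmax goes to zero", {
  d <- error_density(pop_params(rmax = 1e-9, fwhm = 1.25))
  expect_equal(d$density, rep(1 / (2 * pi), nrow(d)), tolerance = 1e-6)
})

test_that("quadrature and Monte Carlo density evaluations agree", {
  p <- pop_params(rmax = 15, fwhm = 1.25)
  dq <- error_density(p)
  dm <- error_density(p, density_settings(method = "mc", n_draws = 50000L,
                                          seed = 33))
  # aggregate to 10-degree bins; Monte Carlo noise per bin is well below 3%
  agg <- function(x) colSums(matrix(x, nrow = 10))
  q <- agg(dq$density); m <- agg(dm$density)
  core <- m > 2          # high-density bins, where MC noise is below 1%
  expect_lt(max(abs(q[core] - m[core]) / m[core]), 0.04)
  expect_lt(max(abs(q - m)) * (2 * pi / 360), 0.01)   # mass error per 10-deg bin
})

test_that("densities are cached, exportable, and interpolate linearly", {
  p <- pop_params(rmax = 12, fwhm = 1.4)
  d1 <- error_density(p)
  d2 <- error_density(p)
  expect_identical(d1$density, d2$density)
  path <- withr::local_tempfile(fileext = ".csv")
  write_density(d1, path)
  d3 <- read_density(path)
  expect_equal(d3$density, d1$density, tolerance = 1e-12)
  expect_equal(attr(d3, "gain"), attr(d1, "gain"), tolerance = 1e-12)
  # interpolation: exact at nodes, linear between
  i <- which(d1$error > 0.1)[1]
  expect_equal(density_at(d1, d1$error[i]), d1$density[i], tolerance = 1e-12)
  mid <- (d1$error[i] + d1$error[i + 1]) / 2
  expect_equal(density_at(d1, mid), (d1$density[i] + d1$density[i + 1]) / 2,
               tolerance = 1e-12)
})

test_that("popmodel_loglik reduces correctly and conserves mixture weights", {
  tr1 <- make_trials(target = 0.3, response = 0.3,
                     nontargets = matrix(c(-2, 2), 1))
  # pure guessing: density is uniform whatever the response
  pg <- pop_params(rmax = 15, fwhm = 1.25, pguess = 1)
  expect_equal(popmodel_loglik(tr1, pg), -log(2 * pi), tolerance = 1e-9)
  trT <- make_trials(target = rep(0.3, 5), response = rep(0.3, 5))
  p0 <- pop_params(rmax = 15, fwhm = 1.25)
  d <- error_density(p0)
  expect_equal(popmodel_loglik(trT, p0), 5 * log(density_at(d, 0)),
               tolerance = 1e-9)
  # weights (1 - ps - pg, ps, pg) recompose the per-trial density exactly
  pmix <- pop_params(rmax = 15, fwhm = 1.25, pswap = 0.22, pguess = 0.13)
  ll <- popmodel_loglik(tr1, pmix)
  by_hand <- log(
    (1 - 0.22 - 0.13) * density_at(d, tr1$response - tr1$target) +
      0.22 / 2 * (density_at(d, tr1$response - tr1$nontarget_1) +
                  density_at(d, tr1$response - tr1$nontarget_2)) +
      0.13 / (2 * pi))
  expect_equal(ll, by_hand, tolerance = 1e-9)
})

test_that("the likelihood peaks near the generating parameters", {
  wins <- vapply(1:8, function(rep) {
    tr <- generate_experiment(experiment_design(
      n_subjects = 1, trials_per_condition = 1000,
      conditions = list(retrocue = pop_params(rmax = 15, fwhm = 1.25),
                        control = pop_params(rmax = 15, fwhm = 1.25)),
      seed = 100 + rep))
    tr <- tr[tr$condition == "retrocue", ]
    ll_true <- popmodel_loglik(tr, pop_params(rmax = 15, fwhm = 1.25))
    ll_lo <- popmodel_loglik(tr, pop_params(rmax = 7.5, fwhm = 1.25))
    ll_hi <- popmodel_loglik(tr, pop_params(rmax = 22.5, fwhm = 1.25))
    ll_true > ll_lo && ll_true > ll_hi
  }, logical(1))
  expect_gte(mean(wins), 7 / 8)
})

test_that("an infeasible truncation cap raises a settings error", {
  s <- density_settings(n_cap = 60L)
  expect_error(
    popmodel_loglik(make_trials(0, 0), pop_params(rmax = 500, fwhm = 1.25), s),
    class = "retropop_gain_cap")
})

test_that("set-size and swap preconditions are enforced", {
  tr <- make_trials(target = c(0, 0.5), response = c(0.1, 0.4))
  expect_error(popmodel_loglik(tr, pop_params(rmax = 10, fwhm = 1.25, pswap = 0.1)),
               "set size")
  mixed <- dplyr::bind_rows(
    make_trials(0, 0.1),
    make_trials(0, 0.1, nontargets = matrix(1, 1)))
  expect_error(popmodel_loglik(mixed, pop_params(rmax = 10, fwhm = 1.25)),
               "one set size")
})
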