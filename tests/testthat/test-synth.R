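test_that("generated arrays respect the minimum separation and the schema", {
  d <- experiment_design(n_subjects = 2, trials_per_condition = 120,
                         set_size = 4, min_separation = 0.5, seed = 71)
  tr <- generate_experiment(d)
  expect_silent(validate_trials(tr))
  vals <- cbind(tr$target, tr$nontarget_1, tr$nontarget_2, tr$nontarget_3)
  min_sep <- apply(vals, 1, function(v) {
    dd <- abs(circ_dist(rep(v, each = 4), rep(v, 4)))
    min(dd[dd > 0])
  })
  expect_true(all(min_sep >= 0.5))
  expect_error(experiment_design(set_size = 20, min_separation = 0.5),
               "feasible")
})

test_that("generation is reproducible under the design seed", {
  d <- experiment_design(n_subjects = 2, trials_per_condition = 40, seed = 72)
  expect_identical(generate_experiment(d)$response,
                   generate_experiment(d)$response)
  d2 <- experiment_design(n_subjects = 2, trials_per_condition = 40, seed = 73)
  expect_false(identical(generate_experiment(d)$response,
                         generate_experiment(d2)$response))
})

test_that("a silent population produces uniform responses", {
  d <- experiment_design(
    n_subjects = 1, trials_per_condition = 2000,
    conditions = list(retrocue = pop_params(rmax = 0, fwhm = 1.25),
                      control = pop_params(rmax = 0, fwhm = 1.25)),
    seed = 74)
  tr <- generate_experiment(d)
  tr <- tr[tr$condition == "retrocue", ]
  eps <- circ_dist(tr$response, tr$target)
  expect_lt(sqrt(mean(cos(eps))^2 + mean(sin(eps))^2), 0.05)
})

test_that("pswap = 1 swaps the roles of target and non-target", {
  base <- list(
    swapped = pop_params(rmax = 15, fwhm = 1.25, pswap = 1),
    clean = pop_params(rmax = 15, fwhm = 1.25, pswap = 0))
  mk <- function(par, seed) {
    d <- experiment_design(n_subjects = 1, trials_per_condition = 2000,
                           set_size = 2,
                           conditions = list(retrocue = par, control = par),
                           seed = seed)
    tr <- generate_experiment(d)
    tr[tr$condition == "retrocue", ]
  }
  tr_swap <- mk(base$swapped, 75)
  tr_clean <- mk(base$clean, 76)
  err_to_nt <- circ_dist(tr_swap$response, tr_swap$nontarget_1)
  err_to_t <- circ_dist(tr_clean$response, tr_clean$target)
  ks <- suppressWarnings(stats::ks.test(err_to_nt, err_to_t))
  expect_gt(ks$p.value, 0.01)
})

test_that("the generator agrees with the analytic error density", {
  p <- pop_params(rmax = 15, fwhm = 1.25)
  d <- experiment_design(n_subjects = 1, trials_per_condition = 20000,
                         conditions = list(retrocue = p, control = p),
                         seed = 77)
  dsn <- d; dsn$conditions$control <- pop_params(rmax = 1e-6, fwhm = 1.25)
  tr <- generate_experiment(dsn)
  tr <- tr[tr$condition == "retrocue", ]
  eps <- circ_dist(tr$response, tr$target)
  breaks <- seq(-pi, pi, length.out = 37)
  obs <- tabulate(findInterval(eps, breaks, all.inside = TRUE), 36)
  dens <- error_density(p)
  # bin masses by midpoint quadrature of the interpolated density
  sub <- 40L
  fine <- seq(-pi, pi, length.out = 36 * sub + 1)
  mids <- fine[-1] - diff(fine) / 2
  pr <- tapply(density_at(dens, mids) * (2 * pi / (36 * sub)),
               rep(1:36, each = sub), sum)
  chi <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr)))
  expect_gt(chi$p.value, 0.01)
})

test_that("recovery_study validates its inputs and summarizes recovery", {
  expect_error(experiment_design(trials_per_condition = 0), ">= 1")
  d <- experiment_design(
    n_subjects = 3, trials_per_condition = 80,
    conditions = list(retrocue = mixture_params(10, pguess = 0.1),
                      control = mixture_params(10, pguess = 0.25)),
    seed = 78)
  expect_error(recovery_study(d, model_spec("popcode")), "family")
  rec <- suppressWarnings(   # 3 subjects: signed-rank power warning expected
    recovery_study(d, model_spec("normal_uniform"),
                   fit_options(n_starts = 3, min_trials = 20), seed = 1))
  expect_s3_class(rec, "rc_recovery")
  expect_setequal(unique(rec$summary$term), c("kappa_prime", "pguess"))
  expect_true(all(rec$summary$rmse >= abs(rec$summary$bias) - 1e-9))
  expect_equal(nrow(rec$fits), 6)
  expect_true(all(c("term", "p_value") %in% names(rec$contrasts)))
})
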