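test_that("parameter transforms round-trip and keep the simplex safe", {
  specs <- list(model_spec("popcode", with_swaps = TRUE, with_guess = TRUE),
                model_spec("popcode", with_swaps = TRUE),
                model_spec("popcode"),
                model_spec("normal_uniform", with_swaps = TRUE),
                model_spec("normal_uniform"))
  withr::with_seed(41, {
    for (spec in specs) {
      for (i in 1:20) {
        vals <- list(rmax = exp(runif(1, 0, 5)),
                     kappa = log(2) / 2 + exp(runif(1, -2, 4)),
                     kappa_prime = exp(runif(1, -1, 6)))
        ps <- runif(1, 1e-4, 0.5); pg <- runif(1, 1e-4, 0.4)
        vals$pswap <- ps; vals$pguess <- pg
        th <- retropop:::transform_params(vals, spec)
        expect_length(th, spec$k)
        back <- retropop:::untransform_params(th, spec)
        for (nm in intersect(names(back), names(vals))) {
          free <- nm %in% c(retropop:::free_prob_names(spec),
                            if (spec$family == "popcode") c("rmax", "kappa", "fwhm")
                            else "kappa_prime")
          if (free && nm != "fwhm") {
            expect_equal(back[[nm]], vals[[nm]], tolerance = 1e-10)
          }
        }
      }
      # arbitrary unconstrained vectors always map into the valid region
      for (i in 1:30) {
        th <- runif(spec$k, -20, 20)
        back <- retropop:::untransform_params(th, spec)
        expect_gte(back$pswap, 0)
        expect_gte(back$pguess, 0)
        expect_lte(back$pswap + back$pguess, 1)
      }
    }
  })
})

test_that("aic follows 2k - 2*loglik", {
  expect_equal(aic(-100, 2), 204)
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(-50, 4) - aic(-60, 2), 2 * (4 - 2) - 2 * (-50 - -60))
  expect_error(aic(0, 0))
})

test_that("model_spec counts free parameters from its flags", {
  expect_equal(model_spec("popcode")$k, 2)
  expect_equal(model_spec("popcode", with_swaps = TRUE)$k, 3)
  expect_equal(model_spec("popcode", with_swaps = TRUE, with_guess = TRUE)$k, 4)
  expect_equal(model_spec("normal_uniform")$k, 2)
  expect_equal(model_spec("normal_uniform", with_swaps = TRUE)$k, 3)
  expect_error(model_spec("normal_uniform", with_guess = TRUE))
})

test_that("fit_mle recovers mixture parameters and is seed-deterministic", {
  tr <- generate_experiment(experiment_design(
    n_subjects = 1, trials_per_condition = 500,
    conditions = list(retrocue = mixture_params(12, pguess = 0.1),
                      control = mixture_params(12, pguess = 0.1)),
    seed = 42))
  tr <- tr[tr$condition == "retrocue", ]
  f <- fit_mle(tr, model_spec("normal_uniform"), fit_options(n_starts = 5),
               seed = 3)
  expect_s3_class(f, "rc_fit")
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["kappa_prime"]] - 12) / 12, 0.2)
  expect_lt(abs(f$estimates[["pguess"]] - 0.1), 0.05)
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)
  expect_gte(f$loglik, max(f$starts$loglik) - 1e-9)
  f2 <- fit_mle(tr, model_spec("normal_uniform"), fit_options(n_starts = 5),
                seed = 3)
  expect_identical(f$estimates, f2$estimates)
  expect_identical(f$loglik, f2$loglik)
  # broom-style accessors
  expect_named(tidy(f), c("term", "estimate"))
  expect_equal(glance(f)$aic, f$aic)
})

test_that("fit preconditions are enforced", {
  small <- make_trials(runif(5, -1, 1), runif(5, -1, 1))
  expect_error(fit_mle(small, model_spec("normal_uniform")),
               class = "retropop_few_trials")
  ss1 <- make_trials(runif(30, -1, 1), runif(30, -1, 1))
  expect_error(fit_mle(ss1, model_spec("normal_uniform", with_swaps = TRUE)),
               class = "retropop_model_spec")
})

test_that("compare_models handles identical fits with the tie conventions", {
  tr <- generate_experiment(experiment_design(
    n_subjects = 3, trials_per_condition = 60,
    conditions = list(retrocue = mixture_params(8, pguess = 0.1),
                      control = mixture_params(8, pguess = 0.1)),
    seed = 43))
  tr <- tr[tr$condition == "retrocue", ]
  fits <- fit_participants(tr, model_spec("normal_uniform"),
                           fit_options(n_starts = 2), seed = 1)
  cmp <- compare_models(fits, fits)
  expect_equal(cmp$total_delta_aic, 0)
  expect_equal(cmp$fraction_favoring_b, 0.5)
  expect_equal(cmp$sign_test_p, 1)
  expect_error(compare_models(fits, fits[1:2, ]), "do not match")
})
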