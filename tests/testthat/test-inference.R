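make_training_cohort <- function(temp_C, seed, proto = observation_protocol()) {
  simulate_cohort(population_params(), proto, temp_C = temp_C,
                  law = default_temperature_law(), seed = seed)
}

test_that("the likelihood prefers the generating parameters", {
  law <- default_temperature_law()
  truth <- params_at_temperature(25, law)
  tab <- make_training_cohort(25, seed = 11)
  pp <- population_params()
  nll_true <- negloglik_timecourse(tab, truth$params$k_max, truth$params$k_d,
                                   0, pp)
  nll_pert <- negloglik_timecourse(tab, 2 * truth$params$k_max,
                                   truth$params$k_d, 0, pp)
  expect_lt(nll_true, nll_pert)
  expect_error(negloglik_timecourse(tab[0, ], 7, 0.01, 0, pp), "empty")
  # zero-heterogeneity candidate with data off the deterministic curve:
  # the variance floor keeps the likelihood finite but heavily penalized
  pp0 <- population_params(sigma_S = 0, sigma_t0 = 0, sigma_kmax = 0)
  nll0 <- negloglik_timecourse(tab, truth$params$k_max, truth$params$k_d,
                               0, pp0)
  expect_true(is.finite(nll0))
  expect_gt(nll0, nll_true)
  # invalid candidates take the penalty path
  expect_equal(negloglik_timecourse(tab, -1, 0.01, 0, pp), 1e10)
})

test_that("parameters are recovered in the deterministic limit", {
  # vanishing heterogeneity: counts lie on the model curve up to rounding
  pp0 <- population_params(sigma_S = 0, sigma_t0 = 0, sigma_kmax = 0)
  p <- kinetic_params(k_max = 9, k_hat = 100, k_d = 0.02)
  pp0$mu_kmax <- 9
  tab <- simulate_cohort(pp0, observation_protocol(n_per_dense = 4),
                         temp_C = 25, params = p, seed = 21)
  fit <- fit_mle(tab, 25, pp0, n_starts = 2, seed = 5)
  expect_lt(abs(fit$estimates$mu_kmax / 9 - 1), 0.01)
  expect_lt(abs(fit$estimates$k_d / 0.02 - 1), 0.01)
})

test_that("stochastic cohorts at the study scale recover the kinetics", {
  law <- default_temperature_law()
  truth <- params_at_temperature(25, law)
  tab <- make_training_cohort(25, seed = 31)
  ppf <- population_params()
  sp <- infer_sperm_from_brood(suppressWarnings(
    brood_sizes(make_training_cohort(20, seed = 30))))
  ppf$mu_S <- sp$mu_S
  ppf$sigma_S <- sp$sigma_S
  fit <- fit_mle(tab, 25, ppf, n_starts = 3, seed = 5)
  expect_lt(abs(fit$estimates$mu_kmax / truth$params$k_max - 1), 0.15)
  expect_lt(abs(fit$estimates$k_d / truth$params$k_d - 1), 0.15)
  expect_true(all(fit$convergence == 0))
})

test_that("temperature-law fitting recovers exact exponentials", {
  mk_fit <- function(temp, kmax, kd, delta = NA_real_) {
    structure(list(estimates = list(mu_kmax = kmax, k_d = kd, delta = delta),
                   temp_C = temp, k_hat = 100,
                   bounds = list(mu_kmax = c(0.5, 100), k_d = c(1e-6, 10),
                                 delta = c(1e-4, 0.999))),
              class = "worm_fit")
  }
  f <- function(temp) exp(-2 + 0.1 * temp)
  fits <- lapply(c(20, 25, 29), function(tc)
    mk_fit(tc, kmax = f(tc), kd = f(tc) / 100, delta = f(tc) / 10))
  law <- fit_temperature_law(fits)
  expect_equal(unname(law$k_max), c(-2, 0.1), tolerance = 1e-10)
  expect_equal(unname(law$k_d), c(-2 - log(100), 0.1), tolerance = 1e-10)
  # constant parameters give zero slope
  fits_flat <- lapply(c(20, 25, 29), function(tc) mk_fit(tc, 5, 0.05, 0.2))
  law_flat <- fit_temperature_law(fits_flat)
  expect_equal(unname(law_flat$k_max["b"]), 0, tolerance = 1e-10)
  # delta fixed at zero at permissive temperatures is excluded with a
  # warning; the delta law is anchored on the remaining points
  fits_mix <- list(mk_fit(20, 7.5, 1e-4, 0),
                   mk_fit(28, 10.5, 0.5, 0.25),
                   mk_fit(29, 11, 1.4, 0.6))
  expect_warning(law_mix <- fit_temperature_law(fits_mix), "delta")
  expect_equal(unname(law_mix$delta["b"]), log(0.6 / 0.25), tolerance = 1e-8)
  # fewer than two positive delta points: law degrades to zero
  w <- capture_warnings(law_deg <- fit_temperature_law(fits_mix[c(1, 3)]))
  expect_true(any(grepl("law set to zero", w)))
  expect_equal(params_at_temperature(29, law_deg)$delta, 0)
  # at-bound estimates are treated as uninformative
  fits_bound <- list(mk_fit(20, 7.5, 1.01e-6, NA),
                     mk_fit(25, 9.3, 0.02, NA),
                     mk_fit(29, 11, 1.4, NA))
  w <- capture_warnings(law_b <- fit_temperature_law(fits_bound))
  expect_true(any(grepl("k_d", w)))
  expect_equal(unname(law_b$k_d["b"]), log(1.4 / 0.02) / 4, tolerance = 1e-8)
})

test_that("estimation bias shrinks as cohorts grow", {
  # one-dimensional capacity fits (death rate held at truth) on small
  # vs large cohorts
  p25 <- params_at_temperature(25, default_temperature_law())$params
  pp <- population_params()
  pp$delta <- 0
  err <- function(n_long, seeds) {
    mean(vapply(seeds, function(s) {
      tab <- simulate_cohort(pp, brood_proto(n_long), temp_C = 25,
                             params = p25, seed = s)
      est <- optimize(function(km)
        negloglik_timecourse(tab, km, p25$k_d, 0, pp), c(2, 30))$minimum
      abs(est / p25$k_max - 1)
    }, numeric(1)))
  }
  expect_lt(err(120, 41:44), err(8, 41:44))
})

test_that("sperm caches are inferred from permissive-temperature broods", {
  expect_equal(infer_sperm_from_brood(rep(300, 5)),
               list(mu_S = 300, sigma_S = 0))
  expect_equal(infer_sperm_from_brood(mean = 437, sd = 40),
               list(mu_S = 437, sigma_S = 40))   # tra-3 summary
  expect_equal(infer_sperm_from_brood(mean = 238, sd = 115),
               list(mu_S = 238, sigma_S = 115))  # cdc-48.1 summary
  b <- c(250, 300, 350)
  expect_equal(infer_sperm_from_brood(b), list(mu_S = 300, sigma_S = sd(b)))
  expect_error(infer_sperm_from_brood(300), ">= 2")
})

test_that("cohort predictions are self-consistent and respond to the law", {
  law <- default_temperature_law()
  pp <- population_params()
  proto <- observation_protocol()
  # at a training temperature the prediction matches a direct simulation
  pred <- predict_cohort(law, pp, temp_C = 25, proto = proto, n_rep = 300,
                         seed = 51)
  tab <- simulate_cohort(pp, brood_proto(100), temp_C = 25, law = law,
                         seed = 52)
  b <- suppressWarnings(brood_sizes(tab))
  expect_lt(abs(mean(attr(pred, "broods")) / mean(b) - 1), 0.1)
  # uncertainty bands widen with capacity heterogeneity
  wide <- population_params(sigma_kmax = 2)
  pred_w <- predict_cohort(law, wide, temp_C = 25, proto = proto,
                           n_rep = 300, seed = 51)
  mid <- which(pred$time_h == 36)
  expect_gt(pred_w$sd[mid], pred$sd[mid])
  # at 30 C the non-robust fraction saturates and reproduction collapses
  pred30 <- predict_cohort(law, pp, temp_C = 30, proto = proto, n_rep = 200,
                           seed = 53)
  expect_equal(attr(pred30, "delta"), 1)
  expect_lt(mean(attr(pred30, "broods")), 10)
})
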