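test_that("elementary rates follow mass action and gonad saturation", {
  p <- ref_params()
  # direct evaluations
  expect_equal(generation_rate(50, p), 5.0)
  expect_equal(ovulation_rate(20, 300, p), 6.0)
  expect_equal(sperm_death_rate(300, p), 3.0)
  # structural limits
  expect_equal(generation_rate(p$k_g / p$k_s, p), 0) # carrying capacity
  expect_equal(generation_rate(0, p), p$k_g)
  expect_equal(ovulation_rate(20, 0, p), 0)          # no sperm, no ovulation
  expect_equal(ovulation_rate(0, 300, p), 0)
  expect_equal(sperm_death_rate(0, p), 0)
  p0 <- kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001, k_d = 0)
  expect_equal(sperm_death_rate(500, p0), 0)
  # domain errors
  expect_error(generation_rate(-1, p), "O must be")
  expect_error(ovulation_rate(2, -1, p), "S_a must be")
  expect_error(sperm_death_rate(-1, p), "S_a must be")
  expect_error(kinetic_params(k_g = -1, k_s = 0.1, k_o = 0.001), ">= 0")
})

test_that("QSS oocyte pool and egg rate are consistent closed forms", {
  p <- ref_params()
  expect_equal(qss_oocyte_count(300, p), 25.0)
  expect_equal(qss_egg_rate(300, p), 7.5)
  expect_equal(qss_oocyte_count(0, p), p$k_g / p$k_s) # carrying capacity
  expect_equal(qss_egg_rate(p$k_hat, p), p$k_max / 2) # half-saturation
  expect_lt(abs(qss_egg_rate(1e9, p) - p$k_max), 1e-5) # saturation limit
  # the oocyte pool is the root of generation - ovulation
  expect_equal(generation_rate(qss_oocyte_count(300, p), p),
               ovulation_rate(qss_oocyte_count(300, p), 300, p))
  # the two algebraic code paths agree to machine precision
  for (q in random_params(10)) {
    S <- runif(1, 0, 1000)
    expect_equal(qss_egg_rate(S, q),
                 ovulation_rate(qss_oocyte_count(S, q), S, q),
                 tolerance = 1e-12)
  }
  pdeg <- kinetic_params(k_g = 10, k_s = 0, k_o = 0.001)
  expect_error(qss_oocyte_count(0, pdeg), "degenerate")
})

test_that("trajectories conserve gametes and are monotone", {
  for (q in random_params(6, seed = 7)) {
    S0 <- round(runif(1, 50, 500))
    trf <- integrate_full(q, S0, horizon = 300)
    trq <- integrate_qss(q, S0, horizon = 300)
    for (tr in list(trf, trq)) {
      expect_lt(max(abs(tr$E + tr$S_a + tr$S_d - S0)), 1e-6 * S0)
      expect_true(all(diff(tr$E) > -1e-8))
      expect_true(all(diff(tr$S_a) < 1e-8))
    }
  }
  # no sperm, no eggs
  expect_true(all(integrate_full(ref_params(), 0, horizon = 50)$E == 0))
  expect_true(all(integrate_qss(ref_params(), 0, horizon = 50)$E == 0))
})

test_that("terminal brood is bounded by the sperm cache", {
  p0 <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0)
  tr <- integrate_qss(p0, 300, to_cessation = TRUE)
  expect_equal(round(tail(tr$E, 1)), 300)  # all sperm eventually used
  expect_true(all(tr$E <= 300 + 1e-6))
  expect_equal(brood_total(p0, 300), 300)
  for (kd in c(0.005, 0.05, 0.5)) {
    p <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = kd)
    bt <- brood_total(p, 300)
    expect_lt(bt, 300)
    num <- tail(integrate_qss(p, 300, to_cessation = TRUE)$E, 1)
    expect_equal(num, bt, tolerance = 1e-5)
  }
})

test_that("QSS model converges to the full model as oocyte dynamics speed up", {
  # same (k_max, k_hat, k_d), increasing oocyte relaxation rate k_s
  gaps <- vapply(c(0.5, 5, 50), function(ks) {
    p <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0.01,
                        oocyte_relax = ks)
    grid <- seq(0, 150, length.out = 151)
    max(abs(integrate_full(p, 300, grid = grid)$E -
              integrate_qss(p, 300, grid = grid)$E)) / 300
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})

test_that("oocyte-death model is equivalent to the remapped parsimonious model", {
  p <- ref_params()
  expect_identical(unclass(with_oocyte_death(p))[1:5], unclass(p)[1:5])
  pd <- kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001, k_d = 0.01,
                       k_do = 0.05)
  pr <- with_oocyte_death(pd)
  expect_gt(pr$k_hat, pd$k_hat)  # death inflates the half-saturation constant
  grid <- seq(0, 200, length.out = 101)
  td <- integrate_full(pd, 300, grid = grid)
  tp <- integrate_full(pr, 300, grid = grid)
  expect_lt(max(abs(td$E - tp$E)), 1e-6)
  expect_lt(max(abs(td$S_a - tp$S_a)), 1e-6)
  # dead oocytes accumulate only in the death-inclusive model
  expect_true(all(diff(td$O_d) > 0))
})

test_that("mean-field closed form matches numerical integration", {
  ts <- c(0, 6, 24, 48, 96)
  for (kmax in c(5, 10)) for (khat in c(50, 150)) for (kd in c(0, 0.01, 0.5)) {
    p <- kinetic_params(k_max = kmax, k_hat = khat, k_d = kd)
    mf <- mean_field_solution(p, 300, ts)
    nm <- integrate_qss(p, 300, grid = ts)
    expect_equal(mf$S_a[1], 300)
    expect_equal(mf$E[1], 0)
    expect_lt(max(abs(mf$E - nm$E) / pmax(abs(mf$E), 1)), 1e-5)
    expect_lt(max(abs(mf$S_a - nm$S_a) / pmax(abs(mf$S_a), 1)), 1e-5)
  }
})

test_that("temperature laws evaluate exponentially and clip delta", {
  law <- temperature_law(k_max = c(-2, 0.1), k_d = c(-2, 0.1),
                         delta = c(-2, 0.1), k_hat = 100)
  at <- params_at_temperature(25, law)
  expect_equal(at$params$k_max, exp(0.5), tolerance = 1e-12)
  expect_false(at$extrapolated)
  # monotone in T for b > 0; constant for b = 0
  expect_gt(params_at_temperature(30, law)$params$k_max,
            params_at_temperature(20, law)$params$k_max)
  flat <- temperature_law(k_max = c(1, 0), k_d = c(-5, 0), delta = c(-9, 0))
  expect_equal(params_at_temperature(20, flat)$params$k_max,
               params_at_temperature(30, flat)$params$k_max)
  # delta clipped into [0, 1]
  steep <- temperature_law(k_max = c(1, 0), k_d = c(-5, 0), delta = c(0, 0.5))
  expect_equal(params_at_temperature(25, steep)$delta, 1)
  expect_warning(params_at_temperature(35, law), "extrapolating")
})
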