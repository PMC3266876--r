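test_that("individual draws honour the heterogeneity model", {
  # degenerate population: deterministic individual
  pp0 <- population_params(sigma_S = 0, sigma_t0 = 0, sigma_kmax = 0,
                           delta = 0)
  set.seed(1)
  ind <- draw_individual(pp0, 5)
  expect_true(all(ind$S0 == 300))
  expect_true(all(ind$t0 == 4))
  expect_true(all(ind$k_max_i == 7.5))
  expect_true(all(ind$robust))
  # delta = 1: every animal non-robust
  pp1 <- population_params(delta = 1)
  set.seed(2)
  expect_true(all(!draw_individual(pp1, 50)$robust))
  # shared latent draw couples sperm cache and onset delay
  pp <- population_params()
  set.seed(3)
  big <- draw_individual(pp, 1e4)
  expect_lt(abs(mean(big$S0) - 300), 3 * 45 / sqrt(1e4))
  expect_gt(cor(big$S0, big$t0), 0.99)
})

test_that("individual egg counts start at onset and conserve the cache", {
  p <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0)
  ind <- list(S0 = 300, t0 = 6, k_max_i = 7.5)
  counts <- simulate_individual(ind, p, times = c(2, 4, 6, 8, 200, 400))
  expect_true(all(counts[1:3] == 0))        # nothing before onset
  expect_gt(counts[4], 0)
  expect_equal(counts[6], 300L)             # k_d = 0: count reaches S0
  # monotone non-decreasing counts over random individuals
  set.seed(11)
  pp <- population_params(delta = 0.3)
  inds <- draw_individual(pp, 8)
  pk <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0.05)
  for (i in seq_len(8)) {
    ci <- simulate_individual(inds[i, ], pk, times = seq(0, 120, by = 4))
    expect_true(all(diff(ci) >= 0))
  }
})

test_that("cohorts are reproducible and respect per-animal conservation", {
  pp <- population_params()
  proto <- observation_protocol(n_per_dense = 4, n_longitudinal = 12)
  law <- default_temperature_law()
  tab1 <- simulate_cohort(pp, proto, temp_C = 25, law = law, seed = 9)
  tab2 <- simulate_cohort(pp, proto, temp_C = 25, law = law, seed = 9)
  expect_identical(as.data.frame(tab1), as.data.frame(tab2))
  expect_false(identical(
    as.data.frame(tab1),
    as.data.frame(simulate_cohort(pp, proto, temp_C = 25, law = law,
                                  seed = 10))))
  validate_egg_table(tab1)
  # each dense time point uses fresh animals: one record per animal
  cs <- tab1[tab1$mode == "cross_sectional", ]
  expect_true(all(table(cs$individual_id) == 1))
  expect_equal(nrow(cs), 4 * length(proto$dense_times))
  # no brood exceeds its animal's sperm cache
  inds <- attr(tab1, "individuals")
  broods <- suppressWarnings(brood_sizes(tab1))
  caches <- inds$S0[match(as.integer(sub(".*_", "", names(broods))), inds$id)]
  expect_true(all(broods <= caches))
})

test_that("total broods are extracted only from ceased longitudinal records", {
  tab <- data.frame(
    individual_id = c("a", "a", "a", "b", "b", "c"),
    strain = "N2", temp_C = 20,
    time_h = c(12, 24, 36, 12, 24, 12),
    eggs_cum = c(100, 300, 300, 100, 200, 50),
    mode = "longitudinal")
  expect_warning(b <- brood_sizes(tab), "without cessation")
  expect_equal(b, c(a = 300))
  expect_error(brood_sizes(tab[0, ]), "empty")
})

test_that("permissive-temperature broods are normally distributed", {
  pp <- population_params()
  law <- default_temperature_law()
  passes <- 0
  for (i in 1:100) {
    b <- suppressWarnings(
      brood_sizes(simulate_cohort(pp, brood_proto(30), temp_C = 20,
                                  law = law, seed = 1000 + i)))
    if (ks_normality_test(b, n_boot = 99, seed = i)$p_value > 0.01)
      passes <- passes + 1
  }
  expect_gte(passes, 95)
})

test_that("stressed cohorts with a non-robust class reject a single normal", {
  pp <- population_params(delta = 0.5)
  p29 <- params_at_temperature(29, default_temperature_law())$params
  rejects <- 0
  for (i in 1:10) {
    b <- suppressWarnings(
      brood_sizes(simulate_cohort(pp, brood_proto(40), temp_C = 29,
                                  params = p29, seed = 2000 + i)))
    if (ks_normality_test(b, n_boot = 99, seed = i)$p_value < 0.05)
      rejects <- rejects + 1
  }
  expect_gte(rejects, 7)  # clear majority
})

test_that("brood CoV is stable when only the capacity changes", {
  # two temperatures differing only in k_max (k_d = 0, delta = 0):
  # broods equal the sperm caches, so the CoV is preserved
  pp <- population_params()
  cvs <- vapply(c(7.5, 11), function(km) {
    p <- kinetic_params(k_max = km, k_hat = 100, k_d = 0)
    b <- suppressWarnings(
      brood_sizes(simulate_cohort(pp, brood_proto(200), temp_C = 20,
                                  params = p, seed = round(100 * km))))
    coef_variation(b)
  }, numeric(1))
  expect_lt(abs(cvs[1] - cvs[2]), 0.05)
  expect_lt(abs(cvs[1] - 45 / 300), 0.05)
})
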