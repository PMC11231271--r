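test_that("monthly panel aggregates match hand-computed values", {
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-01-31"), by = "day")
  n <- length(dates)
  split <- tibble::tibble(date = dates, bc_transport = seq(1, 2, length.out = n))
  met <- tibble::tibble(date = dates, U10 = 1, V10 = 2, D2M = 280, T2M = 285,
                        BLH = 500, MBLD = 300, SP = 101000, TP = 0.001)
  epidemic <- tibble::tibble(
    date = dates, cases = c(rep(0, 20), rep(3, 11)),
    transmission = c(rep(0, 20), rep(1, 11)),
    fatality = c(rep(0, 20), rep(3, 11)),
    period = c(rep("workday", 21), rep("legal-vacation", 10)))
  vols <- tibble::tibble(month = as.Date("2020-01-01"),
                         bus_volume = 40, metro_volume = 30)
  panel <- build_monthly_panel(split, vols, met, epidemic)
  expect_equal(nrow(panel), 1)
  expect_equal(panel$bc_private, mean(split$bc_transport))
  expect_equal(panel$TP, 31 * 0.001)
  expect_equal(panel$T2M, 285)
  expect_equal(panel$cases, 33)
  expect_equal(panel$transmission, 1)
  expect_equal(panel$fatality, 3)
  expect_equal(panel$period_share, 10 / 31)
  expect_equal(panel$metro_volume, 30)

  expect_error(build_monthly_panel(split, vols[0, ], met, epidemic),
               class = "carbonsplit_alignment_error")
})

test_that("a six-year scenario yields 72 panel months with quiet outbreak months", {
  chain <- default_chain(1)
  panel <- chain$panel
  expect_equal(nrow(panel), 72)
  quiet <- panel[panel$month == as.Date("2019-06-01"), ]
  expect_equal(quiet$transmission, 0)
  expect_equal(quiet$fatality, 0)
  expect_equal(quiet$cases, 0)
})

test_that("response forest sanity: leakage, permutation, determinism", {
  chain <- default_chain(1)
  panel <- chain$panel
  # leak harness: a perfect copy of a smooth target must be learned almost
  # exactly once regularization is lifted
  leak <- panel
  leak$leak <- leak$T2M
  m_leak <- fit_response_model(leak, "T2M", seed = 1, features = "leak",
                               mtry = 1, max_depth = 0,
                               splitrule = "variance", min_node_size = 2)
  expect_gte(m_leak$oob_r2, 0.99)

  set.seed(5)
  perm <- panel
  perm$bc_private <- sample(perm$bc_private)
  m_perm <- fit_response_model(perm, "bc_private", seed = 1)
  expect_lte(m_perm$oob_r2, 0.1)

  m1 <- fit_response_model(panel, "metro_volume", seed = 9)
  m2 <- fit_response_model(panel, "metro_volume", seed = 9)
  expect_identical(m1$oob_r2, m2$oob_r2)

  expect_error(fit_response_model(panel[1:20, ], "bc_private"),
               class = "carbonsplit_insufficient_data_error")
  expect_error(fit_response_model(panel, "nope"),
               class = "carbonsplit_feature_error")
})

test_that("partial dependence is exact on stub surfaces", {
  chain <- default_chain(1)
  panel <- chain$panel
  stub_const <- carbonsplit:::new_response_stub(
    function(nd) rep(2.5, nrow(nd)), panel)
  pd_flat <- partial_dependence(stub_const, "cases", n_grid = 15)
  expect_equal(max(pd_flat$pd) - min(pd_flat$pd), 0)

  stub_id <- carbonsplit:::new_response_stub(
    function(nd) nd$cases, panel)
  pd_id <- partial_dependence(stub_id, "cases", n_grid = 15)
  expect_equal(pd_id$pd, pd_id$value)

  expect_error(partial_dependence(stub_id, "unknown_feature"),
               class = "carbonsplit_feature_error")
})

test_that("partial dependence averages to the mean prediction on additive surfaces", {
  chain <- default_chain(1)
  panel <- chain$panel
  stub_add <- carbonsplit:::new_response_stub(
    function(nd) 0.3 * nd$cases + 2 * nd$transmission + 0.1 * nd$T2M, panel)
  # grid at every observed value, weighted by its empirical frequency
  obs <- panel$cases
  pd_vals <- vapply(obs, function(v) {
    nd <- as.data.frame(panel[, stub_add$features])
    nd$cases <- v
    mean(stub_add$predict_fn(nd))
  }, numeric(1))
  mean_pred <- mean(stub_add$predict_fn(as.data.frame(panel[, stub_add$features])))
  expect_lt(abs(mean(pd_vals) - mean_pred), 1e-6)
})

test_that("a generator-unused noise feature has flat partial dependence", {
  chain <- default_chain(1)
  panel <- chain$panel
  set.seed(77)
  # orthogonalize against the target: with 72 rows a raw draw can carry a
  # chance correlation of ~0.2, which is association, not estimator noise
  z <- rnorm(nrow(panel))
  panel$noise <- residuals(lm(z ~ panel$metro_volume))
  m <- fit_response_model(panel, "metro_volume", seed = 1,
                          features = c(RESPONSE_FEATURES, "noise"))
  pd <- partial_dependence(m, "noise", n_grid = 20)
  expect_lte(max(pd$pd) - min(pd$pd), 0.05 * sd(panel$metro_volume))
})

test_that("permutation test attains the smallest p on a determining feature", {
  chain <- default_chain(1)
  panel <- chain$panel
  panel$driver <- panel$bc_private
  m <- fit_response_model(panel, "bc_private", seed = 2, num_trees = 200,
                          features = c("driver", "T2M", "TP"))
  tst <- feature_effect_test(m, "driver", n_permutations = 99, seed = 1)
  expect_equal(tst$p_value, 1 / 100)
  expect_equal(length(tst$null), 99)
  expect_error(feature_effect_test(m, "driver", n_permutations = 50),
               class = "carbonsplit_config_error")
})
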