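base_config <- function() {
  calibrate_drug_price(make_cost_config("high"), target_delta_cost = 112744.35)
}

test_that("one-way analysis collapses to zero spread at zero range and is monotone in price", {
  config <- base_config()
  model <- cea_model(config)
  frozen <- param_spec("utilities.u_pd",
    base = 0.321, low = 0.321, high = 0.321, dist = "beta"
  )
  tor <- one_way(model, list(frozen))
  expect_equal(tor$spread, 0)
  price <- config$arms$atezolizumab$drug_cost_per_cycle
  tor2 <- one_way(model, list(
    param_spec("arms.atezolizumab.drug_cost_per_cycle", base = price, dist = "gamma")
  ))
  expect_lt(tor2$icer_at_low, tor2$icer_base)
  expect_gt(tor2$icer_at_high, tor2$icer_base)
  # strictly increasing along a finer price grid
  icers <- vapply(
    price * c(0.5, 0.75, 1, 1.25, 1.5),
    function(p) model(list(arms.atezolizumab.drug_cost_per_cycle = p))$icer,
    numeric(1)
  )
  expect_true(all(diff(icers) > 0))
})

test_that("the dominant tornado parameters are the drug price and the utilities", {
  config <- base_config()
  tor <- one_way(cea_model(config), attr(config, "psa_params"))
  expect_setequal(
    tor$parameter[1:3],
    c(
      "arms.atezolizumab.drug_cost_per_cycle",
      "utilities.u_pd", "utilities.u_pfs"
    )
  )
})

test_that("parameter sampling reproduces the specified moments", {
  u <- local({
    set.seed(123)
    runif(1e5)
  })
  gamma_draws <- markovcea:::draw_param(
    param_spec("x", base = 4754, dist = "gamma"), u
  )
  expect_equal(mean(gamma_draws), 4754, tolerance = 0.01)
  beta_draws <- markovcea:::draw_param(
    param_spec("y", base = 0.321, dist = "beta"), u
  )
  expect_true(all(beta_draws > 0 & beta_draws < 1))
  se <- sd(beta_draws) / sqrt(length(beta_draws))
  expect_lt(abs(mean(beta_draws) - 0.321), 3 * se + 1e-3)
  ln_draws <- markovcea:::draw_param(
    param_spec("z", base = 2, dist = "lognormal"), u
  )
  expect_equal(mean(ln_draws), 2, tolerance = 0.01)
})

test_that("the Monte Carlo analysis is reproducible and collapses when degenerate", {
  config <- base_config()
  model <- cea_model(config)
  params <- attr(config, "psa_params")
  s1 <- psa(model, params, n_iter = 60, seed = 14)
  s2 <- psa(model, params, n_iter = 60, seed = 14)
  expect_identical(s1, s2)
  # zero-variance limit: every sample equals the base-case increments
  degenerate <- lapply(params, function(p) {
    param_spec(p$name, base = p$base, low = p$base, high = p$base, dist = "fixed")
  })
  s3 <- psa(model, degenerate, n_iter = 10, seed = 1)
  base <- model()
  expect_equal(s3$delta_cost, rep(base$delta_cost, 10), tolerance = 1e-12)
  expect_equal(s3$delta_qaly, rep(base$delta_qaly, 10), tolerance = 1e-12)
})

test_that("the acceptability curve implements the net-monetary-benefit rule", {
  # synthetic sample cloud with known geometry
  set.seed(99)
  samples <- structure(
    tibble::tibble(
      iteration = 1:1000,
      delta_cost = rnorm(1000, 112744, 8000),
      delta_qaly = rnorm(1000, 0.91, 0.05),
      icer = NA_real_
    ),
    class = c("psa_samples", class(tibble::tibble()))
  )
  curve <- ceac(samples, wtp = c(0, 50000, 124000, 500000, 1e7))
  expect_equal(curve$probability[1], mean(samples$delta_cost < 0))
  expect_equal(curve$probability[nrow(curve)], mean(samples$delta_qaly > 0))
  # 50% crossing sits near delta_cost / delta_qaly
  mid <- curve$probability[curve$wtp == 124000]
  expect_gt(mid, 0.35)
  expect_lt(mid, 0.65)
  expect_true(all(diff(curve$probability) >= 0)) # all delta_qaly draws > 0 here
})

test_that("price reductions monotonically raise the probability of cost-effectiveness", {
  config <- base_config()
  params <- attr(config, "psa_params")
  scan <- price_scan(config, params,
    reductions = c(0, 0.4, 0.75, 0.95),
    n_iter = 150, seed = 8
  )
  expect_true(all(diff(scan$probability) >= 0))
  # identity at zero reduction: same seed, same samples as a plain run
  baseline <- ceac(
    psa(cea_model(config), params, n_iter = 150, seed = 8),
    wtp = config$wtp
  )
  expect_equal(scan$probability[1], baseline$probability)
  # deep price cuts push the treatment below the threshold somewhere
  expect_gt(scan$probability[length(scan$probability)], 0.5)
})
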