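test_that("the generator is deterministic under a fixed seed", {
  spec <- exp_trial_spec(n = 80)
  t1 <- simulate_trial(spec, seed = 3)
  t2 <- simulate_trial(spec, seed = 3)
  expect_identical(t1$a$ipd, t2$a$ipd)
  expect_identical(t1$a$digitization$pfs$coords, t2$a$digitization$pfs$coords)
  expect_error(simulate_trial(spec), "seed")
})

test_that("generated OS dominates PFS pointwise", {
  trial <- simulate_trial(exp_trial_spec(n = 300, censor = 36), seed = 21)
  expect_true(all(trial$a$true_times$os >= trial$a$true_times$pfs))
  pfs_dig <- trial$a$digitization$pfs
  os_dig <- trial$a$digitization$os
  shared <- intersect(pfs_dig$coords$time, os_dig$coords$time)
  s_pfs <- pfs_dig$coords$survival[match(shared, pfs_dig$coords$time)]
  s_os <- os_dig$coords$survival[match(shared, os_dig$coords$time)]
  expect_true(all(s_os >= s_pfs - 1e-12))
})

test_that("degenerate censoring propagates the right error downstream", {
  trial <- simulate_trial(exp_trial_spec(n = 50, censor = 0), seed = 1)
  expect_true(all(trial$a$ipd$pfs$event == 0))
  expect_error(fit_parametric(trial$a$ipd$pfs, "exponential"), "no events")
  expect_null(trial$a$digitization$pfs) # nothing to digitize
})

test_that("the full pipeline recovers generating rates end to end", {
  # arm size mirroring an IMpower110-like arm
  spec <- trial_spec(
    arms = list(a = list(
      pfs = surv_dist("exponential", rate = 0.12),
      post_progression = surv_dist("exponential", rate = 0.10), n = 286
    )),
    admin_censor_time = 30
  )
  trial <- simulate_trial(spec, seed = 17)
  ipd <- reconstruct_ipd(trial$a$digitization$pfs)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(unname(fit$dist$params["rate"]), 0.12, tolerance = 0.15)
})

test_that("model life-years match the generating OS distribution", {
  # PFS ~ Exp(r), post-progression ~ Exp(r)  =>  OS ~ Gamma(2, r), a family
  # the fitter can recover exactly; r = 0.15/month puts median OS around
  # 11 months, typical of chemotherapy-treated metastatic NSCLC, and leaves
  # almost no survival beyond the 60-month follow-up to extrapolate
  r <- 0.15
  spec <- trial_spec(
    arms = list(a = list(
      pfs = surv_dist("exponential", rate = r),
      post_progression = surv_dist("exponential", rate = r), n = 1000
    )),
    admin_censor_time = 60, digitization_step = 0.1
  )
  trial <- simulate_trial(spec, seed = 1)
  pfs_fit <- select_best(fit_families(reconstruct_ipd(trial$a$digitization$pfs)))
  os_fit <- select_best(fit_families(reconstruct_ipd(trial$a$digitization$os)))
  settings <- model_settings(half_cycle_correction = TRUE)
  tr <- markov_trace(pfs_fit$best$dist, os_fit$best$dist, settings)
  horizon <- settings$cycle_length * settings$n_cycles
  truth <- surv_rmst(surv_dist("gamma", shape = 2, rate = r), horizon) / 12
  expect_equal(trace_life_years(tr), truth, tolerance = 0.05 / truth)
})

test_that("synthetic cost configs are flagged, tunable and serializable", {
  config <- make_cost_config("high")
  expect_true(config$synthetic)
  expect_s3_class(config, "cea_config")
  # the calibration fixed point: incremental cost within $1 of the target
  cal <- calibrate_drug_price(config, target_delta_cost = 112744.35)
  expect_lt(abs(run_cea(cal)$icer$delta_cost - 112744.35), 1)
  # turning the assistance program on strictly cuts the treatment arm cost
  pap_cfg <- make_cost_config("high", with_pap = TRUE)
  expect_lt(
    run_cea(pap_cfg)$treatment$total_cost,
    run_cea(config)$treatment$total_cost
  )
  # JSON round-trip preserves every value the model consumes
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_cea_config(cal, path)
  back <- read_cea_config(path)
  expect_identical(
    cea_model(cal)(),
    cea_model(back)()
  )
  expect_identical(
    back$arms$atezolizumab$drug_cost_per_cycle,
    cal$arms$atezolizumab$drug_cost_per_cycle
  )
})
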