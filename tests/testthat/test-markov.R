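test_that("identical PFS and OS curves leave the progressed state empty", {
  os <- surv_dist("log_logistic", shape = 1.407, scale = 11.610)
  tr <- markov_trace(os, os, model_settings(background_mortality = 0))
  expect_equal(max(tr$n_pd), 0)
  expect_equal(tr$n_pfs, surv_prob(os, tr$t), tolerance = 1e-12)
})

test_that("exponential curves give time-homogeneous stay probabilities", {
  s <- model_settings(cycle_length = 1, n_cycles = 60, background_mortality = 0)
  sch <- transition_schedule(
    surv_dist("exponential", rate = 0.12),
    surv_dist("exponential", rate = 0.05), s
  )
  expect_equal(sch$p_pfs_pfs, rep(exp(-0.12), 60), tolerance = 1e-12)
  # PD retention settles to the OS conditional survival once PD is populated
  expect_equal(
    sch$p_pd_pd[10:60] + sch$p_pd_death[10:60],
    rep(1, 51),
    tolerance = 1e-12
  )
})

test_that("occupancy tracks the survival curves for the published parameters", {
  for (pop in c("high", "high_or_intermediate", "any")) {
    for (arm in c("atezolizumab", "chemotherapy")) {
      pfs <- impower110_curve(pop, arm, "pfs")
      os <- impower110_curve(pop, arm, "os")
      tr <- markov_trace(pfs, os, model_settings())
      expect_lt(max(abs(tr$n_pfs - surv_prob(pfs, tr$t))), 1e-6)
      expect_lt(max(abs(tr$n_pfs + tr$n_pd - surv_prob(os, tr$t))), 1e-6)
    }
  }
})

test_that("the trace conserves the cohort and death is absorbing", {
  tr <- markov_trace(
    impower110_curve("high", "atezolizumab", "pfs"),
    impower110_curve("high", "atezolizumab", "os"),
    model_settings()
  )
  expect_lt(max(abs(tr$n_pfs + tr$n_pd + tr$n_death - 1)), 1e-9)
  expect_true(all(diff(tr$n_death) >= -1e-12))
  expect_true(all(tr$n_pfs >= 0 & tr$n_pd >= 0 & tr$n_death >= 0))
  expect_equal(sum(tr$incident_deaths), tr$n_death[nrow(tr)], tolerance = 1e-9)
})

test_that("life-years are invariant to background mortality", {
  pfs <- impower110_curve("high", "chemotherapy", "pfs")
  os <- impower110_curve("high", "chemotherapy", "os")
  lys <- vapply(c(0, 0.01, 0.05), function(bg) {
    trace_life_years(markov_trace(pfs, os, model_settings(background_mortality = bg)))
  }, numeric(1))
  expect_equal(lys[1], lys[2], tolerance = 1e-9)
  expect_equal(lys[1], lys[3], tolerance = 1e-9)
})

test_that("halving the cycle length barely moves 10-year life-years", {
  pfs <- impower110_curve("high", "atezolizumab", "pfs")
  os <- impower110_curve("high", "atezolizumab", "os")
  ly1 <- trace_life_years(markov_trace(pfs, os, model_settings()))
  ly2 <- trace_life_years(markov_trace(
    pfs, os, model_settings(cycle_length = 0.375, n_cycles = 348)
  ))
  expect_lt(abs(ly1 - ly2), 0.02)
})

test_that("a PFS curve above the OS curve is clamped with a warning", {
  pfs <- surv_dist("exponential", rate = 0.05) # slower than OS: crossing
  os <- surv_dist("exponential", rate = 0.10)
  expect_warning(
    tr <- markov_trace(pfs, os, model_settings(background_mortality = 0)),
    "clamped"
  )
  expect_equal(max(tr$n_pd), 0)
  expect_lt(max(abs(tr$n_pfs + tr$n_pd + tr$n_death - 1)), 1e-9)
})

test_that("running the trace from the schedule reproduces the engine", {
  pfs <- impower110_curve("any", "atezolizumab", "pfs")
  os <- impower110_curve("any", "atezolizumab", "os")
  s <- model_settings()
  sch <- transition_schedule(pfs, os, s)
  expect_true(all(abs(rowSums(sch[, c("p_pfs_pfs", "p_pfs_pd", "p_pfs_death")]) - 1) < 1e-12))
  expect_true(all(abs(sch$p_pd_pd + sch$p_pd_death - 1) < 1e-12))
  tr1 <- run_trace(sch)
  tr2 <- markov_trace(pfs, os, s)
  expect_equal(as.data.frame(tr1), as.data.frame(tr2), tolerance = 1e-12)
})

test_that("half-cycle-corrected life-years agree with quadrature RMST", {
  s <- model_settings(half_cycle_correction = TRUE)
  horizon <- s$cycle_length * s$n_cycles
  os <- impower110_curve("high_or_intermediate", "atezolizumab", "os") # gompertz
  pfs <- impower110_curve("high_or_intermediate", "atezolizumab", "pfs")
  ly <- trace_life_years(markov_trace(pfs, os, s))
  expect_equal(ly, surv_rmst(os, horizon) / 12, tolerance = 0.01 / ly)
})
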