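test_that("the SAE inclusion rule keys on the between-arm incidence gap", {
  cand <- tibble::tibble(
    name = c("a", "b", "c"),
    incidence_a = c(0.10, 0.04, 0.05),
    incidence_b = c(0.05, 0.02, 0.02),
    cost = c(500, 250, 100), disutility = c(0.07, 0.05, 0.01)
  )
  expect_equal(sae_filter(cand)$name, c("a", "c")) # diffs 0.05, 0.02, 0.03
  expect_equal(sae_filter(cand, threshold = 0)$name, c("a", "b", "c"))
  expect_equal(nrow(sae_filter(cand, threshold = 0.10)), 0)
})

test_that("the patient-assistance schedule charges 2 cycles in every 5", {
  cfg <- strategy_config("tx", drug_cost_per_cycle = 100, pap = pap_schedule())
  expect_equal(
    drug_cost_at_cycle(cfg, 1:10),
    c(100, 100, 0, 0, 0, 100, 100, 0, 0, 0)
  )
  plain <- strategy_config("tx", drug_cost_per_cycle = 100)
  expect_equal(drug_cost_at_cycle(plain, 1:10), rep(100, 10))
  capped <- strategy_config("tx", drug_cost_per_cycle = 100, max_treatment_cycles = 4)
  expect_equal(drug_cost_at_cycle(capped, 1:6), c(100, 100, 100, 100, 0, 0))
})

make_res <- function(cfg, utilities = utility_set(), discount_rate = NULL,
                     settings = model_settings()) {
  tr <- markov_trace(
    impower110_curve("high", "chemotherapy", "pfs"),
    impower110_curve("high", "chemotherapy", "os"),
    settings
  )
  accumulate(tr, cfg, utilities, discount_rate = discount_rate)
}

test_that("discounting and utility identities hold", {
  cfg <- strategy_config("tx",
    drug_cost_per_cycle = 100, supportive_care_cost_per_cycle = 20,
    end_of_life_cost = 500
  )
  # full utilities, no discounting, no disutility -> QALY equals LY exactly
  res0 <- make_res(cfg, utility_set(1, 1), discount_rate = 0)
  expect_equal(res0$total_qaly, res0$total_ly, tolerance = 1e-12)
  # QALY <= LY always; discounting can only shrink QALYs
  res <- make_res(cfg)
  expect_lte(res$total_qaly, res$total_ly)
  undisc <- make_res(cfg, discount_rate = 0)
  expect_lt(res$total_qaly, undisc$total_qaly)
  expect_equal(res$total_ly, undisc$total_ly) # LYs are never discounted
})

test_that("total cost is homogeneous of degree one in the cost inputs", {
  base_args <- list(
    arm_label = "tx", drug_cost_per_cycle = 100,
    supportive_care_cost_per_cycle = 20, followup_cost_per_cycle = 10,
    end_of_life_cost = 500, second_line_fraction = 0.4,
    second_line_cost_per_cycle = 50,
    saes = tibble::tibble(
      name = "anemia", incidence = 0.1, cost = 300, disutility = 0
    )
  )
  doubled <- base_args
  for (f in c(
    "drug_cost_per_cycle", "supportive_care_cost_per_cycle",
    "followup_cost_per_cycle", "end_of_life_cost", "second_line_cost_per_cycle"
  )) {
    doubled[[f]] <- base_args[[f]] * 2
  }
  doubled$saes$cost <- 600
  r1 <- make_res(do.call(strategy_config, base_args))
  r2 <- make_res(do.call(strategy_config, doubled))
  expect_equal(r2$total_cost, 2 * r1$total_cost, tolerance = 1e-12)
})

test_that("ICER arithmetic, degenerate and dominance cases", {
  fake <- function(cost, qaly, ly = qaly, label = "x") {
    structure(
      list(
        arm_label = label, total_cost = cost, total_ly = ly,
        total_qaly = qaly, discount_rate = 0.05, currency = "USD"
      ),
      class = "economic_result"
    )
  }
  r <- icer(fake(100, 1.0), fake(50, 0.5))
  expect_equal(r$icer, 100)
  expect_equal(r$dominance, "none")
  # equal QALYs: undefined, flagged
  r2 <- icer(fake(100, 1.0), fake(50, 1.0))
  expect_true(r2$undefined)
  expect_true(is.na(r2$icer))
  # cheaper and better: dominant; dearer and worse: dominated
  expect_equal(icer(fake(40, 1.0), fake(50, 0.5))$dominance, "dominant")
  expect_equal(icer(fake(60, 0.4), fake(50, 0.5))$dominance, "dominated")
})

test_that("a cost stream identical in both arms cancels out of the ICER", {
  cfg_a <- strategy_config("a", drug_cost_per_cycle = 300)
  cfg_b <- strategy_config("b", drug_cost_per_cycle = 100)
  shared_sae <- tibble::tibble(
    name = "shared", incidence = 0.2, cost = 1000, disutility = 0
  )
  tr_a <- markov_trace(
    impower110_curve("high", "atezolizumab", "pfs"),
    impower110_curve("high", "atezolizumab", "os"), model_settings()
  )
  tr_b <- markov_trace(
    impower110_curve("high", "chemotherapy", "pfs"),
    impower110_curve("high", "chemotherapy", "os"), model_settings()
  )
  base <- icer(accumulate(tr_a, cfg_a), accumulate(tr_b, cfg_b))
  with_shared <- icer(
    accumulate(tr_a, strategy_config("a", drug_cost_per_cycle = 300, saes = shared_sae)),
    accumulate(tr_b, strategy_config("b", drug_cost_per_cycle = 100, saes = shared_sae))
  )
  expect_equal(base$icer, with_shared$icer, tolerance = 1e-9)
})

test_that("dose helpers price per mg and convert currency linearly", {
  expect_equal(drug_cost_from_dose(2, dose_mg = 1200), 2400)
  expect_equal(drug_cost_from_dose(1.5, dose_mg_per_m2 = 500), 1.5 * 500 * 1.72)
  expect_error(drug_cost_from_dose(1, dose_mg = 10, dose_mg_per_m2 = 10), "exactly one")
  expect_equal(cny_to_usd(6899), 1000)
})

test_that("negative inputs are rejected", {
  expect_error(strategy_config("x", drug_cost_per_cycle = -1), ">= 0")
  expect_error(utility_set(u_pfs = 1.2), "\\[0, 1\\]")
  expect_error(
    strategy_config("x",
      drug_cost_per_cycle = 1,
      saes = tibble::tibble(name = "a", incidence = 1.5, cost = 1, disutility = 0)
    ),
    "\\[0, 1\\]"
  )
})
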