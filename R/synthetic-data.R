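#' Specification of a synthetic two-endpoint trial arm set
#'
#' Describes how to simulate a trial whose progression-free and overall
#' survival have known ground truth. Overall survival is generated
#' additively — OS time = PFS time + a positive post-progression residual —
#' so the OS curve dominates the PFS curve by construction.
#'
#' @param arms Named list; each element is a list with components
#'   `pfs` (a [surv_dist()] for time to progression),
#'   `post_progression` (a [surv_dist()] for the residual survival after
#'   progression), and `n` (arm size).
#' @param admin_censor_time Administrative censoring time in months (end of
#'   follow-up).
#' @param dropout_rate Exponential dropout (loss to follow-up) rate per
#'   month; 0 disables dropout.
#' @param risk_interval Spacing of the numbers-at-risk table, months.
#' @param digitization_step Spacing of the synthetic "digitized" curve
#'   coordinates, months.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(arms, admin_censor_time, dropout_rate = 0,
                       risk_interval = 3, digitization_step = 0.25) {
  stopifnot(
    length(arms) >= 1, !is.null(names(arms)),
    admin_censor_time >= 0, dropout_rate >= 0,
    risk_interval > 0, digitization_step > 0
  )
  for (a in arms) {
    stopifnot(
      inherits(a$pfs, "surv_dist"), inherits(a$post_progression, "surv_dist"),
      a$n > 0
    )
  }
  structure(
    list(
      arms = arms, admin_censor_time = admin_censor_time,
      dropout_rate = dropout_rate, risk_interval = risk_interval,
      digitization_step = digitization_step
    ),
    class = "trial_spec"
  )
}

#' Simulate a trial and its digitized Kaplan-Meier fixtures
#'
#' Draws event times from the specified families, applies administrative
#' censoring and dropout, then produces for each arm and endpoint both the
#' true individual-patient data and a [km_digitization()] built the way a
#' digitizer would see it: the KM step curve read at a regular grid plus a
#' numbers-at-risk table. The true IPD is retained for oracle comparisons.
#'
#' @param spec A [trial_spec()].
#' @param seed Mandatory integer seed; the same seed reproduces the trial
#'   exactly.
#' @return A list of class `synthetic_trial`: per arm, `ipd` (list with
#'   `pfs` and `os` tibbles of observed `time`/`event`), `true_times`
#'   (uncensored), and `digitization` (list with `pfs` and `os`
#'   [km_digitization()] objects).
#' @export
simulate_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "trial_spec"))
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  set.seed(seed)
  out <- lapply(names(spec$arms), function(label) {
    arm <- spec$arms[[label]]
    n <- arm$n
    t_pfs <- surv_rand(arm$pfs, n)
    t_os <- t_pfs + surv_rand(arm$post_progression, n)
    cens <- rep(spec$admin_censor_time, n)
    if (spec$dropout_rate > 0) cens <- pmin(cens, rexp(n, spec$dropout_rate))
    make_endpoint <- function(true_t) {
      obs <- pmin(true_t, cens)
      ev <- as.integer(true_t <= cens)
      tibble(time = obs, event = ev)
    }
    ipd <- list(pfs = make_endpoint(t_pfs), os = make_endpoint(t_os))
    dig <- lapply(names(ipd), function(ep) {
      x <- ipd[[ep]]
      if (sum(x$event) == 0 || max(x$time) == 0) {
        return(NULL) # degenerate: nothing to digitize
      }
      km <- km_estimate(x)
      grid <- seq(0, max(x$time), by = spec$digitization_step)
      if (max(grid) < max(x$time)) grid <- c(grid, max(x$time))
      coords <- tibble(time = grid, survival = km_survival_at(km, grid))
      ticks <- seq(0, max(x$time), by = spec$risk_interval)
      km_digitization(
        coords = coords,
        risk_table = ipd_n_at_risk(x, ticks),
        arm_label = paste(label, ep, sep = "_"),
        total_events = sum(x$event)
      )
    })
    names(dig) <- names(ipd)
    list(
      ipd = ipd,
      true_times = tibble(pfs = t_pfs, os = t_os, censor = cens),
      digitization = dig
    )
  })
  names(out) <- names(spec$arms)
  structure(out, class = "synthetic_trial", seed = seed)
}

#' Synthetic cost/utility configuration for the atezolizumab comparison
#'
#' Builds a complete [cea_config()] in the shape of the published analysis:
#' the Table 1 survival curves of the chosen PD-L1 population, utilities
#' 0.804/0.321, the 3% SAE inclusion rule, 5% discounting, the $30,828/QALY
#' willingness-to-pay threshold, and (optionally) the 2-paid/3-free
#' patient-assistance schedule. The monetary values are synthetic
#' stand-ins (the published charge data are not redistributable); every
#' config carries `synthetic = TRUE` so reports cannot silently present
#' them as the original inputs. Use [calibrate_drug_price()] to pin the
#' incremental cost to a target.
#'
#' Alongside the config, a list of [param_spec()]s is attached as the
#' `psa_params` attribute: costs as gamma, utilities and incidences as
#' beta, each with a +/-25% one-way range.
#'
#' @param population PD-L1 stratum (`"high"`, `"high_or_intermediate"`,
#'   `"any"`).
#' @param with_pap Apply the patient-assistance schedule to the
#'   atezolizumab arm?
#' @return A [cea_config()] with attribute `psa_params`.
#' @export
make_cost_config <- function(population = c("high", "high_or_intermediate", "any"),
                             with_pap = FALSE) {
  population <- match.arg(population)
  curves <- list(
    atezolizumab = list(
      pfs = impower110_curve(population, "atezolizumab", "pfs"),
      os = impower110_curve(population, "atezolizumab", "os")
    ),
    chemotherapy = list(
      pfs = impower110_curve(population, "chemotherapy", "pfs"),
      os = impower110_curve(population, "chemotherapy", "os")
    )
  )
  arms <- list(
    atezolizumab = list(
      # 1200 mg flat every 3 weeks; synthetic price in USD
      drug_cost_per_cycle = 4754,
      supportive_care_cost_per_cycle = 160,
      followup_cost_per_cycle = 70,
      end_of_life_cost = 1850,
      second_line_fraction = 0.40,
      second_line_cost_per_cycle = 640
    ),
    chemotherapy = list(
      # platinum + pemetrexed/gemcitabine at BSA 1.72 m^2; synthetic price
      drug_cost_per_cycle = 1190,
      supportive_care_cost_per_cycle = 160,
      followup_cost_per_cycle = 70,
      end_of_life_cost = 1850,
      second_line_fraction = 0.40,
      second_line_cost_per_cycle = 640
    )
  )
  saes <- tibble::tribble(
    ~name, ~incidence_a, ~incidence_b, ~cost, ~disutility,
    "anemia", 0.010, 0.120, 550, 0.07,
    "neutropenia", 0.005, 0.140, 600, 0.09,
    "thrombocytopenia", 0.005, 0.080, 1200, 0.05,
    "fatigue", 0.010, 0.030, 250, 0.07 # below the 3% rule, filtered out
  )
  config <- cea_config(
    treatment = "atezolizumab", comparator = "chemotherapy",
    curves = curves, arms = arms,
    pap = if (with_pap) pap_schedule() else NULL,
    saes = saes,
    utilities = utility_set(),
    settings = model_settings(),
    synthetic = TRUE
  )
  params <- list(
    param_spec("arms.atezolizumab.drug_cost_per_cycle",
      base = arms$atezolizumab$drug_cost_per_cycle, dist = "gamma"
    ),
    param_spec("arms.chemotherapy.drug_cost_per_cycle",
      base = arms$chemotherapy$drug_cost_per_cycle, dist = "gamma"
    ),
    param_spec("arms.atezolizumab.second_line_cost_per_cycle",
      base = 640, dist = "gamma"
    ),
    param_spec("arms.atezolizumab.supportive_care_cost_per_cycle",
      base = 160, dist = "gamma"
    ),
    param_spec("arms.atezolizumab.end_of_life_cost", base = 1850, dist = "gamma"),
    # the +25% arm of the PFS utility is capped at 1 (a utility cannot
    # exceed full health)
    param_spec("utilities.u_pfs",
      base = 0.804, low = 0.804 * 0.75, high = 1, dist = "beta"
    ),
    param_spec("utilities.u_pd", base = 0.321, dist = "beta"),
    param_spec("saes.anemia.cost", base = 550, dist = "gamma"),
    param_spec("saes.neutropenia.incidence_b", base = 0.140, dist = "beta")
  )
  attr(config, "psa_params") <- params
  config
}

#' Calibrate the treatment drug price to a target incremental cost
#'
#' Total discounted cost is affine in any per-cycle price, so the price
#' that achieves a target incremental cost is solved exactly from two model
#' evaluations. Used to build regression fixtures whose incremental cost
#' matches a published figure.
#'
#' @param config A [cea_config()].
#' @param target_delta_cost Desired incremental (treatment minus
#'   comparator) discounted cost.
#' @param param Dot path of the price being tuned.
#' @return The config with the calibrated price set.
#' @export
calibrate_drug_price <- function(config, target_delta_cost,
                                 param = "arms.atezolizumab.drug_cost_per_cycle") {
  model <- cea_model(config)
  d0 <- model(setNames(list(0), param))$delta_cost
  d1 <- model(setNames(list(1), param))$delta_cost
  slope <- d1 - d0
  if (abs(slope) < 1e-12) abort("incremental cost does not depend on this price")
  price <- (target_delta_cost - d0) / slope
  if (price < 0) abort("target incremental cost implies a negative price")
  config <- config_set(config, param, price)
  # keep the attached sensitivity specs centred on the calibrated value
  specs <- attr(config, "psa_params")
  if (!is.null(specs)) {
    for (i in seq_along(specs)) {
      if (identical(specs[[i]]$name, param)) {
        specs[[i]] <- param_spec(param, base = price, dist = specs[[i]]$dist)
      }
    }
    attr(config, "psa_params") <- specs
  }
  config
}
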