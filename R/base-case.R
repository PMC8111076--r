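#' Published survival parameterizations from the IMpower110 comparison
#'
#' The parametric curves fitted to the IMpower110 progression-free and
#' overall survival data (time in months) for first-line atezolizumab
#' versus platinum-based chemotherapy, by PD-L1 expression stratum. These
#' are the inputs to the base-case cohort model.
#'
#' @return A tibble with columns `population` (`"high"`,
#'   `"high_or_intermediate"`, `"any"`), `arm`, `endpoint` (`"pfs"`/`"os"`),
#'   `family`, and the two parameter columns `par1`, `par2` named per
#'   family convention (see [surv_dist()]).
#' @export
impower110_parameters <- function() {
  tibble::tribble(
    ~population, ~arm, ~endpoint, ~family, ~par1, ~par2,
    "high", "atezolizumab", "pfs", "log_normal", 2.098, 1.494,
    "high", "atezolizumab", "os", "log_normal", 3.180, 2.002,
    "high", "chemotherapy", "pfs", "log_logistic", 1.724, 4.995,
    "high", "chemotherapy", "os", "log_logistic", 1.407, 11.610,
    "high_or_intermediate", "atezolizumab", "pfs", "log_normal", 1.971, 1.312,
    "high_or_intermediate", "atezolizumab", "os", "gompertz", -0.020, 0.043,
    "high_or_intermediate", "chemotherapy", "pfs", "log_logistic", 1.902, 5.188,
    "high_or_intermediate", "chemotherapy", "os", "log_logistic", 1.538, 13.316,
    "any", "atezolizumab", "pfs", "log_normal", 1.798, 1.321,
    "any", "atezolizumab", "os", "log_logistic", 1.117, 17.245,
    "any", "chemotherapy", "pfs", "log_logistic", 1.919, 5.279,
    "any", "chemotherapy", "os", "log_logistic", 1.503, 13.17
  )
}

#' Look up one published survival curve as a distribution object
#'
#' @param population One of `"high"`, `"high_or_intermediate"`, `"any"`.
#' @param arm `"atezolizumab"` or `"chemotherapy"`.
#' @param endpoint `"pfs"` or `"os"`.
#' @return A [surv_dist()].
#' @export
impower110_curve <- function(population, arm, endpoint) {
  population <- match.arg(population, c("high", "high_or_intermediate", "any"))
  arm <- match.arg(arm, c("atezolizumab", "chemotherapy"))
  endpoint <- match.arg(endpoint, c("pfs", "os"))
  tab <- impower110_parameters()
  row <- tab[tab$population == population & tab$arm == arm & tab$endpoint == endpoint, ]
  stopifnot(nrow(row) == 1)
  params <- setNames(c(row$par1, row$par2), surv_param_names(row$family))
  surv_dist(row$family, params)
}

#' Base-case life-years and QALYs by arm
#'
#' Runs the three-state cohort model for both arms of one PD-L1 population
#' using the published survival curves, and returns undiscounted life-years
#' and discounted QALYs (no cost inputs are needed for these).
#'
#' @param population PD-L1 stratum.
#' @param settings A [model_settings()].
#' @param utilities A [utility_set()].
#' @return A tibble with one row per arm: `arm`, `ly`, `qaly`.
#' @examples
#' base_case_outcomes("high")
#' @export
base_case_outcomes <- function(population = c("high", "high_or_intermediate", "any"),
                               settings = model_settings(),
                               utilities = utility_set()) {
  population <- match.arg(population)
  purrr::map_dfr(c("atezolizumab", "chemotherapy"), function(arm) {
    trace <- markov_trace(
      impower110_curve(population, arm, "pfs"),
      impower110_curve(population, arm, "os"),
      settings
    )
    cfg <- strategy_config(arm_label = arm, drug_cost_per_cycle = 0)
    res <- accumulate(trace, cfg, utilities)
    tibble(arm = arm, ly = res$total_ly, qaly = res$total_qaly)
  })
}
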