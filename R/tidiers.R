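#' Tidy a survival fit
#'
#' @param x A `surv_fit` from [fit_parametric()].
#' @param ... Unused.
#' @return One row per parameter: `family`, `term`, `estimate`.
#' @export
tidy.surv_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(
      family = x$family, term = character(0), estimate = numeric(0)
    ))
  }
  tibble(
    family = x$family,
    term = names(x$dist$params),
    estimate = unname(x$dist$params)
  )
}

#' @rdname tidy.surv_fit
#' @export
glance.surv_fit <- function(x, ...) {
  tibble(
    family = x$family, converged = x$converged,
    loglik = x$loglik, n_params = x$n_params, aic = x$aic,
    n = x$n, n_event = x$n_event
  )
}

#' Tidy a model-selection result
#'
#' @param x A `fit_selection` from [select_best()].
#' @param ... Unused.
#' @return The per-family comparison table with a `best` flag, sorted by
#'   AIC.
#' @export
tidy.fit_selection <- function(x, ...) {
  dplyr::arrange(
    dplyr::mutate(x$table, best = .data$family == x$best_family),
    .data$aic
  )
}

#' @rdname tidy.fit_selection
#' @export
glance.fit_selection <- function(x, ...) {
  tibble(
    best_family = x$best_family,
    aic = x$best$aic, loglik = x$best$loglik,
    n_converged = sum(x$table$converged)
  )
}

#' Tidy an economic result
#'
#' @param x An `economic_result` from [accumulate()].
#' @param ... Unused.
#' @return The per-cycle breakdown tibble.
#' @export
tidy.economic_result <- function(x, ...) x$breakdown

#' @rdname tidy.economic_result
#' @export
glance.economic_result <- function(x, ...) {
  tibble(
    arm = x$arm_label, total_cost = x$total_cost,
    total_ly = x$total_ly, total_qaly = x$total_qaly,
    discount_rate = x$discount_rate, currency = x$currency
  )
}

#' Tidy an incremental comparison
#'
#' @param x An `icer_result` from [icer()].
#' @param ... Unused.
#' @return One-row tibble with the incremental cost, QALYs, life-years,
#'   ICER and dominance flag.
#' @export
tidy.icer_result <- function(x, ...) {
  tibble(
    treatment = x$treatment, comparator = x$comparator,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    delta_ly = x$delta_ly, icer = x$icer, dominance = x$dominance
  )
}
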