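#' Parameter specification for sensitivity analysis
#'
#' One model parameter with its base value, one-way range, and sampling
#' distribution for probabilistic analysis. When no range is given, the
#' one-way range defaults to +/-25% of the base value. Distribution
#' hyperparameters are derived by method of moments from (base, se), with
#' the standard error defaulting to a quarter of the base value when no
#' confidence interval is available.
#'
#' Distributions: `gamma` for costs, `beta` for incidences, proportions and
#' utilities, `lognormal` for ratio-like quantities, `normal`, or `fixed`
#' (degenerate at base).
#'
#' @param name Dot path of the parameter inside a [cea_config()] (see
#'   [run_cea()]).
#' @param base Base-case value.
#' @param low,high One-way bounds; default `base * 0.75` / `base * 1.25`.
#' @param dist Sampling distribution.
#' @param se Standard error for the sampling distribution; default
#'   `(high - low) / (2 * 1.96)` if bounds were given explicitly, else
#'   `base / 4`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base, low = NULL, high = NULL,
                       dist = c("gamma", "beta", "lognormal", "normal", "fixed"),
                       se = NULL) {
  dist <- match.arg(dist)
  explicit_range <- !is.null(low) || !is.null(high)
  low <- low %||% (base * 0.75)
  high <- high %||% (base * 1.25)
  if (base < 0) {
    lo <- low; low <- min(low, high); high <- max(lo, high)
  }
  if (!(low <= base && base <= high)) abort("need low <= base <= high")
  se <- se %||% if (explicit_range) (high - low) / (2 * 1.96) else abs(base) / 4
  if (dist == "beta" && (base <= 0 || base >= 1)) {
    abort("beta-distributed parameters need base in (0, 1)")
  }
  if (dist %in% c("gamma", "lognormal") && base <= 0 && se > 0) {
    abort(sprintf("%s-distributed parameters need base > 0", dist))
  }
  structure(
    list(name = name, base = base, low = low, high = high, dist = dist, se = se),
    class = "param_spec"
  )
}

# quantile-based sampling so that draws scale monotonically with the mean
draw_param <- function(spec, u) {
  m <- spec$base
  s <- spec$se
  if (spec$dist == "fixed" || s == 0) {
    return(rep(m, length(u)))
  }
  switch(spec$dist,
    gamma = {
      shape <- (m / s)^2
      rate <- m / s^2
      qgamma(u, shape = shape, rate = rate)
    },
    beta = {
      v <- s^2
      v <- min(v, m * (1 - m) * 0.99) # keep the method of moments proper
      nu <- m * (1 - m) / v - 1
      qbeta(u, shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      qlnorm(u, meanlog, sdlog)
    },
    normal = qnorm(u, mean = m, sd = s)
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the model twice per parameter — once at its low and once at its
#' high value, everything else at base — and reports the ICER swing.
#'
#' @param model A model closure from [cea_model()].
#' @param params List of [param_spec()]s.
#' @return A tibble of class `tornado`, sorted by decreasing `spread`:
#'   `parameter`, `low`, `high`, `icer_base`, `icer_at_low`, `icer_at_high`,
#'   `spread`.
#' @export
one_way <- function(model, params) {
  stopifnot(is.function(model), length(params) >= 1)
  base_icer <- model()$icer
  rows <- purrr::map_dfr(params, function(p) {
    lo <- model(setNames(list(p$low), p$name))$icer
    hi <- model(setNames(list(p$high), p$name))$icer
    tibble(
      parameter = p$name, low = p$low, high = p$high,
      icer_base = base_icer, icer_at_low = lo, icer_at_high = hi,
      spread = abs(hi - lo)
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$spread))
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Each iteration samples every parameter jointly (independently across
#' parameters) from its [param_spec()] distribution, reruns both arms, and
#' records the incremental cost and QALYs. Survival-curve uncertainty can
#' be added through `curve_draws`: named lists of [surv_dist()] draws (e.g.
#' from [resample_fit()]) keyed like the config's `curves` entries.
#'
#' @param model A model closure from [cea_model()].
#' @param params List of [param_spec()]s.
#' @param n_iter Number of iterations (the published analysis used 1000).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @param curve_draws Optional list like
#'   `list(atezolizumab.os = list(<surv_dist>, ...))` of length-`n_iter`
#'   curve resamples; entry i is applied at iteration i via the
#'   `curves.<arm>.<endpoint>.<param>` overrides.
#' @return A tibble of class `psa_samples`: `iteration`, `delta_cost`,
#'   `delta_qaly`, `icer`, plus one column per sampled parameter.
#' @export
psa <- function(model, params, n_iter = 1000, seed = NULL, curve_draws = NULL) {
  stopifnot(is.function(model), length(params) >= 1, n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(runif(n_iter * length(params)), nrow = n_iter)
  nms <- vapply(params, `[[`, "", "name")
  draws <- as_tibble(setNames(
    lapply(seq_along(params), function(j) draw_param(params[[j]], u[, j])),
    nms
  ))
  results <- purrr::map_dfr(seq_len(n_iter), function(i) {
    ov <- as.list(draws[i, , drop = FALSE])
    if (!is.null(curve_draws)) {
      for (key in names(curve_draws)) {
        d <- curve_draws[[key]][[i]]
        for (pn in names(d$params)) {
          ov[[paste("curves", key, pn, sep = ".")]] <- d$params[[pn]]
        }
      }
    }
    model(ov)[, c("delta_cost", "delta_qaly", "icer")]
  })
  out <- dplyr::bind_cols(tibble(iteration = seq_len(n_iter)), results, draws)
  class(out) <- c("psa_samples", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the treatment is
#' cost-effective is the fraction of PSA samples with positive incremental
#' net monetary benefit, `wtp * delta_qaly - delta_cost > 0`. Every grid
#' point is computed from the same sample set.
#'
#' @param samples A `psa_samples` tibble from [psa()].
#' @param wtp Willingness-to-pay grid (default 0 to 200,000 by 1,000).
#' @return A tibble of class `ceac_curve`: `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp = seq(0, 200000, by = 1000)) {
  stopifnot(nrow(samples) > 0, all(wtp >= 0))
  prob <- vapply(
    wtp,
    function(l) mean(l * samples$delta_qaly - samples$delta_cost > 0),
    numeric(1)
  )
  out <- tibble(wtp = wtp, probability = prob)
  class(out) <- c("ceac_curve", class(out))
  out
}

scale_param <- function(spec, factor) {
  param_spec(
    name = spec$name, base = spec$base * factor,
    low = spec$low * factor, high = spec$high * factor,
    dist = spec$dist, se = spec$se * factor
  )
}

#' Price-reduction scenario scan
#'
#' Reruns the probabilistic analysis with the treatment drug price (its
#' base value and sampling distribution) scaled down by each reduction on
#' the grid, and reports the probability of cost-effectiveness at the given
#' willingness-to-pay threshold. The same seed is used at every grid point,
#' so the probability is nondecreasing along the grid.
#'
#' @param config A [cea_config()].
#' @param params List of [param_spec()]s (must contain `price_param`).
#' @param reductions Price-reduction grid in `[0, 1]` (0 = list price).
#' @param wtp Willingness-to-pay threshold; defaults to the config's.
#' @param n_iter,seed Passed to [psa()].
#' @param price_param Dot path of the treatment drug price.
#' @return A tibble: `reduction`, `probability`.
#' @export
price_scan <- function(config, params, reductions = seq(0, 0.9, by = 0.1),
                       wtp = NULL, n_iter = 1000, seed = 1,
                       price_param = "arms.atezolizumab.drug_cost_per_cycle") {
  stopifnot(all(reductions >= 0 & reductions <= 1))
  wtp <- wtp %||% config$wtp
  names_ <- vapply(params, `[[`, "", "name")
  if (!price_param %in% names_) abort("price_param must appear in params")
  purrr::map_dfr(reductions, function(red) {
    cfg <- config_set(config, price_param, config_get(config, price_param) * (1 - red))
    pars <- params
    pars[[which(names_ == price_param)]] <-
      scale_param(params[[which(names_ == price_param)]], 1 - red)
    samples <- psa(cea_model(cfg), pars, n_iter = n_iter, seed = seed)
    tibble(
      reduction = red,
      probability = ceac(samples, wtp = wtp)$probability
    )
  })
}
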