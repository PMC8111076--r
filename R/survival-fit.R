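flexsurv_dist_name <- function(family) {
  switch(family,
    exponential  = "exp",
    gamma        = "gamma",
    weibull      = "weibull",
    log_logistic = "llogis",
    log_normal   = "lnorm",
    gompertz     = "gompertz"
  )
}

#' Fit one parametric survival family by maximum likelihood
#'
#' Right-censored MLE via [flexsurv::flexsurvreg()], returned with the
#' package's own [surv_dist()] attached so the fitted curve can be fed
#' straight into the Markov engine. Non-convergence is reported as a flagged
#' failure (`converged = FALSE`), not an error, so that model selection can
#' skip the family.
#'
#' @param ipd Data frame with columns `time` (> 0, months) and `event`
#'   (1 = event, 0 = censored); at least one event.
#' @param family A family name from [surv_families()].
#' @return An object of class `surv_fit`: the fitted `dist`, `loglik`,
#'   `aic`, `n_params`, the covariance of the estimates on the fit
#'   (transformed) scale, and the transforms needed to resample them.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (sum(ipd$event) < 1) abort("no events in ipd; cannot fit")
  dat <- data.frame(time = as.numeric(ipd$time), event = as.integer(ipd$event))
  dat <- dat[order(dat$time), , drop = FALSE] # fit invariant to subject order
  dat$time <- pmax(dat$time, 1e-8) # log-time families need t > 0
  fit <- tryCatch(
    withCallingHandlers(
      flexsurv::flexsurvreg(
        survival::Surv(time, event) ~ 1,
        data = dat, dist = flexsurv_dist_name(family)
      ),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(
        family = family, converged = FALSE, message = conditionMessage(fit),
        dist = NULL, loglik = -Inf, aic = Inf,
        n_params = length(surv_param_names(family)),
        n = nrow(dat), n_event = sum(dat$event)
      ),
      class = "surv_fit"
    ))
  }
  est <- fit$res[, "est"]
  names(est) <- rownames(fit$res)
  # flexsurv uses the same parameter names and order as surv_dist()
  dist <- surv_dist(family, est, loglik = fit$loglik, vcov = fit$cov)
  structure(
    list(
      family = family, converged = TRUE, dist = dist,
      loglik = fit$loglik, aic = fit$AIC,
      n_params = nrow(fit$res),
      estimates_transformed = fit$res.t[, "est"],
      vcov_transformed = fit$cov,
      inv_transforms = fit$dlist$inv.transforms,
      n = nrow(dat), n_event = sum(dat$event)
    ),
    class = "surv_fit"
  )
}

#' @export
print.surv_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<surv_fit> %s: did not converge (%s)\n", x$family, x$message))
  } else {
    cat(sprintf(
      "<surv_fit> %s(%s)  loglik = %.3f  AIC = %.3f  (n = %d, events = %d)\n",
      x$family,
      paste(sprintf("%s = %.4g", names(x$dist$params), x$dist$params), collapse = ", "),
      x$loglik, x$aic, x$n, x$n_event
    ))
  }
  invisible(x)
}

#' Fit several survival families to the same data
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @param families Families to try; defaults to all six.
#' @return Named list of [fit_parametric()] results, class `surv_fit_list`.
#' @export
fit_families <- function(ipd, families = surv_families()) {
  structure(
    setNames(lapply(families, function(f) fit_parametric(ipd, f)), families),
    class = "surv_fit_list"
  )
}

#' Akaike information criterion
#'
#' @param loglik Fit log-likelihood.
#' @param n_params Number of free parameters.
#' @return `2 * n_params - 2 * loglik`.
#' @export
aic <- function(loglik, n_params) 2 * n_params - 2 * loglik

#' Select the best-fitting survival family by AIC
#'
#' Lowest AIC wins; ties are broken by fewer parameters, then by the fixed
#' family order of [surv_families()]. Families that failed to converge are
#' excluded.
#'
#' @param fits A `surv_fit_list` from [fit_families()].
#' @return An object of class `fit_selection` with the comparison table and
#'   the chosen fit.
#' @export
select_best <- function(fits) {
  stopifnot(inherits(fits, "surv_fit_list") || is.list(fits))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) abort("no survival family converged")
  fam <- unname(vapply(fits, function(f) f$family, character(1)))
  tab <- tibble(
    family = fam,
    converged = unname(ok),
    loglik = unname(vapply(fits, function(f) f$loglik, numeric(1))),
    n_params = unname(vapply(fits, function(f) f$n_params, numeric(1))),
    aic = unname(vapply(fits, function(f) f$aic, numeric(1))),
    family_order = match(fam, surv_families())
  )
  cand <- dplyr::arrange(
    dplyr::filter(tab, .data$converged),
    .data$aic, .data$n_params, .data$family_order
  )
  best_family <- cand$family[1]
  structure(
    list(
      table = dplyr::select(tab, -"family_order"),
      best_family = best_family,
      best = fits[[best_family]],
      fits = fits
    ),
    class = "fit_selection"
  )
}

#' @export
print.fit_selection <- function(x, ...) {
  cat(sprintf("<fit_selection> best family: %s\n", x$best_family))
  print(dplyr::arrange(x$table, .data$aic))
  invisible(x)
}

#' Resample fitted survival parameters for probabilistic analysis
#'
#' Draws parameter vectors from a multivariate normal on the fit
#' (transformed) scale using the MLE covariance, then back-transforms, so
#' positivity constraints are respected. This is how survival-curve
#' uncertainty enters the probabilistic sensitivity analysis.
#'
#' @param fit A converged [fit_parametric()] result.
#' @param n Number of draws.
#' @return A list of [surv_dist()] objects of length `n`.
#' @export
resample_fit <- function(fit, n) {
  stopifnot(inherits(fit, "surv_fit"), isTRUE(fit$converged))
  mu <- fit$estimates_transformed
  sig <- fit$vcov_transformed
  draws <- MASS::mvrnorm(n, mu = mu, Sigma = sig)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
  lapply(seq_len(n), function(i) {
    nat <- vapply(
      seq_along(mu),
      function(j) fit$inv_transforms[[j]](draws[i, j]), numeric(1)
    )
    names(nat) <- surv_param_names(fit$family)
    surv_dist(fit$family, nat)
  })
}
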