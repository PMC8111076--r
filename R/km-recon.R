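#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' Bundles the click coordinates read off a published KM plot with the
#' numbers-at-risk table printed beneath it, after validating both. This is
#' the input to [reconstruct_ipd()].
#'
#' Risk-table counts are interpreted as subjects still under observation
#' immediately *after* the tick time, so a curve step exactly at a tick is
#' processed before the count applies. For the dense digitizations this
#' package works with the boundary choice is immaterial.
#'
#' @param coords Data frame with columns `time` (months) and `survival`
#'   (fraction). Times must be nondecreasing, survival nonincreasing and in
#'   `[0, 1]`.
#' @param risk_table Data frame with columns `time` and `n_risk`
#'   (nonincreasing counts; the count at the first time is the arm size).
#' @param arm_label Label carried through to outputs.
#' @param total_events Optional total event count reported by the trial.
#'   Stored for reference; the unconstrained reconstruction variant is used
#'   either way.
#' @return An object of class `km_digitization`.
#' @export
km_digitization <- function(coords, risk_table, arm_label = "arm",
                            total_events = NULL) {
  coords <- as_tibble(coords)
  risk_table <- as_tibble(risk_table)
  if (!all(c("time", "survival") %in% names(coords))) {
    abort("coords needs columns time, survival")
  }
  if (!all(c("time", "n_risk") %in% names(risk_table))) {
    abort("risk_table needs columns time, n_risk")
  }
  if (nrow(risk_table) < 2) abort("need at least 2 risk-table entries")
  if (is.unsorted(coords$time)) abort("coords times must be nondecreasing")
  if (any(diff(coords$survival) > 1e-12)) {
    abort("survival fractions must be nonincreasing (fix digitization noise upstream)")
  }
  if (any(coords$survival < 0 | coords$survival > 1)) {
    abort("survival fractions must lie in [0, 1]")
  }
  if (is.unsorted(risk_table$time, strictly = TRUE)) {
    abort("risk_table times must be strictly increasing")
  }
  if (any(diff(risk_table$n_risk) > 0)) {
    abort("risk_table counts must be nonincreasing")
  }
  if (risk_table$n_risk[1] <= 0) abort("arm size (n at first risk time) must be > 0")
  if (min(coords$time) > risk_table$time[1] ||
    max(coords$time) < risk_table$time[nrow(risk_table)]) {
    abort("coords must span the risk-table interval")
  }
  structure(
    list(
      arm_label = arm_label, coords = coords, risk_table = risk_table,
      total_events = total_events
    ),
    class = "km_digitization"
  )
}

#' @export
print.km_digitization <- function(x, ...) {
  cat(sprintf(
    "<km_digitization> %s: %d coordinates, %d risk-table rows, n = %d\n",
    x$arm_label, nrow(x$coords), nrow(x$risk_table), x$risk_table$n_risk[1]
  ))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Iterative reconstruction in the style of Guyot et al.: within each
#' risk-table interval a number of censorings is proposed, spread uniformly
#' over the interval, event counts at each digitized coordinate are chosen
#' so the product-limit estimator tracks the digitized survival, and the
#' censoring count is adjusted until the implied number at risk at the next
#' tick matches the printed risk table. In the final interval (beyond the
#' last tick the curve extends past) the censoring rate is carried over from
#' the earlier intervals. Subjects still at risk after the last coordinate
#' are administratively censored there, so the reconstructed cohort size
#' equals the arm size.
#'
#' @param dig A [km_digitization()], or a coords data frame (in which case
#'   `risk_table` must be supplied).
#' @param risk_table Optional risk table when `dig` is a plain data frame.
#' @param arm_label Label used when building the digitization on the fly.
#' @return A tibble with columns `time` (months) and `event`
#'   (1 = event, 0 = censored), one row per reconstructed subject.
#' @examples
#' dig <- km_digitization(
#'   coords = data.frame(time = c(0, 6), survival = c(1, 0.5)),
#'   risk_table = data.frame(time = c(0, 6), n_risk = c(2, 1))
#' )
#' reconstruct_ipd(dig)
#' @export
reconstruct_ipd <- function(dig, risk_table = NULL, arm_label = "arm") {
  if (!inherits(dig, "km_digitization")) {
    dig <- km_digitization(dig, risk_table, arm_label = arm_label)
  }
  ts <- dig$coords$time
  S <- dig$coords$survival
  tr <- dig$risk_table$time
  nr <- dig$risk_table$n_risk
  K <- length(ts)
  J <- length(tr)

  # coordinate index ranges per interval: interval j covers (tr[j], tr[j+1]],
  # interval 1 additionally includes the origin coordinate, the last interval
  # runs to the final coordinate
  upper <- integer(J)
  for (j in seq_len(J - 1)) upper[j] <- max(0L, findInterval(tr[j + 1] + 1e-9, ts))
  upper[J] <- K
  lower <- c(1L, head(upper, -1) + 1L)

  # Walk the coordinates of interval j assuming n_cen censorings spread
  # uniformly over it. Events at each coordinate are chosen so the running
  # product-limit estimate tracks the digitized survival; `sref` is the KM
  # value at the last coordinate that carried events.
  walk <- function(j, n_cen, nhat0, sref0) {
    lo <- lower[j]
    up <- upper[j]
    a <- tr[j]
    b <- if (j < J) tr[j + 1] else max(ts)
    ct <- if (n_cen > 0 && b > a) {
      a + (b - a) * (seq_len(n_cen) - 0.5) / n_cen
    } else {
      numeric(0)
    }
    dj <- integer(max(0L, up - lo + 1L))
    sref <- sref0
    if (up >= lo) {
      for (i in seq_len(up - lo + 1L)) {
        k <- lo + i - 1L
        nhat_k <- nhat0 - sum(ct < ts[k] - 1e-9) - sum(dj)
        dk <- 0L
        if (nhat_k > 0 && sref > 0) {
          dk <- as.integer(min(max(round_half_up(nhat_k * (1 - S[k] / sref)), 0), nhat_k))
        }
        if (dk > 0) sref <- sref * (1 - dk / nhat_k)
        dj[i] <- dk
      }
    }
    list(
      nhat_end = nhat0 - sum(dj) - length(ct),
      d = dj, cen_times = ct, sref = sref
    )
  }

  events_at <- integer(K)
  censor_times <- list()
  nhat <- nr[1]
  sref <- 1
  total_cen <- 0
  total_width <- 0
  for (j in seq_len(J)) {
    if (j < J) {
      s_next <- if (upper[j] < K) S[upper[j] + 1L] else S[K]
      guess <- round_half_up(nhat * s_next / max(S[lower[min(j, J)]], 1e-12) - nr[j + 1])
      n_cen <- as.integer(min(max(guess, 0L), nhat))
      best <- NULL
      tried <- integer(0)
      for (iter in 1:50) {
        res <- walk(j, n_cen, nhat, sref)
        gap <- res$nhat_end - nr[j + 1]
        if (is.null(best) || abs(gap) < abs(best$gap)) best <- list(res = res, gap = gap, n_cen = n_cen)
        if (gap == 0L || n_cen %in% tried) break
        tried <- c(tried, n_cen)
        n_cen <- as.integer(min(max(n_cen + gap, 0L), nhat))
      }
      res <- best$res
      if (best$gap != 0L) {
        warn(sprintf(
          "interval %d: implied n at risk %d differs from risk table %d",
          j, res$nhat_end, nr[j + 1]
        ))
      }
      total_cen <- total_cen + length(res$cen_times)
      total_width <- total_width + (tr[j + 1] - tr[j])
    } else {
      # final interval: carry over the censoring rate seen so far
      w <- max(max(ts) - tr[J], 0)
      rate <- if (total_width > 0) total_cen / total_width else 0
      n_cen <- as.integer(min(round_half_up(rate * w), nhat))
      res <- walk(j, n_cen, nhat, sref)
    }
    if (upper[j] >= lower[j]) {
      events_at[lower[j]:upper[j]] <- res$d
    }
    censor_times[[j]] <- res$cen_times
    nhat <- res$nhat_end
    sref <- res$sref
  }

  cens <- unlist(censor_times)
  times <- c(rep(ts, events_at), cens)
  events <- c(rep(1L, sum(events_at)), rep(0L, length(cens)))
  # whoever is left is administratively censored at the last coordinate
  if (nhat > 0) {
    times <- c(times, rep(max(ts), nhat))
    events <- c(events, rep(0L, nhat))
  }
  ord <- order(times, -events)
  tibble(time = times[ord], event = events[ord])
}

#' Product-limit (Kaplan-Meier) estimate from individual-patient data
#'
#' Thin wrapper around [survival::survfit()] returning the step curve as a
#' tibble, used to verify that reconstruction round-trips the digitized
#' coordinates.
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(ipd) {
  stopifnot(all(c("time", "event") %in% names(ipd)), nrow(ipd) > 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = as.data.frame(ipd))
  tibble(
    time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
}

#' Evaluate a KM step curve at arbitrary times
#'
#' @param km Output of [km_estimate()].
#' @param t Times at which to read the step function (S = 1 before the
#'   first event/censoring time).
#' @return Survival fractions.
#' @export
km_survival_at <- function(km, t) {
  idx <- findInterval(t + 1e-12, km$time)
  out <- rep(1, length(t))
  out[idx > 0] <- km$survival[idx[idx > 0]]
  out
}

#' Numbers at risk implied by individual-patient data
#'
#' Counts subjects still under observation immediately after each requested
#' time, the convention used for [km_digitization()] risk tables.
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @param times Tick times.
#' @return A tibble with columns `time`, `n_risk`.
#' @export
ipd_n_at_risk <- function(ipd, times) {
  tibble(
    time = times,
    n_risk = vapply(times, function(tt) sum(ipd$time > tt + 1e-12), integer(1))
  )
}
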