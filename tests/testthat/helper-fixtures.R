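# shared fixtures: small synthetic trials with known ground truth

exp_trial_spec <- function(n = 200, rate_pfs = 0.10, rate_pp = 0.10,
                           censor = 24, risk_interval = 3,
                           digitization_step = 0.25) {
  trial_spec(
    arms = list(a = list(
      pfs = surv_dist("exponential", rate = rate_pfs),
      post_progression = surv_dist("exponential", rate = rate_pp),
      n = n
    )),
    admin_censor_time = censor,
    risk_interval = risk_interval,
    digitization_step = digitization_step
  )
}

table1_curves <- function() {
  tab <- impower110_parameters()
  lapply(split(tab, seq_len(nrow(tab))), function(row) {
    list(
      population = row$population, arm = row$arm, endpoint = row$endpoint,
      dist = impower110_curve(row$population, row$arm, row$endpoint)
    )
  })
}
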