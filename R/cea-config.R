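#' Assemble a full cost-effectiveness configuration
#'
#' A `cea_config` bundles everything one pairwise comparison needs: the two
#' arms' survival curves, their economic inputs, utilities, SAE candidates,
#' and model settings. It is a plain nested list of scalars and small
#' tables, so it serializes losslessly to JSON.
#'
#' @param treatment,comparator Arm labels (treatment is the new strategy).
#' @param curves Named list: for each arm label, a list with `pfs` and `os`
#'   [surv_dist()] objects.
#' @param arms Named list: for each arm label, a list of
#'   [strategy_config()] arguments (without `arm_label`, `pap`, `saes`).
#' @param pap `NULL`, or a [pap_schedule()] applied to the treatment arm.
#' @param saes SAE candidate tibble for [sae_filter()]: columns `name`,
#'   `incidence_a` (treatment), `incidence_b` (comparator), `cost`,
#'   `disutility`.
#' @param utilities A [utility_set()] or list with `u_pfs`, `u_pd`.
#' @param settings A [model_settings()].
#' @param sae_threshold Between-arm incidence difference below which an SAE
#'   is ignored (default 0.03).
#' @param wtp Willingness-to-pay threshold per QALY (default 30828 USD,
#'   three times China's 2019 per-capita GDP).
#' @param synthetic Flag marking cost values as synthetic stand-ins rather
#'   than the published charge data.
#' @return An object of class `cea_config`.
#' @export
cea_config <- function(treatment, comparator, curves, arms,
                       pap = NULL, saes = NULL,
                       utilities = utility_set(),
                       settings = model_settings(),
                       sae_threshold = 0.03, wtp = 30828,
                       synthetic = TRUE) {
  stopifnot(
    all(c(treatment, comparator) %in% names(curves)),
    all(c(treatment, comparator) %in% names(arms))
  )
  structure(
    list(
      treatment = treatment, comparator = comparator,
      curves = curves, arms = arms, pap = pap, saes = saes,
      utilities = utilities, settings = settings,
      sae_threshold = sae_threshold, wtp = wtp, synthetic = isTRUE(synthetic)
    ),
    class = "cea_config"
  )
}

# set a scalar leaf addressed by a dot path, e.g.
# "arms.atezolizumab.drug_cost_per_cycle", "utilities.u_pd",
# "saes.anemia.cost", "curves.atezolizumab.os.meanlog"
config_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "saes") {
    stopifnot(length(parts) == 3)
    i <- which(config$saes$name == parts[2])
    if (length(i) != 1) abort(sprintf("unknown SAE '%s'", parts[2]))
    config$saes[[parts[3]]][i] <- value
    return(config)
  }
  if (parts[1] == "curves") {
    stopifnot(length(parts) == 4)
    d <- config$curves[[parts[2]]][[parts[3]]]
    d$params[[parts[4]]] <- value
    config$curves[[parts[2]]][[parts[3]]] <-
      surv_dist(d$family, d$params)
    return(config)
  }
  node <- config
  for (p in head(parts, -1)) {
    node <- node[[p]]
    if (is.null(node)) abort(sprintf("unknown config path '%s'", path))
  }
  expr <- paste0(
    "config", paste0("[['", parts, "']]", collapse = ""), " <- value"
  )
  eval(parse(text = expr))
  config
}

config_get <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "saes") {
    i <- which(config$saes$name == parts[2])
    return(config$saes[[parts[3]]][i])
  }
  if (parts[1] == "curves") {
    return(config$curves[[parts[2]]][[parts[3]]]$params[[parts[4]]])
  }
  node <- config
  for (p in parts) node <- node[[p]]
  node
}

build_arm <- function(config, arm, role) {
  args <- config$arms[[arm]]
  args$arm_label <- arm
  if (!is.null(config$pap) && identical(arm, config$treatment)) {
    args$pap <- config$pap
  }
  if (!is.null(config$saes)) {
    kept <- sae_filter(config$saes, config$sae_threshold)
    if (nrow(kept) > 0) {
      inc <- if (role == "treatment") kept$incidence_a else kept$incidence_b
      args$saes <- tibble(
        name = kept$name, incidence = inc,
        cost = kept$cost, disutility = kept$disutility
      )
    }
  }
  do.call(strategy_config, args)
}

#' Evaluate a configuration: traces, per-arm economics, ICER
#'
#' @param config A [cea_config()].
#' @param overrides Named list of scalar overrides keyed by dot paths into
#'   the config (e.g. `"arms.atezolizumab.drug_cost_per_cycle"`,
#'   `"utilities.u_pd"`, `"saes.anemia.cost"`,
#'   `"curves.chemotherapy.os.scale"`).
#' @return A list with elements `treatment` and `comparator`
#'   ([accumulate()] results) and `icer` ([icer()] result).
#' @export
run_cea <- function(config, overrides = list()) {
  stopifnot(inherits(config, "cea_config"))
  for (nm in names(overrides)) {
    config <- config_set(config, nm, overrides[[nm]])
  }
  utilities <- do.call(utility_set, config$utilities[c("u_pfs", "u_pd")])
  settings <- config$settings
  if (!inherits(settings, "model_settings")) {
    settings <- do.call(model_settings, settings)
  }
  eval_arm <- function(arm, role) {
    trace <- markov_trace(
      config$curves[[arm]]$pfs, config$curves[[arm]]$os, settings
    )
    accumulate(trace, build_arm(config, arm, role), utilities)
  }
  res_t <- eval_arm(config$treatment, "treatment")
  res_c <- eval_arm(config$comparator, "comparator")
  list(treatment = res_t, comparator = res_c, icer = icer(res_t, res_c))
}

#' Close over a configuration as a one-argument model function
#'
#' The returned closure maps a named list of parameter overrides to a
#' one-row tibble of incremental results — the shape the sensitivity-
#' analysis drivers consume.
#'
#' @param config A [cea_config()].
#' @return `function(overrides = list())` returning a tibble with columns
#'   `cost_treatment`, `cost_comparator`, `qaly_treatment`,
#'   `qaly_comparator`, `delta_cost`, `delta_qaly`, `icer`.
#' @export
cea_model <- function(config) {
  stopifnot(inherits(config, "cea_config"))
  force(config)
  function(overrides = list()) {
    res <- run_cea(config, overrides)
    tibble(
      cost_treatment = res$treatment$total_cost,
      cost_comparator = res$comparator$total_cost,
      qaly_treatment = res$treatment$total_qaly,
      qaly_comparator = res$comparator$total_qaly,
      delta_cost = res$icer$delta_cost,
      delta_qaly = res$icer$delta_qaly,
      icer = res$icer$icer
    )
  }
}

#' Write / read a configuration as JSON
#'
#' Full-precision JSON so a config round-trips exactly.
#'
#' @param config A [cea_config()].
#' @param path File path.
#' @return `read_cea_config()` returns the [cea_config()];
#'   `write_cea_config()` returns `path` invisibly.
#' @export
write_cea_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  ser <- config
  ser$curves <- lapply(config$curves, function(arm) {
    lapply(arm, function(d) list(family = d$family, params = as.list(d$params)))
  })
  ser$settings <- unclass(
    if (inherits(config$settings, "model_settings")) {
      config$settings
    } else {
      do.call(model_settings, config$settings)
    }
  )
  ser$utilities <- unclass(config$utilities)
  # JSON has no Inf; an uncapped treatment duration is encoded by absence
  ser$arms <- lapply(ser$arms, function(a) {
    if (!is.null(a$max_treatment_cycles) && !is.finite(a$max_treatment_cycles)) {
      a$max_treatment_cycles <- NULL
    }
    a
  })
  ser$pap <- if (is.null(config$pap)) NULL else unclass(config$pap)
  ser$saes <- if (is.null(config$saes)) NULL else as.list(config$saes)
  jsonlite::write_json(unclass(ser), path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_cea_config
#' @export
read_cea_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(raw$curves, function(arm) {
    lapply(arm, function(d) surv_dist(d$family, unlist(d$params)))
  })
  cea_config(
    treatment = raw$treatment, comparator = raw$comparator,
    curves = curves,
    arms = lapply(raw$arms, function(a) {
      a$max_treatment_cycles <- a$max_treatment_cycles %||% Inf
      a
    }),
    pap = if (is.null(raw$pap)) NULL else do.call(pap_schedule, raw$pap),
    saes = if (is.null(raw$saes)) NULL else as_tibble(raw$saes),
    utilities = do.call(utility_set, raw$utilities[c("u_pfs", "u_pd", "u_death")]),
    settings = do.call(model_settings, raw$settings),
    sae_threshold = raw$sae_threshold, wtp = raw$wtp,
    synthetic = raw$synthetic
  )
}
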