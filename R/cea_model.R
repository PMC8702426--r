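# Model-input configuration: a YAML schema mirroring the published input
# table (per-cycle drug costs, adverse-event risks/costs/disutilities,
# utilities, ranges and distribution families), strategy definitions, and
# the scenario variant. This file also builds the flat parameter table
# driving the deterministic and probabilistic sensitivity analyses, and
# the closure that re-evaluates the incremental result for any parameter
# assignment.

#' Path of the packaged base-case configuration
#' @return File path of `config_default.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "config_default.yaml", package = "oncocea",
              mustWork = TRUE)
}

#' Read and validate a model configuration
#'
#' @param path YAML file path (default: the packaged base case).
#' @return The configuration as a named list, class `cea_config`.
#' @export
read_cea_config <- function(path = default_config_path()) {
  cfg <- yaml::read_yaml(path)
  required <- c("drugs", "other_costs", "ae_costs", "ae_risks",
                "utilities", "disutilities", "discount", "model",
                "strategies", "trial")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L)
    stop("configuration is missing field(s): ", paste(missing, collapse = ", "))
  for (s in c("experimental", "control")) {
    if (is.null(cfg$strategies[[s]]))
      stop(sprintf("configuration is missing strategies$%s", s))
    mix <- cfg$strategies[[s]]$subsequent_mix
    if (abs(sum(unlist(mix)) - 1) > 1e-6)
      stop(sprintf("strategies$%s$subsequent_mix weights must sum to 1", s))
  }
  class(cfg) <- c("cea_config", "list")
  cfg
}

#' Flat parameter table for sensitivity analyses
#'
#' One row per uncertain input with its base value, low/high range and
#' distribution tag: Gamma for costs, Beta for risks, utilities and
#' disutilities, and the discount rate fixed in the PSA (its 0-0.08 range
#' is exercised only in the deterministic analysis).
#'
#' @param config a `cea_config`.
#' @return Data frame with columns `name`, `base`, `low`, `high`, `dist`.
#' @export
cea_parameters <- function(config) {
  rows <- list()
  add <- function(name, x, dist) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, base = x$base, low = x$low, high = x$high, dist = dist)
  }
  for (d in names(config$drugs))
    add(paste0("cost_", d), config$drugs[[d]], "gamma")
  for (d in names(config$other_costs))
    add(paste0("cost_", d), config$other_costs[[d]], "gamma")
  for (d in names(config$ae_costs))
    add(paste0("cost_ae_", d), config$ae_costs[[d]], "gamma")
  for (arm in names(config$ae_risks))
    for (d in names(config$ae_risks[[arm]]))
      add(paste0("risk_", d, "_", arm), config$ae_risks[[arm]][[d]], "beta")
  for (d in names(config$utilities))
    add(paste0("utility_", d), config$utilities[[d]], "beta")
  for (d in names(config$disutilities))
    add(paste0("disutility_", d), config$disutilities[[d]], "beta")
  add("discount_rate", config$discount, "fixed")
  out <- do.call(rbind, rows)
  if (any(out$low > out$base | out$base > out$high))
    stop("parameter table violates low <= base <= high")
  out
}

# Resolve the effective value of a named parameter under overrides.
.pval <- function(values, name, base) {
  if (!is.null(values[[name]])) values[[name]] else base
}

#' Build the two strategy objects from a configuration
#'
#' Drug, adverse-event and subsequent-therapy inputs are assembled from
#' the named parameter values (base case by default); per-cycle
#' subsequent-therapy cost is the configured mixture of drug costs, so an
#' override of e.g. `cost_camrelizumab` propagates into the control arm's
#' second line.
#'
#' @param config a `cea_config`.
#' @param values optional named list of parameter overrides (names as in
#'   [cea_parameters]).
#' @param scenario logical: use the crossover-adjusted scenario's control
#'   subsequent mix (no PD-1/PD-L1 antibodies in second line).
#' @return List with `experimental` and `control` [strategy] objects.
#' @export
build_strategies <- function(config, values = list(), scenario = FALSE) {
  drug_cost <- function(d)
    .pval(values, paste0("cost_", d), config$drugs[[d]]$base)
  mk <- function(role) {
    sdef <- config$strategies[[role]]
    mix <- sdef$subsequent_mix
    if (scenario && role == "control" &&
        !is.null(config$scenario$control_subsequent_mix))
      mix <- config$scenario$control_subsequent_mix
    sub_cost <- sum(vapply(names(mix), function(d)
      mix[[d]] * drug_cost(d), numeric(1)))
    ae <- do.call(rbind, lapply(names(config$ae_risks[[role]]), function(a)
      data.frame(
        name = a,
        risk = .pval(values, paste0("risk_", a, "_", role),
                     config$ae_risks[[role]][[a]]$base),
        cost = .pval(values, paste0("cost_ae_", a),
                     config$ae_costs[[a]]$base),
        disutility = .pval(values, paste0("disutility_", a),
                           config$disutilities[[a]]$base))))
    strategy(
      name = sdef$name,
      induction_cost = sum(vapply(sdef$induction_drugs, drug_cost,
                                  numeric(1))),
      induction_cycles = sdef$induction_cycles,
      maintenance_cost = sum(vapply(sdef$maintenance_drugs, drug_cost,
                                    numeric(1))),
      max_treatment_cycles = sdef$max_treatment_cycles,
      ae = ae,
      subsequent_fraction = sdef$subsequent_fraction,
      subsequent_cost = sub_cost,
      subsequent_max_cycles = sdef$subsequent_max_cycles,
      tot_ratio = sdef$tot_ratio)
  }
  list(experimental = mk("experimental"), control = mk("control"))
}

#' Model configuration object from the YAML configuration
#' @param config a `cea_config`.
#' @param values optional named overrides (recognizes `discount_rate`).
#' @return A [model_config].
#' @export
build_model_config <- function(config, values = list()) {
  m <- config$model
  model_config(cycle_length_weeks = m$cycle_length_weeks,
               discount_annual = .pval(values, "discount_rate",
                                       config$discount$base),
               horizon_cycles = m$horizon_cycles, wtp = m$wtp,
               stop_threshold = m$stop_threshold)
}

#' Incremental-result evaluator for sensitivity analyses
#'
#' Returns a closure mapping a named list of parameter values to the
#' incremental result (experimental minus control). The Markov traces
#' depend only on the fitted survival curves, so they are computed once
#' and reused; each call re-accrues costs and health outcomes under the
#' assigned parameter values. This makes a 1,000-draw PSA a matter of
#' seconds.
#'
#' @param config a `cea_config`.
#' @param fits list with `experimental` and `control` elements, each a
#'   list with `pfs` and `os` `surv_fit` objects.
#' @param scenario logical, passed to [build_strategies].
#' @return Function `(values) -> incremental_result`. The function also
#'   returns full [evaluate_strategy]-style outcomes via attribute
#'   `"outcomes"` on its result.
#' @export
make_cea_evaluator <- function(config, fits, scenario = FALSE) {
  base_cfg <- build_model_config(config)
  traces <- lapply(c(experimental = "experimental", control = "control"),
                   function(arm) {
    sched <- build_transition_schedule(fits[[arm]]$pfs, fits[[arm]]$os,
                                       base_cfg)
    run_trace(sched, base_cfg)
  })
  function(values = list()) {
    values <- as.list(values)
    cfg <- build_model_config(config, values)
    strats <- build_strategies(config, values, scenario = scenario)
    u_pfs <- .pval(values, "utility_pfs", config$utilities$pfs$base)
    u_pd <- .pval(values, "utility_pd", config$utilities$pd$base)
    fu <- .pval(values, "cost_followup", config$other_costs$followup$base)
    sup <- .pval(values, "cost_supportive",
                 config$other_costs$supportive$base)
    pal <- .pval(values, "cost_palliative",
                 config$other_costs$palliative$base)
    out <- lapply(c(experimental = "experimental", control = "control"),
                  function(arm) {
      trace <- traces[[arm]]
      costs <- accrue_costs(trace, strats[[arm]], cfg, followup_cost = fu,
                            supportive_cost = sup, palliative_cost = pal)
      health <- accrue_health(trace, u_pfs, u_pd, ae = strats[[arm]]$ae,
                              cfg = cfg)
      structure(list(strategy = strats[[arm]]$name, cost = costs$total,
                     ly = health$ly, qaly = health$qaly,
                     cost_undiscounted = costs$total_undiscounted,
                     ly_undiscounted = health$ly_undiscounted,
                     qaly_undiscounted = health$qaly_undiscounted,
                     components = costs$components, trace = trace),
                class = "econ_outcome")
    })
    res <- incremental(out$experimental, out$control)
    attr(res, "outcomes") <- out
    res
  }
}

#' Deterministic sensitivity specs from the parameter table
#'
#' @param config a `cea_config`.
#' @return Data frame with `name`, `base`, `low`, `high` (all parameters,
#'   including the discount rate) for [one_way_dsa].
#' @export
dsa_specs <- function(config) {
  p <- cea_parameters(config)
  p[, c("name", "base", "low", "high")]
}
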