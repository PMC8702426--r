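# Three-state (progression-free, progressed, dead) Markov cohort model on
# 3-week cycles. Death hazards come from the fitted OS curve and apply
# identically from both alive states; progression hazards are the excess
# of PFS-exit over death. Costs and QALYs are accrued per cycle from
# start-of-cycle occupancy (no half-cycle correction by default) and
# discounted at an annual rate.

#' Model configuration
#'
#' @param cycle_length_weeks cycle length in weeks (default 3).
#' @param discount_annual annual discount rate for costs and health
#'   outcomes (default 0.05; deterministic sensitivity range 0-0.08).
#' @param horizon_cycles maximum number of cycles (default 520, i.e. 30
#'   years of 3-week cycles: a lifetime horizon).
#' @param wtp willingness-to-pay threshold in $/QALY (default 31500,
#'   triple Chinese per-capita GDP).
#' @param stop_threshold trace truncation: stop once the alive fraction
#'   falls below this (default 1e-4).
#' @param weeks_per_year calendar constant for discounting (365.25/7).
#' @param half_cycle logical, apply a half-cycle correction (default
#'   `FALSE`; exposed as a switch).
#' @return Object of class `model_config`.
#' @export
model_config <- function(cycle_length_weeks = 3, discount_annual = 0.05,
                         horizon_cycles = 520, wtp = 31500,
                         stop_threshold = 1e-4,
                         weeks_per_year = WEEKS_PER_YEAR,
                         half_cycle = FALSE) {
  if (discount_annual < 0) stop("discount rate must be >= 0")
  if (horizon_cycles < 1) stop("horizon must be at least one cycle")
  if (cycle_length_weeks <= 0) stop("cycle length must be positive")
  structure(list(cycle_length_weeks = cycle_length_weeks,
                 discount_annual = discount_annual,
                 horizon_cycles = as.integer(horizon_cycles), wtp = wtp,
                 stop_threshold = stop_threshold,
                 weeks_per_year = weeks_per_year, half_cycle = half_cycle),
            class = "model_config")
}

#' Per-cycle discount factors
#' @param cfg a [model_config].
#' @param k cycle indices (0-based).
#' @return `d(k) = (1 + r)^(-k * delta / weeks_per_year)`.
#' @export
discount_factor <- function(cfg, k) {
  (1 + cfg$discount_annual)^(-k * cfg$cycle_length_weeks / cfg$weeks_per_year)
}

#' Treatment strategy definition
#'
#' @param name strategy label.
#' @param induction_cost per-cycle drug cost during induction ($).
#' @param induction_cycles number of induction cycles (4-6; default 4).
#' @param maintenance_cost per-cycle drug cost during maintenance ($).
#' @param max_treatment_cycles cap on treated cycles (e.g. 35 cycles = 2
#'   years of 3-week cycles for camrelizumab; `Inf` for treat-to-progression).
#' @param ae data frame of adverse events with columns `name`, `risk`,
#'   `cost`, `disutility` (grade 3-4 events, applied once at model entry).
#' @param subsequent_fraction fraction of progressors receiving subsequent
#'   active therapy (0.58 camrelizumab arm / 0.70 chemotherapy arm).
#' @param subsequent_cost per-cycle cost of subsequent therapy ($).
#' @param subsequent_max_cycles cap on subsequent-therapy cycles (default 6).
#' @param tot_ratio ratio of median time on treatment to median PFS, used
#'   to scale drug cost to the fraction actually still on therapy.
#' @return Object of class `strategy`.
#' @export
strategy <- function(name, induction_cost, induction_cycles = 4,
                     maintenance_cost, max_treatment_cycles = Inf,
                     ae = data.frame(name = character(), risk = numeric(),
                                     cost = numeric(), disutility = numeric()),
                     subsequent_fraction, subsequent_cost,
                     subsequent_max_cycles = 6, tot_ratio = 1) {
  if (induction_cost < 0 || maintenance_cost < 0 || subsequent_cost < 0)
    stop("costs must be non-negative")
  if (subsequent_fraction < 0 || subsequent_fraction > 1)
    stop("subsequent_fraction must lie in [0, 1]")
  if (nrow(ae) && any(ae$risk < 0 | ae$risk > 1))
    stop("AE risks must lie in [0, 1]")
  structure(list(name = name, induction_cost = induction_cost,
                 induction_cycles = induction_cycles,
                 maintenance_cost = maintenance_cost,
                 max_treatment_cycles = max_treatment_cycles, ae = ae,
                 subsequent_fraction = subsequent_fraction,
                 subsequent_cost = subsequent_cost,
                 subsequent_max_cycles = subsequent_max_cycles,
                 tot_ratio = tot_ratio),
            class = "strategy")
}

#' Build the per-cycle transition schedule from fitted PFS and OS curves
#'
#' `p_death(k) = 1 - S_OS((k+1)D)/S_OS(kD)` applies from both alive
#' states; `p_progress(k) = max(0, p_exit_pfs(k) - p_death(k))` where
#' `p_exit_pfs` comes from the PFS curve the same way. If the fitted PFS
#' curve sits above the OS curve the excess is floored at zero with a
#' warning.
#'
#' @param pfs_fit,os_fit `surv_fit` objects.
#' @param cfg a [model_config].
#' @param n_cycles schedule length (default `cfg$horizon_cycles`).
#' @return Data frame with columns `cycle`, `p_death`, `p_progress`.
#' @export
build_transition_schedule <- function(pfs_fit, os_fit, cfg,
                                      n_cycles = cfg$horizon_cycles) {
  k <- 0:(n_cycles - 1L)
  delta <- cfg$cycle_length_weeks
  p_death <- cycle_transition_prob(os_fit, k, delta)
  p_exit <- cycle_transition_prob(pfs_fit, k, delta)
  raw <- p_exit - p_death
  if (any(raw < -1e-6))
    warning("fitted PFS exceeds OS over part of the horizon; progression floored at 0")
  data.frame(cycle = k, p_death = p_death, p_progress = pmax(0, raw))
}

#' Run the cohort trace
#'
#' The cohort starts fully progression-free. Per cycle k:
#' `PFS' = PFS*(1 - p_death - p_progress)`,
#' `PD' = PD*(1 - p_death) + PFS*p_progress`, death absorbs the rest.
#' Incident deaths and progressions during cycle k are recorded at cycle
#' k+1. The trace stops once the alive fraction drops below
#' `cfg$stop_threshold`.
#'
#' @param schedule data frame from [build_transition_schedule].
#' @param cfg a [model_config].
#' @return Object of class `markov_trace`: data frame with columns
#'   `cycle`, `pfs`, `pd`, `death`, `inc_death`, `inc_prog`.
#' @export
run_trace <- function(schedule, cfg) {
  if (nrow(schedule) < cfg$horizon_cycles)
    stop("schedule shorter than the model horizon")
  if (any(schedule$p_death < 0 | schedule$p_death > 1 |
            schedule$p_progress < 0 | schedule$p_progress > 1))
    stop("transition probabilities outside [0, 1]")
  K <- cfg$horizon_cycles
  pfs <- pd <- dead <- inc_d <- inc_p <- numeric(K + 1L)
  pfs[1L] <- 1
  last <- K
  for (k in seq_len(K)) {
    pd_k <- schedule$p_death[k]
    pp_k <- min(schedule$p_progress[k], 1 - pd_k)
    inc_d[k + 1L] <- (pfs[k] + pd[k]) * pd_k
    inc_p[k + 1L] <- pfs[k] * pp_k
    pfs[k + 1L] <- pfs[k] * (1 - pd_k - pp_k)
    pd[k + 1L] <- pd[k] * (1 - pd_k) + inc_p[k + 1L]
    dead[k + 1L] <- 1 - pfs[k + 1L] - pd[k + 1L]
    if (pfs[k + 1L] + pd[k + 1L] < cfg$stop_threshold) { last <- k; break }
  }
  idx <- seq_len(last + 1L)
  out <- data.frame(cycle = idx - 1L, pfs = pfs[idx], pd = pd[idx],
                    death = dead[idx], inc_death = inc_d[idx],
                    inc_prog = inc_p[idx],
                    p_death = c(schedule$p_death[seq_len(last)], NA))
  class(out) <- c("markov_trace", "data.frame")
  out
}

#' On-treatment fraction per cycle
#'
#' Scales the progression-free occupancy by the time-on-treatment to
#' median-PFS ratio to reflect early discontinuation, and zeroes it beyond
#' the treatment cap.
#'
#' @param pfs_occ vector of PFS occupancies indexed by cycle (0-based).
#' @param tot_ratio ratio in (0, 1]; values above 1 are clamped with a
#'   warning.
#' @param max_treatment_cycles treatment cap in cycles.
#' @return Vector of on-treatment fractions, never above `pfs_occ`.
#' @export
on_treatment_fraction <- function(pfs_occ, tot_ratio,
                                  max_treatment_cycles = Inf) {
  if (tot_ratio > 1) {
    warning("time-on-treatment ratio > 1 clamped to 1")
    tot_ratio <- 1
  }
  if (tot_ratio <= 0) stop("time-on-treatment ratio must be positive")
  k <- seq_along(pfs_occ) - 1L
  ifelse(k < max_treatment_cycles, tot_ratio * pfs_occ, 0)
}

# Occupancy of the "on subsequent therapy" slice of the PD state: new
# progressors receive active subsequent therapy for up to `cap` cycles,
# dying meanwhile at the same per-cycle death hazard as the rest of PD.
.subsequent_eligible <- function(trace, cap) {
  K <- nrow(trace)
  elig <- numeric(K)
  queue <- numeric(0)              # cohort sizes by entry recency
  for (k in seq_len(K)) {
    queue <- c(trace$inc_prog[k], queue)   # arrivals at cycle k-1 (0-based)
    if (length(queue) > cap) queue <- queue[seq_len(cap)]
    elig[k] <- sum(queue)
    pd_k <- trace$p_death[k]
    if (!is.na(pd_k)) queue <- queue * (1 - pd_k)
  }
  elig
}

#' Accrue discounted cost components over a trace
#'
#' Components per cycle k (discount factor `d(k)`, start-of-cycle
#' occupancy): drug cost = on-treatment fraction x (induction cost for
#' `k < induction_cycles`, else maintenance cost); AE management cost =
#' sum(risk x cost), once at cycle 0; routine follow-up = `followup_cost`
#' x alive fraction; subsequent therapy = fraction treated x per-cycle
#' cost x the PD occupancy still within its cycle cap; best supportive
#' care = `supportive_cost` x (1 - fraction treated) x PD occupancy;
#' palliative care = `palliative_cost` x incident deaths.
#'
#' @param trace a [run_trace] result.
#' @param strat a [strategy].
#' @param cfg a [model_config].
#' @param followup_cost,supportive_cost,palliative_cost unit costs ($;
#'   defaults are the base-case inputs 85.71 per cycle, 338.00 per cycle,
#'   2464.50 per death).
#' @return List with `total`, `total_undiscounted` and per-component
#'   breakdowns `components`, `components_undiscounted`.
#' @export
accrue_costs <- function(trace, strat, cfg, followup_cost = 85.71,
                         supportive_cost = 338.00,
                         palliative_cost = 2464.50) {
  if (any(trace$pfs < -1e-12 | trace$pd < -1e-12))
    stop("negative occupancy in trace")
  k <- trace$cycle
  d <- discount_factor(cfg, k)
  if (cfg$half_cycle) d <- d * discount_factor(cfg, 0.5)
  alive <- trace$pfs + trace$pd

  on_trt <- on_treatment_fraction(trace$pfs, strat$tot_ratio,
                                  strat$max_treatment_cycles)
  per_cycle_drug <- ifelse(k < strat$induction_cycles,
                           strat$induction_cost, strat$maintenance_cost)
  drug <- on_trt * per_cycle_drug
  ae <- numeric(length(k))
  ae[1L] <- sum(strat$ae$risk * strat$ae$cost)
  followup <- followup_cost * alive
  elig <- .subsequent_eligible(trace, strat$subsequent_max_cycles)
  subsequent <- strat$subsequent_fraction * strat$subsequent_cost * elig
  supportive <- supportive_cost * (1 - strat$subsequent_fraction) * trace$pd
  palliative <- palliative_cost * trace$inc_death

  comp <- function(w) c(drug = sum(drug * w), ae = sum(ae * w),
                        followup = sum(followup * w),
                        supportive = sum(supportive * w),
                        subsequent = sum(subsequent * w),
                        palliative = sum(palliative * w))
  disc <- comp(d); undisc <- comp(rep(1, length(k)))
  list(total = sum(disc), total_undiscounted = sum(undisc),
       components = disc, components_undiscounted = undisc)
}

#' Accrue discounted life-years and QALYs over a trace
#'
#' Per cycle, `LY += alive x delta/weeks_per_year x d(k)` and
#' `QALY += (PFS x u_pfs + PD x u_pd) x delta/weeks_per_year x d(k)`;
#' adverse-event disutility (sum of risk x disutility) is charged for one
#' cycle's duration at model entry.
#'
#' @param trace a [run_trace] result.
#' @param u_pfs,u_pd health-state utilities in `[0, 1]` (base case 0.81
#'   stable disease, 0.58 progressed disease).
#' @param ae data frame with `risk` and `disutility` columns (may be empty).
#' @param cfg a [model_config].
#' @return List with `ly`, `qaly`, `ly_undiscounted`, `qaly_undiscounted`.
#' @export
accrue_health <- function(trace, u_pfs, u_pd, ae = NULL, cfg) {
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1)
    stop("utilities must lie in [0, 1]")
  k <- trace$cycle
  d <- discount_factor(cfg, k)
  if (cfg$half_cycle) d <- d * discount_factor(cfg, 0.5)
  yrs <- cfg$cycle_length_weeks / cfg$weeks_per_year
  alive <- trace$pfs + trace$pd
  q_cycle <- (trace$pfs * u_pfs + trace$pd * u_pd) * yrs
  ae_dis <- if (is.null(ae) || nrow(ae) == 0L) 0 else
    sum(ae$risk * ae$disutility) * yrs
  list(ly = sum(alive * yrs * d),
       qaly = sum(q_cycle * d) - ae_dis * d[1L],
       ly_undiscounted = sum(alive * yrs),
       qaly_undiscounted = sum(q_cycle) - ae_dis)
}

#' Evaluate one strategy end to end
#'
#' Composes schedule, trace, cost accrual and health accrual; fully
#' deterministic given its inputs.
#'
#' @param strat a [strategy].
#' @param pfs_fit,os_fit fitted survival curves (`surv_fit`).
#' @param cfg a [model_config].
#' @param u_pfs,u_pd health-state utilities.
#' @param followup_cost,supportive_cost,palliative_cost unit costs passed
#'   to [accrue_costs].
#' @return Object of class `econ_outcome`: list with `strategy`, `cost`,
#'   `ly`, `qaly`, undiscounted counterparts, `components`, and the
#'   `trace`.
#' @export
evaluate_strategy <- function(strat, pfs_fit, os_fit, cfg,
                              u_pfs = 0.81, u_pd = 0.58,
                              followup_cost = 85.71,
                              supportive_cost = 338.00,
                              palliative_cost = 2464.50) {
  sched <- build_transition_schedule(pfs_fit, os_fit, cfg)
  trace <- run_trace(sched, cfg)
  costs <- accrue_costs(trace, strat, cfg, followup_cost = followup_cost,
                        supportive_cost = supportive_cost,
                        palliative_cost = palliative_cost)
  health <- accrue_health(trace, u_pfs, u_pd, ae = strat$ae, cfg = cfg)
  structure(list(strategy = strat$name, cost = costs$total,
                 ly = health$ly, qaly = health$qaly,
                 cost_undiscounted = costs$total_undiscounted,
                 ly_undiscounted = health$ly_undiscounted,
                 qaly_undiscounted = health$qaly_undiscounted,
                 components = costs$components, trace = trace),
            class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf("%s: cost $%.0f | %.3f LY | %.3f QALY (discounted)\n",
              x$strategy, x$cost, x$ly, x$qaly))
  invisible(x)
}

#' Write a Markov trace to CSV
#' @param trace a `markov_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
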