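cfg0 <- model_config()          # base case: 3-week cycles, 5%, 520 cycles
cfg_nodisc <- model_config(discount_annual = 0)

flat_strategy <- function(...) {
  defaults <- list(name = "s", induction_cost = 0, maintenance_cost = 0,
                   subsequent_fraction = 0, subsequent_cost = 0,
                   tot_ratio = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(strategy, args)
}

test_that("transition schedules follow the closed forms", {
  os0 <- surv_fit("exponential", c(rate = 0))
  pfs0 <- surv_fit("exponential", c(rate = 0.05))
  sch <- build_transition_schedule(pfs0, os0, cfg0, n_cycles = 50)
  expect_true(all(sch$p_death == 0))

  # identical PFS and OS curves: nobody progresses
  sch2 <- build_transition_schedule(pfs0, pfs0, cfg0, n_cycles = 50)
  expect_true(all(sch2$p_progress == 0))

  pfs <- surv_fit("exponential", c(rate = 0.05))
  os <- surv_fit("exponential", c(rate = 0.02))
  sch3 <- build_transition_schedule(pfs, os, cfg0, n_cycles = 10)
  expect_equal(sch3$p_death, rep(1 - exp(-0.06), 10))
  expect_equal(sch3$p_progress, rep(exp(-0.06) - exp(-0.15), 10))

  # PFS above OS: floored with a warning
  expect_warning(
    build_transition_schedule(surv_fit("exponential", c(rate = 0.01)),
                              surv_fit("exponential", c(rate = 0.10)),
                              cfg0, n_cycles = 5),
    "floored")
})

test_that("the cohort trace obeys conservation and absorption", {
  zero <- data.frame(cycle = 0:519, p_death = 0, p_progress = 0)
  tr <- run_trace(zero, cfg0)
  expect_true(all(tr$pfs == 1))
  expect_true(all(tr$pd == 0))

  kill <- data.frame(cycle = 0:519, p_death = c(1, rep(0, 519)),
                     p_progress = 0)
  tr2 <- run_trace(kill, cfg0)
  expect_equal(nrow(tr2), 2)                # truncated once extinct
  expect_equal(unlist(tr2[2, c("pfs", "pd", "death")]),
               c(pfs = 0, pd = 0, death = 1))
  expect_equal(tr2$inc_death[2], 1)

  sch <- suppressWarnings(build_transition_schedule(
    surv_fit("weibull", c(scale = 50, shape = 1.3)),
    surv_fit("weibull", c(scale = 80, shape = 0.9)), cfg0))
  tr3 <- run_trace(sch, cfg0)
  expect_true(all(abs(tr3$pfs + tr3$pd + tr3$death - 1) < 1e-12))
  expect_true(all(diff(tr3$death) >= -1e-15))
  expect_true(all(tr3$pfs >= 0 & tr3$pd >= 0))

  # telescoping: alive fraction equals the survival product
  K <- nrow(tr3) - 1
  alive <- tr3$pfs + tr3$pd
  expect_equal(alive[K + 1], prod(1 - sch$p_death[1:K]), tolerance = 1e-10)
})

test_that("cohort trace agrees with a 100,000-subject microsimulation", {
  sch <- build_transition_schedule(
    surv_fit("exponential", c(rate = 0.04)),
    surv_fit("exponential", c(rate = 0.02)), cfg0, n_cycles = 120)
  cfg <- model_config(horizon_cycles = 120, stop_threshold = 0)
  tr <- run_trace(sch, cfg)
  ms <- microsim_trace(sch, n_cycles = 120, n_subj = 100000L, seed = 31)
  occ <- as.matrix(tr[, c("pfs", "pd", "death")])
  expect_lt(max(abs(occ - ms[seq_len(nrow(occ)), ])), 0.005)
})

test_that("on-treatment fraction scales, caps and clamps", {
  occ <- c(1, 0.8, 0.5, 0.2)
  expect_equal(on_treatment_fraction(occ, 1), occ)
  expect_equal(on_treatment_fraction(occ, 0.8)[3], 0.4)
  expect_equal(on_treatment_fraction(occ, 0.8, max_treatment_cycles = 2),
               c(0.8, 0.64, 0, 0))
  expect_warning(f <- on_treatment_fraction(occ, 1.3), "clamped")
  expect_equal(f, occ)
})

test_that("single-cycle extinction cost equals the hand sum of base-case inputs", {
  kill <- data.frame(cycle = 0:519, p_death = c(1, rep(0, 519)),
                     p_progress = 0)
  tr <- run_trace(kill, cfg_nodisc)
  ae <- data.frame(name = c("neutropenia", "anemia", "thrombocytopenia"),
                   risk = c(0.38, 0.19, 0.17),
                   cost = c(175.37, 101.02, 603.79),
                   disutility = c(0.20, 0.07, 0.11))
  strat <- flat_strategy(induction_cost = 1573.03, maintenance_cost = 1555.38,
                         ae = ae)
  costs <- accrue_costs(tr, strat, cfg_nodisc)
  hand <- 1573.03 +                                  # cycle-0 drug
    (0.38 * 175.37 + 0.19 * 101.02 + 0.17 * 603.79) +  # AE one-off
    85.71 +                                          # follow-up, alive = 1
    2464.50                                          # palliative death
  expect_equal(costs$total, hand, tolerance = 1e-10)
  expect_equal(sum(costs$components), costs$total, tolerance = 1e-8)

  # zero-cost strategy: zero total
  none <- flat_strategy()
  expect_equal(accrue_costs(tr, none, cfg_nodisc,
                            followup_cost = 0, supportive_cost = 0,
                            palliative_cost = 0)$total, 0)
})

test_that("cost accrual matches a spreadsheet-style hand oracle", {
  # constant-occupancy synthetic trace, 10 cycles
  tr <- data.frame(cycle = 0:9, pfs = 0.5, pd = 0.3, death = 0.2,
                   inc_death = c(0, rep(0.02, 9)),
                   inc_prog = c(0, rep(0.04, 9)),
                   p_death = c(rep(0, 9), NA))
  strat <- flat_strategy(induction_cost = 1000, induction_cycles = 4,
                         maintenance_cost = 600,
                         subsequent_fraction = 0.7, subsequent_cost = 500,
                         subsequent_max_cycles = 6, tot_ratio = 0.8)
  cfg <- model_config(discount_annual = 0.05)
  d <- (1.05)^(-(0:9) * 3 / (365.25 / 7))
  drug <- 0.8 * 0.5 * c(rep(1000, 4), rep(600, 6))
  followup <- 85.71 * 0.8
  # subsequent-eligible slice: cumulative arrivals, capped at 6 entries,
  # no deaths in this trace
  elig <- c(0, cumsum(rep(0.04, 9)))[1:10]
  elig <- pmin(elig, 6 * 0.04)
  subsq <- 0.7 * 500 * elig
  supp <- 338 * (1 - 0.7) * 0.3
  pall <- 2464.50 * c(0, rep(0.02, 9))
  hand <- sum((drug + followup + subsq + supp + pall) * d)
  got <- accrue_costs(tr, strat, cfg)
  expect_equal(got$total, hand, tolerance = 1e-8)
  expect_true(all(got$components >= 0))
})

test_that("health accrual matches identities and the hand oracle", {
  tr <- data.frame(cycle = 0:9, pfs = 0.5, pd = 0.3, death = 0.2,
                   inc_death = c(0, rep(0.02, 9)),
                   inc_prog = c(0, rep(0.04, 9)),
                   p_death = c(rep(0, 9), NA))
  # utilities 1, no AE, no discounting: QALY equals LY
  h <- accrue_health(tr, 1, 1, ae = NULL, cfg = cfg_nodisc)
  expect_equal(h$qaly, h$ly, tolerance = 1e-12)

  # hand oracle with discounting and AE disutility
  ae <- data.frame(risk = c(0.38, 0.19), disutility = c(0.20, 0.07))
  cfg <- model_config(discount_annual = 0.05)
  d <- (1.05)^(-(0:9) * 3 / (365.25 / 7))
  yrs <- 3 / (365.25 / 7)
  hand_q <- sum((0.5 * 0.81 + 0.3 * 0.58) * yrs * d) -
    (0.38 * 0.20 + 0.19 * 0.07) * yrs
  h2 <- accrue_health(tr, 0.81, 0.58, ae = ae, cfg = cfg)
  expect_equal(h2$qaly, hand_q, tolerance = 1e-8)
  expect_equal(h2$ly, sum(0.8 * yrs * d), tolerance = 1e-8)
  expect_lte(h2$qaly, h2$ly)

  # extinction after cycle 0: only the first cycle contributes
  kill <- data.frame(cycle = 0:1, pfs = c(1, 0), pd = c(0, 0),
                     death = c(0, 1), inc_death = c(0, 1),
                     inc_prog = c(0, 0), p_death = c(1, NA))
  h3 <- accrue_health(kill, 1, 1, cfg = cfg_nodisc)
  expect_equal(h3$ly, yrs)

  expect_error(accrue_health(tr, 1.2, 0.5, cfg = cfg0), "\\[0, 1\\]")
})

test_that("discounting identities hold end to end", {
  pfs <- surv_fit("weibull", c(scale = 45, shape = 1.5))
  os <- surv_fit("weibull", c(scale = 70, shape = 0.9))
  strat <- flat_strategy(induction_cost = 1200, maintenance_cost = 900,
                         subsequent_fraction = 0.6, subsequent_cost = 400)
  ev <- function(...) suppressWarnings(evaluate_strategy(...))
  r0 <- ev(strat, pfs, os, cfg_nodisc)
  expect_equal(r0$cost, r0$cost_undiscounted)
  expect_equal(r0$qaly, r0$qaly_undiscounted)

  r5 <- ev(strat, pfs, os, model_config())
  r10 <- ev(strat, pfs, os, model_config(discount_annual = 0.10))
  expect_lt(r10$cost, r5$cost)
  expect_lt(r10$qaly, r5$qaly)
  expect_lt(r10$ly, r5$ly)
  expect_lt(r5$cost, r0$cost)
  expect_lte(r5$qaly, r5$ly)
  expect_equal(discount_factor(model_config(), 0), 1)
})
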