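# Independent oracles used across the suite. These deliberately use
# brute-force formulations (explicit products, per-event-time tables,
# grid searches, microsimulation) so they stay independent of the code
# paths they check.

# Hand-rolled product-limit estimator evaluated at arbitrary times.
km_oracle <- function(time, event, t_eval) {
  dt <- sort(unique(time[event == 1]))
  d <- vapply(dt, function(s) sum(time == s & event == 1), numeric(1))
  n_at <- vapply(dt, function(s) sum(time >= s), numeric(1))
  vapply(t_eval, function(tt) {
    keep <- dt <= tt
    if (!any(keep)) 1 else prod(1 - d[keep] / n_at[keep])
  }, numeric(1))
}

# Brute-force signed log-rank statistic: one 2x2 table per event time.
logrank_oracle <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ee <- c(e1, e2)
  dt <- sort(unique(tt[ee == 1]))
  O1 <- E1 <- V1 <- 0
  for (s in dt) {
    n1 <- sum(t1 >= s); n2 <- sum(t2 >= s); n <- n1 + n2
    d1 <- sum(t1 == s & e1 == 1)
    d <- d1 + sum(t2 == s & e2 == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V1 <- V1 + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (E1 - O1) / sqrt(V1)
}

# Grid maximization of the (no-ties) Cox partial log-likelihood for a
# single binary covariate.
cox_grid_oracle <- function(time, event, z, grid = seq(-3, 3, by = 1e-3)) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  ll <- vapply(grid, function(b) {
    eta <- exp(b * z)
    rs <- rev(cumsum(rev(eta)))       # risk-set sums at each ordered time
    sum((b * z - log(rs))[event == 1])
  }, numeric(1))
  grid[which.max(ll)]
}

# Individual-level microsimulation of the three-state model under a
# per-cycle (p_death, p_progress) schedule; returns occupancy by cycle.
microsim_trace <- function(schedule, n_cycles, n_subj = 100000L, seed = 1L) {
  set.seed(seed)
  state <- rep(1L, n_subj)            # 1 = PFS, 2 = PD, 3 = dead
  occ <- matrix(0, n_cycles + 1L, 3L)
  occ[1L, ] <- c(1, 0, 0)
  for (k in seq_len(n_cycles)) {
    u <- stats::runif(n_subj)
    pd <- schedule$p_death[k]
    pp <- schedule$p_progress[k]
    from_pfs <- state == 1L
    from_pd <- state == 2L
    state[from_pfs & u < pd] <- 3L
    state[from_pfs & u >= pd & u < pd + pp] <- 2L
    state[from_pd & u < pd] <- 3L
    occ[k + 1L, ] <- c(mean(state == 1L), mean(state == 2L),
                       mean(state == 3L))
  }
  occ
}

# Coherent one-parameter RPSFT world with exponential baselines: the
# experimental arm is on therapy from randomization (all its time scaled
# by exp(-psi)); control switchers have post-progression time scaled by
# exp(-psi). Used for psi-recovery checks.
rpsft_world <- function(n_per_arm, psi, rate_os = 0.05, rate_pfs = 0.10,
                        switch_prob = 0.46, censor = 104, seed = 1L) {
  trial_scenario(
    n_per_arm = n_per_arm,
    pfs = list(experimental = c(scale = exp(-psi) / rate_pfs, shape = 1),
               control = c(scale = 1 / rate_pfs, shape = 1)),
    os = list(experimental = c(scale = exp(-psi) / rate_os, shape = 1),
              control = c(scale = 1 / rate_os, shape = 1)),
    censor_range = c(censor, censor + 1e-9),
    switch_prob = switch_prob, psi = psi, seed = seed)
}
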