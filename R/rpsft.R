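# Rank-preserving structural failure time (RPSFT) adjustment for
# within-trial treatment switching. The one-parameter model writes a
# subject's counterfactual (never-treated) time as
#   U(psi) = T_off + exp(psi) * T_on,
# with psi the log time-acceleration attributable to the experimental
# therapy; psi is estimated by g-estimation, i.e. by finding the psi at
# which a rank (log-rank) test between the randomized arms on the
# counterfactual scale is zero. Recensoring at D*(psi) = min(C, C*exp(psi))
# keeps counterfactual censoring independent of the switching process.

#' Switch records: time, exposure and censoring per subject
#'
#' @param arm character, `"experimental"` or `"control"`.
#' @param time total observed time T in weeks.
#' @param time_on time spent on the experimental therapy after switching
#'   (0 for never-switchers; kept 0 for experimental-arm records — their
#'   exposure from randomization is handled internally by the estimator).
#' @param event 0/1 event indicator.
#' @param censor_time administrative censoring time C in weeks; records
#'   lacking one (`NA`) get the maximum observed time in their arm.
#' @return Object of class `switch_records` (a data frame).
#' @export
switch_records <- function(arm, time, time_on, event, censor_time = NA) {
  d <- data.frame(arm = as.character(arm), time = as.numeric(time),
                  time_on = as.numeric(time_on), event = as.integer(event),
                  censor_time = as.numeric(rep_len(censor_time, length(time))))
  if (!all(d$arm %in% c("experimental", "control")))
    stop("arm must be 'experimental' or 'control'")
  if (any(d$time <= 0)) stop("times must be positive")
  if (any(d$time_on < 0 | d$time_on > d$time + 1e-9))
    stop("time_on must satisfy 0 <= time_on <= time")
  if (any(d$time_on[d$arm == "experimental"] > 0))
    stop("experimental-arm records must carry time_on = 0")
  for (a in unique(d$arm)) {
    idx <- d$arm == a & is.na(d$censor_time)
    if (any(idx)) d$censor_time[idx] <- max(d$time[d$arm == a])
  }
  if (any(d$event == 0L & d$time > d$censor_time + 1e-9))
    stop("censored records must have time <= censor_time")
  class(d) <- c("switch_records", "data.frame")
  d
}

#' Counterfactual (treatment-free) time under the one-parameter model
#'
#' `U = (T - T_on) + exp(psi) * T_on`, recensored at
#' `D*(psi) = min(C, C * exp(psi))`: any record whose U exceeds D* becomes
#' censored at D*.
#'
#' @param rec a `switch_records` data frame (any subset of rows).
#' @param psi log acceleration factor.
#' @return Data frame with columns `time`, `event`, `recensored`.
#' @export
counterfactual_time <- function(rec, psi) {
  u <- (rec$time - rec$time_on) + exp(psi) * rec$time_on
  dstar <- pmin(rec$censor_time, rec$censor_time * exp(psi))
  over <- u > dstar
  data.frame(time = ifelse(over, dstar, u),
             event = ifelse(over, 0L, rec$event),
             recensored = over & rec$event == 1L)
}

#' Signed two-sample log-rank statistic
#'
#' Standard log-rank Z = (E1 - O1)/sqrt(V11) (via [survival::survdiff]),
#' signed so that Z > 0 when group 1 has fewer events than expected under
#' the null.
#'
#' @param time1,event1 times and 0/1 indicators of group 1.
#' @param time2,event2 times and 0/1 indicators of group 2.
#' @return The Z statistic.
#' @export
logrank_z <- function(time1, event1, time2, event2) {
  if (sum(event1) + sum(event2) == 0L) stop("no events: log-rank undefined")
  g <- factor(rep(c(1L, 2L), c(length(time1), length(time2))))
  sd <- survival::survdiff(
    survival::Surv(c(time1, time2), c(event1, event2)) ~ g)
  v <- if (is.matrix(sd$var)) sd$var[1L, 1L] else sd$var[1L]
  (sd$exp[1L] - sd$obs[1L]) / sqrt(v)
}

#' Estimate the RPSFT acceleration parameter by g-estimation
#'
#' Scans a grid of candidate psi values; at each, the control arm is
#' mapped to its counterfactual scale with [counterfactual_time] (with
#' recensoring), the experimental arm is treated as on-therapy from
#' randomization (`U = exp(psi) * T`, recensored) when
#' `test_arm_on = TRUE` (the default, the classic Robins-Tsiatis
#' formulation), and the signed log-rank Z between the arms is computed.
#' The estimate is the zero crossing of Z(psi), linearly interpolated
#' between the bracketing grid points. With `test_arm_on = FALSE` the
#' experimental arm is left at its observed times, which estimates the psi
#' equating the counterfactual control arm to the experimental arm rather
#' than to the common treatment-free baseline.
#'
#' @param records a [switch_records] object containing both arms.
#' @param grid candidate psi values (default `seq(-3, 1, by = 0.01)`).
#' @param test_arm_on logical; see Details.
#' @return Object of class `psi_estimate`: list with `psi`, `z` (log-rank
#'   Z at the estimate), `converged`, `grid`, `z_grid`, `n_crossings`.
#' @export
estimate_psi <- function(records, grid = seq(-3, 1, by = 0.01),
                         test_arm_on = TRUE) {
  stopifnot(inherits(records, "switch_records"))
  ctrl <- records[records$arm == "control", , drop = FALSE]
  expm <- records[records$arm == "experimental", , drop = FALSE]
  switchers <- ctrl$time_on > 0
  if (!any(switchers))
    stop("no switchers in the control arm: the RPSFT model is unidentified")

  z_at <- function(psi) {
    cc <- counterfactual_time(ctrl, psi)
    if (test_arm_on) {
      ee <- expm
      ee$time_on <- ee$time        # exposed from randomization
      ec <- counterfactual_time(ee, psi)
    } else {
      ec <- data.frame(time = expm$time, event = expm$event)
    }
    tryCatch(logrank_z(ec$time, ec$event, cc$time, cc$event),
             error = function(e) NA_real_)
  }
  zg <- vapply(grid, z_at, numeric(1))

  ok <- which(!is.na(zg[-length(zg)]) & !is.na(zg[-1L]) &
                zg[-length(zg)] * zg[-1L] <= 0 &
                !(zg[-length(zg)] == 0 & zg[-1L] == 0))
  if (length(ok) > 0L) {
    i <- ok[1L]
    z0 <- zg[i]; z1 <- zg[i + 1L]
    psi_hat <- if (z1 == z0) grid[i] else
      grid[i] + (0 - z0) * (grid[i + 1L] - grid[i]) / (z1 - z0)
    converged <- TRUE
  } else {
    psi_hat <- grid[which.min(abs(zg))]
    converged <- FALSE
  }
  structure(list(psi = psi_hat, z = z_at(psi_hat), converged = converged,
                 grid = range(grid), z_grid = zg, n_crossings = length(ok)),
            class = "psi_estimate")
}

#' @export
print.psi_estimate <- function(x, ...) {
  cat(sprintf("RPSFT psi estimate: %.4f (log-rank Z = %.3g, %s)\n",
              x$psi, x$z,
              if (x$converged) "sign change bracketed" else "NOT converged"))
  invisible(x)
}

#' Counterfactual control-arm pseudo-IPD at a given psi
#'
#' Convenience wrapper used by the scenario analysis: strips the crossover
#' effect from the control arm and returns it as a [pseudo_ipd].
#'
#' @param records a [switch_records] object.
#' @param psi log acceleration factor (typically from [estimate_psi]).
#' @param endpoint endpoint label for the output.
#' @return A [pseudo_ipd] of the counterfactual control arm.
#' @export
counterfactual_control_ipd <- function(records, psi, endpoint = "OS") {
  ctrl <- records[records$arm == "control", , drop = FALSE]
  cf <- counterfactual_time(ctrl, psi)
  pseudo_ipd(cf$time, cf$event, arm = "control", endpoint = endpoint)
}

#' Hazard ratio between two arms (Cox proportional hazards)
#'
#' Single binary covariate partial-likelihood fit via [survival::coxph]
#' (Newton-Raphson); the hazard ratio is experimental relative to control.
#'
#' @param experimental,control data frames with `time` and `event`
#'   (e.g. [pseudo_ipd] objects).
#' @return List with `hr`, `log_hr`, `se`.
#' @export
adjusted_hr <- function(experimental, control) {
  if (sum(experimental$event) == 0L || sum(control$event) == 0L)
    stop("each arm needs at least one event for a hazard ratio")
  d <- data.frame(
    time = c(experimental$time, control$time),
    event = c(experimental$event, control$event),
    z = rep(c(1L, 0L), c(nrow(experimental), nrow(control))))
  fit <- survival::coxph(survival::Surv(time, event) ~ z, data = d)
  b <- unname(stats::coef(fit))
  list(hr = exp(b), log_hr = b, se = sqrt(unname(stats::vcov(fit)[1L, 1L])))
}

#' Read switch records from CSV
#'
#' Columns: `arm`, `time`, `time_on_experimental`, `event`, `censor_time`.
#' @param path file path.
#' @return A [switch_records] object.
#' @export
read_switch_records <- function(path) {
  d <- utils::read.csv(path)
  switch_records(d$arm, d$time, d$time_on_experimental, d$event,
                 d$censor_time)
}

#' Write switch records to CSV
#' @param records a [switch_records] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_switch_records <- function(records, path) {
  out <- data.frame(arm = records$arm, time = records$time,
                    time_on_experimental = records$time_on,
                    event = records$event, censor_time = records$censor_time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
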