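# Pseudo individual-patient data (IPD) reconstruction from digitized
# Kaplan-Meier curves plus numbers-at-risk tables, and its validation by
# re-estimating the KM curve from the reconstructed records.

#' Digitized survival curve
#'
#' Container for coordinates read off a published Kaplan-Meier plot:
#' ordered `(time, survival)` pairs starting at `(0, 1)`.
#'
#' @param time numeric, strictly increasing times in weeks; the first must
#'   be 0.
#' @param survival numeric in `[0, 1]`, non-increasing; the first must be 1.
#' @param arm arm label, e.g. `"camrelizumab"` or `"chemotherapy"`.
#' @param endpoint endpoint label, `"PFS"` or `"OS"`.
#' @return An object of class `digitized_curve`: a data frame with columns
#'   `time` and `survival` and attributes `arm` and `endpoint`.
#' @export
digitized_curve <- function(time, survival, arm = "arm", endpoint = "OS") {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) < 1L)
    stop("time and survival must be non-empty vectors of equal length")
  if (any(diff(time) <= 0))
    stop("digitized times must be strictly increasing")
  if (time[1L] != 0 || survival[1L] != 1)
    stop("a digitized curve must start at (time = 0, survival = 1)")
  if (any(survival < 0 | survival > 1))
    stop("survival probabilities must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    stop("survival must be non-increasing (increasing curve rejected)")
  out <- data.frame(time = time, survival = survival)
  attr(out, "arm") <- arm
  attr(out, "endpoint") <- endpoint
  class(out) <- c("digitized_curve", "data.frame")
  out
}

#' Numbers-at-risk table
#'
#' @param time interval start times (weeks), strictly increasing, first 0.
#' @param n_risk number of patients still at risk at each start time;
#'   non-increasing, first entry is the initial cohort size.
#' @return An object of class `risk_table`.
#' @export
risk_table <- function(time, n_risk) {
  time <- as.numeric(time)
  n_risk <- as.integer(round(n_risk))
  if (length(time) != length(n_risk) || length(time) < 1L)
    stop("time and n_risk must be non-empty vectors of equal length")
  if (any(diff(time) <= 0)) stop("risk-table times must be strictly increasing")
  if (time[1L] != 0) stop("risk table must start at time 0")
  if (any(n_risk < 0)) stop("numbers at risk must be non-negative")
  if (any(diff(n_risk) > 0))
    stop("numbers at risk must be non-increasing (count exceeding a prior interval rejected)")
  out <- data.frame(time = time, n_risk = n_risk)
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Pseudo individual-patient data
#'
#' @param time event/censoring times in weeks, all positive.
#' @param event integer 0/1 event indicators.
#' @param arm,endpoint labels carried along for bookkeeping.
#' @return An object of class `pseudo_ipd`: a data frame with columns
#'   `time`, `event`, `arm`, `endpoint`.
#' @export
pseudo_ipd <- function(time, event, arm = "arm", endpoint = "OS") {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time <= 0)) stop("pseudo-IPD times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  out <- data.frame(time = time, event = event,
                    arm = rep_len(arm, length(time)),
                    endpoint = rep_len(endpoint, length(time)))
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Reconstruct pseudo-IPD from a digitized curve and risk table
#'
#' Interval-allocation algorithm in the spirit of Hoyle-style pseudo-IPD
#' generation: within each risk-table interval, events are allocated at the
#' digitized step times against the running risk set
#' (`d = round(m * (1 - S_i/S_prev))`), and the residual decline in the
#' numbers at risk is attributed to censoring, assumed uniform in time and
#' therefore interleaved with the event steps (the censoring total is
#' iterated until it reconciles with the risk-table decline). Any rounding
#' residue is absorbed in the final interval as censorings, so the output
#' always contains exactly `n` records.
#'
#' @param curve a [digitized_curve].
#' @param risk a [risk_table]; its intervals must cover the curve's span.
#' @return A [pseudo_ipd] with `risk$n_risk[1]` records.
#' @export
reconstruct_pseudo_ipd <- function(curve, risk) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(risk, "risk_table"))
  n <- risk$n_risk[1L]
  if (n < 1L) stop("initial cohort size must be at least 1")
  t_max <- max(curve$time, risk$time)
  starts <- risk$time
  ends <- c(risk$time[-1L], t_max)
  if (ends[length(ends)] <= starts[length(starts)])
    ends[length(ends)] <- starts[length(starts)] + 1e-8

  m <- n                       # running number at risk
  s_prev_global <- 1
  ev_t <- ev_n <- numeric(0)
  cn_t <- numeric(0)

  for (j in seq_along(starts)) {
    in_int <- which(curve$time > starts[j] & curve$time <= ends[j])
    width <- ends[j] - starts[j]
    target <- if (j < length(starts)) risk$n_risk[j + 1L] else 0L
    m0 <- m
    # Iterate the interval's censoring total so that censorings (assumed
    # uniform in time, hence interleaved with the digitized steps) and
    # step events jointly reconcile the risk-table decline.
    cj <- 0L
    for (iter in 1:3) {
      m <- m0
      s_prev <- s_prev_global
      d_vec <- integer(length(in_int))
      alloc <- 0L
      for (ii in seq_along(in_int)) {
        i <- in_int[ii]
        cum <- round(cj * (curve$time[i] - starts[j]) / width)
        cb <- min(max(cum - alloc, 0L), m)
        alloc <- alloc + cb
        m <- m - cb
        s_i <- curve$survival[i]
        d <- if (s_prev > 0) round(m * (1 - s_i / s_prev)) else 0
        d_vec[ii] <- max(0, min(m, d))
        m <- m - d_vec[ii]
        s_prev <- s_i
      }
      m <- m - (cj - alloc)      # tail censorings after the last step
      cj_new <- max(0L, m0 - sum(d_vec) - target)
      if (cj_new == cj) break
      cj <- cj_new
    }
    keep <- d_vec > 0
    ev_t <- c(ev_t, curve$time[in_int][keep])
    ev_n <- c(ev_n, d_vec[keep])
    if (cj > 0L)
      cn_t <- c(cn_t, starts[j] + (seq_len(cj) - 0.5) / cj * width)
    m <- m0 - sum(d_vec) - cj
    if (length(in_int) > 0L)
      s_prev_global <- curve$survival[in_int[length(in_int)]]
  }
  if (m > 0L) {               # conservation: censor any residue at the end
    cn_t <- c(cn_t, rep(t_max, m))
    m <- 0L
  }
  time <- c(rep(ev_t, ev_n), cn_t)
  event <- c(rep(1L, sum(ev_n)), rep(0L, length(cn_t)))
  time <- pmax(time, .Machine$double.eps)
  pseudo_ipd(time, event, arm = attr(curve, "arm"),
             endpoint = attr(curve, "endpoint"))
}

#' Kaplan-Meier estimate from pseudo-IPD
#'
#' Product-limit estimator (via [survival::survfit]) returned in a small
#' container that can be evaluated as a right-continuous step function.
#'
#' @param ipd a [pseudo_ipd] (or any data frame with `time` and `event`).
#' @return Object of class `km_curve` with elements `time`, `surv`
#'   (values *after* each distinct time), `n`.
#' @export
km_estimate <- function(ipd) {
  if (is.null(ipd) || nrow(ipd) == 0L) stop("no records: cannot estimate a KM curve")
  fit <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1,
                           conf.type = "none")
  out <- list(time = fit$time, surv = fit$surv, n = nrow(ipd))
  class(out) <- "km_curve"
  out
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km a `km_curve` from [km_estimate].
#' @param t times at which to evaluate; `S(t) = 1` before the first
#'   observed time.
#' @return numeric vector of survival probabilities.
#' @export
km_surv <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  if (length(km$time) == 0L) return(rep(1, length(t)))
  sf <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  sf(t)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "records,",
      length(x$time), "distinct times\n")
  invisible(x)
}

# ---- delimited readers / writers -------------------------------------------

#' Read a digitized curve from a CSV file
#'
#' Expects columns `time` and `survival`.
#' @param path file path.
#' @param arm,endpoint labels attached to the curve.
#' @return A [digitized_curve].
#' @export
read_digitized_curve <- function(path, arm = "arm", endpoint = "OS") {
  d <- utils::read.csv(path)
  digitized_curve(d$time, d$survival, arm = arm, endpoint = endpoint)
}

#' Read a numbers-at-risk table from a CSV file (columns `time`, `n_at_risk`)
#' @param path file path.
#' @return A [risk_table].
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  risk_table(d$time, d$n_at_risk)
}

#' Write pseudo-IPD to CSV (columns `time`, `event`, `arm`, `endpoint`)
#' @param ipd a [pseudo_ipd].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}

#' Read pseudo-IPD from CSV
#' @param path file path.
#' @return A [pseudo_ipd].
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  pseudo_ipd(d$time, d$event, arm = d$arm, endpoint = d$endpoint)
}
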