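# Incremental cost-effectiveness, one-way deterministic sensitivity
# analysis (tornado), probabilistic sensitivity analysis with Gamma/Beta
# draws, and cost-effectiveness acceptability curves.

#' Incremental cost-effectiveness between two strategies
#'
#' Differences are `a - b`. The result is labelled `"dominant"` when `a`
#' is no more costly and no less effective (and not identical),
#' `"dominated"` in the mirror case, `"equivalent"` when both differences
#' are zero, and `"icer"` otherwise, in which case
#' `ICER = delta_cost / delta_qaly`.
#'
#' @param a,b `econ_outcome` objects (or lists with `cost`, `ly`, `qaly`).
#' @return Object of class `incremental_result`: list with `d_cost`,
#'   `d_ly`, `d_qaly`, `icer`, `label`.
#' @export
incremental <- function(a, b) {
  d_cost <- a$cost - b$cost
  d_ly <- (a$ly %||% NA_real_) - (b$ly %||% NA_real_)
  d_qaly <- a$qaly - b$qaly
  label <- if (d_cost == 0 && d_qaly == 0) "equivalent"
  else if (d_cost <= 0 && d_qaly >= 0) "dominant"
  else if (d_cost >= 0 && d_qaly <= 0) "dominated"
  else "icer"
  icer <- if (label == "icer") d_cost / d_qaly else NA_real_
  structure(list(d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
                 icer = icer, label = label),
            class = "incremental_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("delta cost $%.0f | delta LY %.3f | delta QALY %.3f | %s\n",
              x$d_cost, x$d_ly, x$d_qaly,
              if (x$label == "icer") sprintf("ICER $%.0f/QALY", x$icer)
              else x$label))
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the model at the low and high bound of each parameter,
#' holding the others at base, and records the resulting ICERs, sorted by
#' the absolute ICER range (the tornado order). Evaluation failures are
#' flagged, not dropped.
#'
#' @param evaluator function taking a named list of parameter overrides
#'   and returning an [incremental] result.
#' @param specs data frame with columns `name`, `low`, `high` (and
#'   optionally `base`).
#' @return Data frame with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `range`, `failed`, in tornado order.
#' @export
one_way_dsa <- function(evaluator, specs) {
  if (is.null(specs) || nrow(specs) == 0L)
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), icer_low = numeric(),
                      icer_high = numeric(), range = numeric(),
                      failed = logical()))
  if (!is.null(specs$base) &&
      any(specs$low > specs$base | specs$base > specs$high))
    stop("each spec must satisfy low <= base <= high")
  eval_at <- function(nm, val) {
    tryCatch({
      inc <- evaluator(setNames(list(val), nm))
      list(icer = inc$icer, failed = FALSE)
    }, error = function(e) list(icer = NA_real_, failed = TRUE))
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- eval_at(specs$name[i], specs$low[i])
    hi <- eval_at(specs$name[i], specs$high[i])
    data.frame(parameter = specs$name[i], low = specs$low[i],
               high = specs$high[i], icer_low = lo$icer,
               icer_high = hi$icer,
               range = abs(hi$icer - lo$icer),
               failed = lo$failed || hi$failed)
  })
  out <- do.call(rbind, rows)
  out[order(-out$range, out$parameter, na.last = TRUE), , drop = FALSE]
}

# Moment-matched distribution draw used by the PSA. Printed ranges are
# treated as 95% intervals, so sd = (high - low)/3.92.
.psa_sd <- function(low, high) (high - low) / (2 * stats::qnorm(0.975))

#' Sample one probabilistic sensitivity analysis draw
#'
#' Gamma for costs and Beta for utilities/disutilities/risks, with
#' parameters moment-matched so that the distribution mean equals the base
#' value and the SD is `(high - low)/3.92`. Parameters tagged `"fixed"`
#' (and any with zero SD) stay at their base value.
#'
#' @param params data frame with columns `name`, `base`, `low`, `high`,
#'   `dist` (`"gamma"`, `"beta"` or `"fixed"`).
#' @return Named numeric vector, one value per parameter; uses the current
#'   RNG stream.
#' @export
sample_psa_draw <- function(params) {
  vals <- vapply(seq_len(nrow(params)), function(i) {
    m <- params$base[i]
    s <- .psa_sd(params$low[i], params$high[i])
    dist <- tolower(params$dist[i])
    if (dist == "fixed" || s == 0) return(m)
    if (dist == "gamma") {
      if (m <= 0) return(m)
      shape <- (m / s)^2
      stats::rgamma(1L, shape = shape, rate = shape / m)
    } else if (dist == "beta") {
      if (s^2 >= m * (1 - m))
        stop(sprintf("beta moment matching infeasible for '%s': sd too large for mean %.3g",
                     params$name[i], m))
      nu <- m * (1 - m) / s^2 - 1
      stats::rbeta(1L, shape1 = m * nu, shape2 = (1 - m) * nu)
    } else stop(sprintf("unknown distribution '%s' for '%s'",
                        params$dist[i], params$name[i]))
  }, numeric(1))
  setNames(vals, params$name)
}

#' Probabilistic sensitivity analysis with acceptability curve
#'
#' Draws `n_draws` parameter sets, evaluates the incremental result for
#' each, and summarizes cost-effectiveness acceptability:
#' `CEAC(lambda)` is the fraction of draws with positive net monetary
#' benefit `lambda * dQALY - dCost`. Failed draws are excluded and
#' counted.
#'
#' @param evaluator function taking a named list of parameter values and
#'   returning an [incremental] result; must be deterministic given a draw.
#' @param params parameter table as in [sample_psa_draw].
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param wtp_grid willingness-to-pay grid in $/QALY (default 0-100,000
#'   by 1,000).
#' @param seed optional integer seed for reproducibility.
#' @return List with `draws` (data frame: draw, d_cost, d_qaly, failed),
#'   `ceac` (data frame: wtp, prob_ce), `n_failed`.
#' @export
run_psa_ceac <- function(evaluator, params, n_draws = 1000,
                         wtp_grid = seq(0, 100000, by = 1000),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d_cost <- d_qaly <- rep(NA_real_, n_draws)
  failed <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    res <- tryCatch({
      draw <- sample_psa_draw(params)
      evaluator(as.list(draw))
    }, error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE
    else { d_cost[i] <- res$d_cost; d_qaly[i] <- res$d_qaly }
  }
  ok <- !failed
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_ce = vapply(wtp_grid, function(l)
      mean(l * d_qaly[ok] - d_cost[ok] > 0), numeric(1)))
  list(draws = data.frame(draw = seq_len(n_draws), d_cost = d_cost,
                          d_qaly = d_qaly, failed = failed),
       ceac = ceac, n_failed = sum(failed))
}

#' Willingness-to-pay at which the acceptability curve crosses one half
#'
#' @param ceac data frame with `wtp` and `prob_ce` (from [run_psa_ceac]).
#' @return The smallest grid value with `prob_ce >= 0.5`, or `NA` if the
#'   curve never reaches 0.5.
#' @export
ceac_crossing <- function(ceac) {
  i <- which(ceac$prob_ce >= 0.5)
  if (length(i) == 0L) NA_real_ else ceac$wtp[min(i)]
}
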