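# Staged, configuration-driven pipeline: simulate (or ingest) digitized
# curves -> reconstruct pseudo-IPD -> fit parametric curves -> RPSFT
# crossover adjustment -> Markov + economic analysis -> report tables.
# Every stage writes plain-text artifacts into the output directory and
# later stages consume them from there, so partial re-runs work; a
# manifest records the configuration hash, seed, stages and outputs.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("simulate", "reconstruct", "fit", "rpsft", "econ",
                     "report")

.arms <- c("experimental", "control")
.endpoints <- c("pfs", "os")

.need <- function(outdir, file, stage, producer) {
  path <- file.path(outdir, file)
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires missing artifact '%s'; run stage '%s' first",
                 stage, file, producer))
  path
}

.fit_to_list <- function(fit)
  list(family = fit$family, params = as.list(fit$params),
       loglik = fit$loglik, aic = fit$aic, bic = fit$bic)

.fit_from_list <- function(x) surv_fit(x$family, unlist(x$params))

#' Run the full analysis pipeline
#'
#' Executes (a subset of) the stages `simulate`, `reconstruct`, `fit`,
#' `rpsft`, `econ`, `report` against a model configuration, writing all
#' artifacts as delimited text or JSON under `outdir`. Re-running with
#' the same configuration and seed reproduces identical outputs.
#'
#' @param config path to a YAML configuration (default: the packaged base
#'   case) or an already-parsed `cea_config`.
#' @param outdir output directory (created if needed).
#' @param seed integer seed driving the trial simulation and the PSA.
#' @param stages character vector, an ordered subset of
#'   `PIPELINE_STAGES`.
#' @param n_psa number of probabilistic sensitivity draws.
#' @param wtp_grid willingness-to-pay grid for the acceptability curves.
#' @return A run manifest (list with `config_hash`, `seed`, `stages`,
#'   `outputs`, `warnings`), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config_path(), outdir,
                         seed = 1L, stages = PIPELINE_STAGES,
                         n_psa = 1000,
                         wtp_grid = seq(0, 100000, by = 1000)) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- read_cea_config(config)
  } else {
    config_hash <- NA_character_
  }
  outputs <- character(0)
  warns <- character(0)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("run started | config hash %s | seed %d\n", config_hash, seed),
      file = log_path)
  logf("model: cycle %sw, horizon %s cycles, discount %s, wtp %s, stop %s",
       config$model$cycle_length_weeks, config$model$horizon_cycles,
       config$discount$base, config$model$wtp, config$model$stop_threshold)
  for (s in .arms)
    logf("strategy %s: induction %s cycles, cap %s, subsequent fraction %s, tot_ratio %s, mix %s",
         s, config$strategies[[s]]$induction_cycles,
         config$strategies[[s]]$max_treatment_cycles,
         config$strategies[[s]]$subsequent_fraction,
         config$strategies[[s]]$tot_ratio,
         paste(names(config$strategies[[s]]$subsequent_mix), collapse = "/"))
  emit <- function(file) {
    outputs <<- c(outputs, file)
    logf("wrote %s", file)
  }
  run_stage <- function(stage, fn) {
    withCallingHandlers(fn(), warning = function(w) {
      warns <<- c(warns, sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    tr <- config$trial
    sc <- trial_scenario(
      n_per_arm = tr$n_per_arm,
      pfs = lapply(tr$pfs, function(x) c(scale = x$scale, shape = x$shape)),
      os = lapply(tr$os, function(x) c(scale = x$scale, shape = x$shape)),
      censor_range = unlist(tr$censor_range_weeks),
      switch_prob = tr$switch_prob, psi = tr$psi, seed = seed)
    sim <- simulate_trial_ipd(sc)
    for (arm in .arms) {
      for (ep in .endpoints) {
        ipd <- if (ep == "pfs") sim$pfs[[arm]] else {
          rec <- sim$os[sim$os$arm == arm, , drop = FALSE]
          pseudo_ipd(rec$time, rec$event, arm = arm, endpoint = "OS")
        }
        dg <- digitize_km(ipd, grid = seq(0, max(ipd$time), by = 6.5),
                          risk_interval = 13)
        utils::write.csv(as.data.frame(dg$curve),
                         file.path(outdir, sprintf("curve_%s_%s.csv", ep, arm)),
                         row.names = FALSE)
        utils::write.csv(data.frame(time = dg$risk$time,
                                    n_at_risk = dg$risk$n_risk),
                         file.path(outdir, sprintf("risk_%s_%s.csv", ep, arm)),
                         row.names = FALSE)
        emit(sprintf("curve_%s_%s.csv", ep, arm))
        emit(sprintf("risk_%s_%s.csv", ep, arm))
      }
    }
    write_switch_records(sim$os, file.path(outdir, "switch_records.csv"))
    emit("switch_records.csv")
  })

  if ("reconstruct" %in% stages) run_stage("reconstruct", function() {
    for (arm in .arms) for (ep in .endpoints) {
      cpath <- .need(outdir, sprintf("curve_%s_%s.csv", ep, arm),
                     "reconstruct", "simulate")
      rpath <- .need(outdir, sprintf("risk_%s_%s.csv", ep, arm),
                     "reconstruct", "simulate")
      curve <- read_digitized_curve(cpath, arm = arm, endpoint = toupper(ep))
      risk <- read_risk_table(rpath)
      ipd <- reconstruct_pseudo_ipd(curve, risk)
      write_ipd(ipd, file.path(outdir, sprintf("ipd_%s_%s.csv", ep, arm)))
      emit(sprintf("ipd_%s_%s.csv", ep, arm))
    }
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    fits <- list()
    for (arm in .arms) {
      fits[[arm]] <- list()
      for (ep in .endpoints) {
        ipath <- .need(outdir, sprintf("ipd_%s_%s.csv", ep, arm),
                       "fit", "reconstruct")
        ipd <- read_ipd(ipath)
        all_fits <- fit_all_parametric(ipd)
        write_fit_summary(all_fits,
                          file.path(outdir,
                                    sprintf("fit_summary_%s_%s.csv", ep, arm)))
        emit(sprintf("fit_summary_%s_%s.csv", ep, arm))
        fits[[arm]][[ep]] <- .fit_to_list(select_best(all_fits, "AIC"))
      }
    }
    jsonlite::write_json(fits, file.path(outdir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("fits.json")
  })

  if ("rpsft" %in% stages) run_stage("rpsft", function() {
    spath <- .need(outdir, "switch_records.csv", "rpsft", "simulate")
    rec <- read_switch_records(spath)
    est <- estimate_psi(rec)
    cf <- counterfactual_control_ipd(rec, est$psi)
    write_ipd(cf, file.path(outdir, "ipd_os_control_adjusted.csv"))
    emit("ipd_os_control_adjusted.csv")
    adj_fits <- fit_all_parametric(cf)
    write_fit_summary(adj_fits,
                      file.path(outdir, "fit_summary_os_control_adjusted.csv"))
    emit("fit_summary_os_control_adjusted.csv")
    expm <- rec[rec$arm == "experimental", , drop = FALSE]
    hr_adj <- adjusted_hr(
      data.frame(time = expm$time, event = expm$event), cf)
    ctrl <- rec[rec$arm == "control", , drop = FALSE]
    hr_unadj <- adjusted_hr(
      data.frame(time = expm$time, event = expm$event),
      data.frame(time = ctrl$time, event = ctrl$event))
    jsonlite::write_json(
      list(psi = est$psi, logrank_z = est$z, converged = est$converged,
           hr_unadjusted = hr_unadj$hr, hr_adjusted = hr_adj$hr,
           os_fit_adjusted = .fit_to_list(select_best(adj_fits, "AIC"))),
      file.path(outdir, "rpsft.json"), auto_unbox = TRUE, digits = NA)
    emit("rpsft.json")
  })

  if ("econ" %in% stages) run_stage("econ", function() {
    fpath <- .need(outdir, "fits.json", "econ", "fit")
    fj <- jsonlite::read_json(fpath)
    fits <- lapply(fj, function(a) lapply(a, .fit_from_list))
    base_eval <- make_cea_evaluator(config, fits)

    base_inc <- base_eval(list())
    outcomes <- attr(base_inc, "outcomes")
    for (arm in .arms) {
      write_trace(outcomes[[arm]]$trace,
                  file.path(outdir, sprintf("trace_%s.csv", arm)))
      emit(sprintf("trace_%s.csv", arm))
    }

    tor <- one_way_dsa(base_eval, dsa_specs(config))
    utils::write.csv(tor, file.path(outdir, "tornado.csv"),
                     row.names = FALSE)
    emit("tornado.csv")

    params <- cea_parameters(config)
    psa <- run_psa_ceac(base_eval, params, n_draws = n_psa,
                        wtp_grid = wtp_grid, seed = seed + 1L)
    utils::write.csv(psa$ceac, file.path(outdir, "ceac.csv"),
                     row.names = FALSE)
    emit("ceac.csv")
    utils::write.csv(psa$draws, file.path(outdir, "psa_draws.csv"),
                     row.names = FALSE)
    emit("psa_draws.csv")

    # crossover-adjusted scenario: RPSFT counterfactual control OS and a
    # second line without PD-1/PD-L1 antibodies
    scen <- NULL
    if (file.exists(file.path(outdir, "rpsft.json"))) {
      rj <- jsonlite::read_json(file.path(outdir, "rpsft.json"))
      fits_adj <- fits
      fits_adj$control$os <- .fit_from_list(rj$os_fit_adjusted)
      scen_eval <- make_cea_evaluator(config, fits_adj, scenario = TRUE)
      scen <- scen_eval(list())
      write_trace(attr(scen, "outcomes")$control$trace,
                  file.path(outdir, "trace_control_adjusted.csv"))
      emit("trace_control_adjusted.csv")
      psa_s <- run_psa_ceac(scen_eval, params, n_draws = n_psa,
                            wtp_grid = wtp_grid, seed = seed + 1L)
      utils::write.csv(psa_s$ceac, file.path(outdir, "ceac_scenario.csv"),
                       row.names = FALSE)
      emit("ceac_scenario.csv")
    }

    block <- function(label, inc) {
      o <- attr(inc, "outcomes")
      data.frame(
        analysis = label,
        strategy = c(o$experimental$strategy, o$control$strategy),
        total_cost = c(o$experimental$cost, o$control$cost),
        ly = c(o$experimental$ly, o$control$ly),
        qaly = c(o$experimental$qaly, o$control$qaly),
        inc_cost = c(inc$d_cost, NA), inc_ly = c(inc$d_ly, NA),
        inc_qaly = c(inc$d_qaly, NA),
        icer = c(if (inc$label == "icer") inc$icer else NA, NA),
        label = c(inc$label, NA))
    }
    summ <- block("base_case", base_inc)
    if (!is.null(scen)) summ <- rbind(summ, block("crossover_adjusted", scen))
    utils::write.csv(summ, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    emit("summary.csv")
  })

  if ("report" %in% stages) run_stage("report", function() {
    spath <- .need(outdir, "summary.csv", "report", "econ")
    summ <- utils::read.csv(spath)
    lines <- c("Cost-effectiveness summary (discounted)",
               strrep("-", 72))
    for (i in seq_len(nrow(summ))) {
      r <- summ[i, ]
      lines <- c(lines, sprintf(
        "%-20s %-26s $%8.0f %6.2f LY %6.2f QALY%s",
        r$analysis, r$strategy, r$total_cost, r$ly, r$qaly,
        if (!is.na(r$icer)) sprintf("  | ICER $%.0f/QALY", r$icer)
        else if (!is.na(r$label) && nzchar(r$label)) paste0("  | ", r$label)
        else ""))
    }
    if (file.exists(file.path(outdir, "rpsft.json"))) {
      rj <- jsonlite::read_json(file.path(outdir, "rpsft.json"))
      lines <- c(lines, strrep("-", 72),
                 sprintf("RPSFT psi %.4f | OS HR unadjusted %.3f -> adjusted %.3f",
                         rj$psi, rj$hr_unadjusted, rj$hr_adjusted))
    }
    writeLines(lines, file.path(outdir, "report.txt"))
    emit("report.txt")
  })

  manifest <- list(config_hash = config_hash, seed = seed,
                   stages = stages, outputs = unique(outputs),
                   warnings = warns)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("run finished: %d outputs, %d warnings", length(unique(outputs)),
       length(warns))
  invisible(manifest)
}
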