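#' Configuration for a full analysis run
#'
#' Bundles data sources, analysis settings and output location for
#' [run_analysis()].  Data can be given as in-memory objects or file paths
#' (trial CSV, value-set CSV, unit-cost YAML, life-table CSV, norms CSV); a
#' `trial_design` may be supplied instead of a dataset, in which case the
#' trial is simulated first.
#'
#' @param trial a trial data.frame, a CSV path, or a [trial_design()].
#' @param value_set an `eq5d_value_set` or CSV path.
#' @param unit_costs a `unit_cost_table` or YAML path.
#' @param life_table a `life_table` or CSV path.
#' @param norms a `utility_norms` object or CSV path.
#' @param lambda headline willingness to pay (GBP/QALY).
#' @param lambda_grid CEAC grid (must lie within 0–500,000).
#' @param m_imputations imputations.
#' @param seed master seed; all randomness (simulation, imputation) derives
#'   from it.
#' @param sensitivity character vector of scenarios to run, subset of
#'   `"s1"`–`"s6"`.
#' @param subgroups subgroup factors to analyse.
#' @param effective_population population for the EVPI.
#' @param discount_rate annual discount rate for the lifetime projection.
#' @param lifetime logical; run the lifetime analysis.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(trial,
                            value_set = default_value_set(),
                            unit_costs = default_unit_costs(),
                            life_table = make_synthetic_lifetable(),
                            norms = make_synthetic_utility_norms(),
                            lambda = 20000,
                            lambda_grid = seq(0, 50000, by = 500),
                            m_imputations = 20,
                            seed = 1L,
                            sensitivity = paste0("s", 1:6),
                            subgroups = c("urgency", "surgery_category",
                                          "recruitment_timing"),
                            effective_population = 270503,
                            discount_rate = 0.035,
                            lifetime = TRUE,
                            out_dir = NULL) {
  if (is.character(trial)) {
    if (!file.exists(trial)) stop("trial file does not exist: ", trial)
    trial <- read_trial(trial)
  }
  if (is.character(value_set)) value_set <- read_value_set(value_set)
  if (is.character(unit_costs)) unit_costs <- read_unit_costs(unit_costs)
  if (is.character(life_table)) life_table <- read_life_table(life_table)
  if (is.character(norms)) norms <- read_utility_norms(norms)
  if (any(lambda_grid < 0) || any(lambda_grid > 5e5)) {
    stop("lambda_grid must lie within [0, 500000]")
  }
  bad <- setdiff(sensitivity, paste0("s", 1:6))
  if (length(bad) > 0) stop("unknown sensitivity scenario(s): ",
                            paste(bad, collapse = ", "))
  structure(
    list(trial = trial, value_set = value_set, unit_costs = unit_costs,
         life_table = life_table, norms = norms, lambda = lambda,
         lambda_grid = lambda_grid, m_imputations = m_imputations,
         seed = as.integer(seed), sensitivity = sensitivity,
         subgroups = subgroups, effective_population = effective_population,
         discount_rate = discount_rate, lifetime = lifetime,
         out_dir = out_dir),
    class = "analysis_config"
  )
}

arm_summary <- function(trial, costs, qalys) {
  by_arm <- function(x, f = mean) tapply(x, trial$arm, f, na.rm = TRUE)
  dead <- !is.na(trial$death_time_days)
  rbind(
    data.frame(quantity = "n", intervention = sum(trial$arm == "intervention"),
               usual_care = sum(trial$arm == "usual_care")),
    data.frame(quantity = "mortality_6m_pct",
               intervention = 100 * mean(dead[trial$arm == "intervention"]),
               usual_care = 100 * mean(dead[trial$arm == "usual_care"])),
    data.frame(quantity = "mean_eq5d_6m_survivors",
               t(by_arm(ifelse(dead, NA, trial$eq5d_6m)))),
    data.frame(quantity = "mean_qaly_6m", t(by_arm(qalys$qaly))),
    data.frame(quantity = "mean_total_cost", t(by_arm(costs$total))),
    data.frame(quantity = "sd_total_cost", t(by_arm(costs$total, stats::sd))),
    data.frame(quantity = "mean_cc_level2_days", t(by_arm(trial$cc_level2_days))),
    data.frame(quantity = "mean_cc_level3_days", t(by_arm(trial$cc_level3_days))),
    data.frame(quantity = "mean_ward_days", t(by_arm(trial$ward_days))),
    data.frame(quantity = "monitor_used_pct",
               t(100 * by_arm(as.numeric(trial$monitor_used))))
  )
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                        row.names = FALSE)
  wr(res$arm_table, "arm_summary.csv")
  wr(res$incremental_table, "incremental_estimates.csv")
  wr(res$ceac_6m, "ceac_6m.csv")
  if (!is.null(res$ceac_lifetime)) wr(res$ceac_lifetime, "ceac_lifetime.csv")
  wr(res$sensitivity_table, "sensitivity_inb.csv")
  if (!is.null(res$subgroup_table)) wr(res$subgroup_table, "subgroups.csv")
  est_json <- function(e) {
    list(delta_cost = e$delta_cost, delta_qaly = e$delta_qaly,
         cov = e$cov, inb = as.list(inb(e, res$lambda)),
         n_imputations = e$n_imputations, label = e$label)
  }
  jsonlite::write_json(
    list(six_month = est_json(res$est_6m),
         lifetime = if (!is.null(res$est_lifetime)) est_json(res$est_lifetime),
         evpi = if (!is.null(res$evpi)) unclass(res$evpi)),
    file.path(out_dir, "ce_estimate.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Run the full cost-effectiveness analysis
#'
#' Orchestrates the pipeline: (simulate if needed) -> costs -> imputation ->
#' QALYs -> 6-month bivariate estimate -> lifetime extrapolation -> EVPI,
#' plus the six pre-specified sensitivity scenarios and the subgroup
#' analyses.  All scenarios reuse the base-case imputations so that each
#' difference isolates the toggled assumption, and every random stage derives
#' from the single master seed, so a rerun with the same configuration
#' reproduces every number exactly.
#'
#' Sensitivity scenarios: `s1` extra level-2 day + 1 nurse-hour for patients
#' not admitted directly to critical care; `s2` 4.5 nurse-hours per
#' intervention patient; `s3` randomisation-anchored QALYs; `s4` decedent
#' utilities interpolated to the death date; `s5` quality of life frozen at
#' the 6-month value over the lifetime; `s6` parametric (best-AIC, screened)
#' survival extrapolation instead of population rates.  `s1`–`s4` are
#' 6-month scenarios, `s5`–`s6` lifetime scenarios.
#'
#' @param cfg an [analysis_config()].
#' @return list of class `analysis_result`: the trial, arm summary table,
#'   incremental estimates, CEACs, EVPI, sensitivity INB table, subgroup
#'   table and run log.  Written to `cfg$out_dir` when set.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  log <- c(paste("periopcea", as.character(utils::packageVersion("periopcea"))),
           paste("seed", cfg$seed), paste("run", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  trial <- cfg$trial
  if (inherits(trial, "trial_design")) {
    trial <- stage("simulate", generate_trial(trial, uc = cfg$unit_costs,
                                              vs = cfg$value_set))
    log <- c(log, "simulated trial from design")
  }
  uc <- cfg$unit_costs; vs <- cfg$value_set
  costs <- stage("costing", compute_costs(trial, uc))
  imps <- stage("imputation",
                impute_trial(trial, m = cfg$m_imputations, seed = cfg$seed,
                             costs = costs, vs = vs))
  qalys <- stage("qaly", compute_qalys(imps[[1]], vs))

  est_6m <- stage("cea_6m",
                  cea_6m(trial, uc, vs, m = cfg$m_imputations, seed = cfg$seed,
                         imputations = imps, label = "6m base case"))
  ceac_6m_tab <- ceac(est_6m, cfg$lambda_grid)

  proj_cfg <- projection_config(discount_rate = cfg$discount_rate)
  est_life <- NULL; ceac_life <- NULL; voi <- NULL
  if (cfg$lifetime) {
    est_life <- stage("lifetime",
                      lifetime_cea(trial, uc, vs, cfg$life_table, cfg$norms,
                                   proj_cfg, m = cfg$m_imputations,
                                   seed = cfg$seed, imputations = imps,
                                   label = "lifetime base case"))
    ceac_life <- ceac(est_life, cfg$lambda_grid)
    voi <- stage("evpi", evpi(est_life, lambda = cfg$lambda,
                              population = cfg$effective_population,
                              discount_rate = cfg$discount_rate))
  }

  sens_rows <- list(data.frame(
    scenario = "base_6m",
    inb = inb(est_6m, cfg$lambda)$mean,
    delta_cost = est_6m$delta_cost, delta_qaly = est_6m$delta_qaly))
  if (cfg$lifetime) {
    sens_rows <- c(sens_rows, list(data.frame(
      scenario = "base_lifetime", inb = inb(est_life, cfg$lambda)$mean,
      delta_cost = est_life$delta_cost, delta_qaly = est_life$delta_qaly)))
  }
  run_scenario <- function(id) {
    e <- switch(id,
      s1 = cea_6m(trial, uc, vs, sensitivity = "s1", imputations = imps,
                  label = "s1"),
      s2 = cea_6m(trial, uc, vs, sensitivity = "s2", imputations = imps,
                  label = "s2"),
      s3 = cea_6m(trial, uc, vs, baseline_rule = "randomisation",
                  imputations = imps, label = "s3"),
      s4 = cea_6m(trial, uc, vs, decedent_rule = "interpolate_to_death",
                  imputations = imps, label = "s4"),
      s5 = if (cfg$lifetime) {
        lifetime_cea(trial, uc, vs, cfg$life_table, cfg$norms,
                     projection_config(discount_rate = cfg$discount_rate,
                                       qol_mode = "frozen_6m"),
                     imputations = imps, label = "s5")
      },
      s6 = if (cfg$lifetime) {
        lifetime_cea(trial, uc, vs, cfg$life_table, cfg$norms,
                     projection_config(discount_rate = cfg$discount_rate,
                                       extrapolation_mode = "parametric"),
                     imputations = imps, label = "s6")
      })
    if (is.null(e)) return(NULL)
    data.frame(scenario = id, inb = inb(e, cfg$lambda)$mean,
               delta_cost = e$delta_cost, delta_qaly = e$delta_qaly)
  }
  for (id in cfg$sensitivity) {
    row <- stage(paste0("sensitivity_", id), run_scenario(id))
    if (!is.null(row)) sens_rows <- c(sens_rows, list(row))
  }
  sensitivity_table <- do.call(rbind, sens_rows)

  subgroup_table <- NULL
  if (length(cfg$subgroups) > 0) {
    rows <- list()
    for (f in cfg$subgroups) {
      ests <- stage(paste0("subgroup_", f),
                    suppressWarnings(subgroup_cea(
                      trial, f, uc = uc, vs = vs,
                      m = cfg$m_imputations, seed = cfg$seed)))
      for (l in names(ests)) {
        e <- ests[[l]]
        b <- inb(e, cfg$lambda)
        rows <- c(rows, list(data.frame(
          factor = f, level = l, n = sum_level(trial, f, l),
          delta_cost = e$delta_cost, delta_qaly = e$delta_qaly,
          inb = b$mean, inb_lower = b$ci_lower, inb_upper = b$ci_upper)))
      }
    }
    subgroup_table <- do.call(rbind, rows)
  }

  ci <- function(e) {
    b <- inb(e, cfg$lambda)
    data.frame(analysis = e$label,
               delta_cost = e$delta_cost,
               delta_cost_lower = e$delta_cost - 1.959964 * sqrt(e$cov[1, 1]),
               delta_cost_upper = e$delta_cost + 1.959964 * sqrt(e$cov[1, 1]),
               delta_qaly = e$delta_qaly,
               delta_qaly_lower = e$delta_qaly - 1.959964 * sqrt(e$cov[2, 2]),
               delta_qaly_upper = e$delta_qaly + 1.959964 * sqrt(e$cov[2, 2]),
               inb = b$mean, inb_lower = b$ci_lower, inb_upper = b$ci_upper)
  }
  incremental_table <- rbind(ci(est_6m),
                             if (cfg$lifetime) ci(est_life))

  res <- structure(
    list(trial = trial, arm_table = arm_summary(trial, costs, qalys),
         incremental_table = incremental_table,
         est_6m = est_6m, est_lifetime = est_life,
         ceac_6m = ceac_6m_tab, ceac_lifetime = ceac_life,
         evpi = voi, sensitivity_table = sensitivity_table,
         subgroup_table = subgroup_table, lambda = cfg$lambda, log = log),
    class = "analysis_result"
  )
  if (!is.null(cfg$out_dir)) write_outputs(res, cfg$out_dir)
  res
}

sum_level <- function(trial, f, l) {
  lev <- switch(f,
    urgency = trial$urgency,
    surgery_category = trial$surgery_category,
    recruitment_timing = ifelse(trial$recruitment_order_in_site <= 10,
                                "first_ten", "subsequent"))
  sum(lev == l)
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("Cost-effectiveness analysis of", nrow(x$trial), "patients\n\n")
  print(x$est_6m, lambda = x$lambda)
  if (!is.null(x$est_lifetime)) {
    cat("\n")
    print(x$est_lifetime, lambda = x$lambda)
    i <- which.min(abs(x$ceac_lifetime$lambda - x$lambda))
    cat(sprintf("\n  P(cost-effective at %0.0f/QALY), lifetime: %.0f%%\n",
                x$lambda, 100 * x$ceac_lifetime$prob_ce[i]))
  }
  if (!is.null(x$evpi)) { cat("\n"); print(x$evpi) }
  invisible(x)
}
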