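#' Design of a synthetic two-arm, multi-site trial
#'
#' Collects the generating parameters for [generate_trial()].  The defaults
#' emulate a pragmatic trial of cardiac output-guided haemodynamic therapy in
#' 17 UK hospitals: 734 high-risk gastrointestinal-surgery patients aged 50+,
#' 6-month mortality of 7.6% (intervention) vs 11.5% (usual care), mean total
#' costs of GBP 8574 vs 8974 with strong right skew, utility means near 0.78
#' (randomisation), 0.66/0.63 (30 days) and 0.73/0.71 (6 months), and
#' missing-at-random questionnaire loss among survivors.  The baseline
#' (randomisation) utility mean is common to both arms: randomisation
#' guarantees equal baseline distributions, and a built-in baseline
#' difference would leak into the baseline-adjusted treatment contrast.
#'
#' @param n_per_arm patients per arm (default 367).
#' @param n_sites number of recruiting sites (default 17).
#' @param true_delta_cost true incremental mean 6-month cost, intervention
#'   minus usual care, GBP (default -400).
#' @param true_delta_qaly true incremental mean 6-month QALY under the
#'   base-case construction (day-30 anchor, zero utility at post-death
#'   assessments); default 0.01.
#' @param mean_cost_usual mean total 6-month cost in the usual-care arm, GBP.
#' @param baseline_mortality_6m length-2 probability vector
#'   `c(intervention, usual_care)` of death within 6 months.
#' @param utility_means 2x3 matrix (rows `intervention`, `usual_care`;
#'   columns randomisation / 30 days / 6 months) of pre-calibration utility
#'   means.  The intervention-arm post-randomisation means are shifted by a
#'   calibrated constant so the generated QALY contrast equals
#'   `true_delta_qaly`.
#' @param utility_sd residual SD of utilities at each time point.
#' @param utility_autocorrelation AR(1) correlation of the three utility
#'   measurements, in `[0, 1)`.
#' @param cost_shape gamma shape for the skewed bed-day cost component;
#'   values below 1 give the heavy right skew seen in hospital costs.
#' @param site_sd_cost,site_sd_utility SDs of additive site random intercepts
#'   on the cost (GBP) and utility scales.
#' @param missing_prob_30d,missing_prob_6m marginal probabilities that a
#'   survivor's EQ-5D at 30 days / 6 months is missing (missingness depends
#'   on arm and age only — missing at random).
#' @param covariate_effects named list; each element is `c(cost = ..,
#'   utility = ..)` giving the log-scale cost effect and additive utility
#'   effect per unit of the centred covariate (`age` in years; binary risk
#'   factors as 0/1).
#' @param seed integer master seed.
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 367,
                         n_sites = 17,
                         true_delta_cost = -400,
                         true_delta_qaly = 0.01,
                         mean_cost_usual = 8974,
                         baseline_mortality_6m = c(intervention = 0.076,
                                                   usual_care = 0.115),
                         utility_means = rbind(
                           intervention = c(0.775, 0.66, 0.73),
                           usual_care   = c(0.775, 0.63, 0.71)),
                         utility_sd = 0.29,
                         utility_autocorrelation = 0.5,
                         cost_shape = 0.75,
                         site_sd_cost = 400,
                         site_sd_utility = 0.02,
                         missing_prob_30d = 0.12,
                         missing_prob_6m = 0.12,
                         covariate_effects = list(
                           age = c(cost = 0.012, utility = -0.004),
                           cardioresp_risk = c(cost = 0.15, utility = -0.02)),
                         seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      stop("invalid design: ", nm, " must be a count >= 1")
    }
  }
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid design: ", nm, " must be probability(ies) in [0, 1]")
    }
  }
  chk_pos <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x <= 0) {
      stop("invalid design: ", nm, " must be a positive real")
    }
  }
  chk_count(n_per_arm, "n_per_arm"); chk_count(n_sites, "n_sites")
  chk_prob(baseline_mortality_6m, "baseline_mortality_6m")
  if (length(baseline_mortality_6m) != 2) {
    stop("invalid design: baseline_mortality_6m must have one probability per arm")
  }
  chk_prob(missing_prob_30d, "missing_prob_30d")
  chk_prob(missing_prob_6m, "missing_prob_6m")
  chk_pos(cost_shape, "cost_shape")
  chk_pos(utility_sd, "utility_sd")
  if (site_sd_cost < 0) stop("invalid design: site_sd_cost must be >= 0")
  if (site_sd_utility < 0) stop("invalid design: site_sd_utility must be >= 0")
  if (!is.finite(utility_autocorrelation) || utility_autocorrelation < 0 ||
      utility_autocorrelation >= 1) {
    stop("invalid design: utility_autocorrelation must be in [0, 1)")
  }
  if (!is.matrix(utility_means) || !all(dim(utility_means) == c(2, 3))) {
    stop("invalid design: utility_means must be a 2x3 matrix (arms x timepoints)")
  }
  structure(
    list(n_per_arm = as.integer(n_per_arm), n_sites = as.integer(n_sites),
         true_delta_cost = true_delta_cost, true_delta_qaly = true_delta_qaly,
         mean_cost_usual = mean_cost_usual,
         baseline_mortality_6m = stats::setNames(
           baseline_mortality_6m, c("intervention", "usual_care")),
         utility_means = utility_means, utility_sd = utility_sd,
         utility_autocorrelation = utility_autocorrelation,
         cost_shape = cost_shape, site_sd_cost = site_sd_cost,
         site_sd_utility = site_sd_utility,
         missing_prob_30d = missing_prob_30d,
         missing_prob_6m = missing_prob_6m,
         covariate_effects = covariate_effects,
         seed = as.integer(seed)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Synthetic trial design:", 2 * x$n_per_arm, "patients,",
      x$n_sites, "sites\n")
  cat("  true delta cost:", x$true_delta_cost,
      "GBP | true delta QALY:", x$true_delta_qaly, "\n")
  cat("  6-month mortality:",
      paste(sprintf("%s %.3f", names(x$baseline_mortality_6m),
                    x$baseline_mortality_6m), collapse = ", "), "\n")
  invisible(x)
}

#' Generating values behind a design
#'
#' Echoes the exact parameters a synthetic dataset was generated under, for
#' parameter-recovery tests.
#'
#' @param design a [trial_design()].
#' @return list with `delta_cost`, `delta_qaly` and `mortality_6m`.
#' @export
ground_truth <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  list(delta_cost = design$true_delta_cost,
       delta_qaly = design$true_delta_qaly,
       mortality_6m = design$baseline_mortality_6m)
}

# mean of a normal(mu, sigma) clipped to [a, b]
clipped_normal_mean <- function(mu, sigma, a, b) {
  if (sigma <= 0) return(pmin(pmax(mu, a), b))
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  a * stats::pnorm(alpha) + b * stats::pnorm(beta, lower.tail = FALSE) +
    mu * (stats::pnorm(beta) - stats::pnorm(alpha)) -
    sigma * (stats::dnorm(beta) - stats::dnorm(alpha))
}

#' Generate a synthetic patient-level trial dataset
#'
#' Draws a complete two-arm, multi-site dataset with known ground truth:
#'
#' * Covariates match the trial's baseline table (age truncated-normal around
#'   72, ~63% male, ~97% elective, the four surgical categories, ASA grade,
#'   post-operative location, comorbidities).
#' * Death within 6 months is Bernoulli per arm; death times are exponential
#'   truncated to the 182.625-day window.
#' * Utilities at the three assessments are a truncated (clipped to the value
#'   set's `[floor, 1]` range) multivariate normal with AR(1) correlation,
#'   additive site intercepts and centred covariate effects.  A constant
#'   post-randomisation shift in the intervention arm is calibrated
#'   numerically — through the clipping and the mortality contrast — so the
#'   true base-case QALY difference equals `design$true_delta_qaly`.
#' * Total cost is an exactly-known sum of itemised components (adjusted
#'   surgery, monitor, dopexamine, fluids and blood) plus a gamma-distributed
#'   bed-day component with log-link covariate effects and additive site
#'   intercepts, calibrated so the arm mean totals differ by exactly
#'   `design$true_delta_cost`; the bed-day component is decomposed into
#'   level-2/level-3 critical-care and ward days so that [compute_costs()]
#'   reconstructs the generated totals exactly.
#' * Missingness of survivor EQ-5D is missing-at-random: its probability
#'   depends only on arm and age, never on the masked value.
#'
#' @param design a [trial_design()].
#' @param uc unit-cost table the cost components are generated against (and
#'   should later be costed with).
#' @param profiles if `TRUE`, utilities are back-converted to the nearest
#'   EQ-5D-3L profile under `vs` and stored as 5-digit strings; the default
#'   stores the index values directly, which keeps the generating QALY
#'   contrast exact.
#' @param vs value set used for the clipping range and profile
#'   back-conversion.
#' @param mask_missing set `FALSE` to keep the generated-but-masked utilities
#'   (used by missing-at-random diagnostics).
#' @return data.frame, one row per patient.  Columns: identifiers and
#'   covariates (`patient_id`, `arm`, `site_id`, `recruitment_order_in_site`,
#'   `age`, `sex`, `urgency`, `surgery_category`, `asa_grade`,
#'   `postop_location`, `renal_impairment`, `diabetes`, `cardioresp_risk`),
#'   utilities (`eq5d_random`, `eq5d_30d`, `eq5d_6m`), survival
#'   (`death_time_days`, `followup_days`), and resource use
#'   (`procedure_code`, `cc_level2_days`, `cc_level3_days`, `ward_days`,
#'   `monitor_used`, `dopexamine_mg`, crystalloid/colloid/blood volumes split
#'   intra-operative vs 6-h post-operative plus totals).
#' @export
generate_trial <- function(design, uc = default_unit_costs(),
                           profiles = FALSE, vs = default_value_set(),
                           mask_missing = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  n <- 2L * design$n_per_arm
  arm <- sample(rep(c("intervention", "usual_care"), design$n_per_arm))
  site_id <- sample.int(design$n_sites, n, replace = TRUE)
  recruitment_order <- stats::ave(seq_len(n), site_id, FUN = seq_along)

  age <- pmin(95, pmax(50, stats::rnorm(n, 71.7, 8.5)))
  sex <- ifelse(stats::runif(n) < 0.635, "M", "F")
  urgency <- ifelse(stats::runif(n) < 0.966, "elective", "non_elective")
  surgery_category <- sample(
    c("upper_GI", "lower_GI", "small_bowel_pancreas", "uro_gynae", "none"),
    n, replace = TRUE, prob = c(0.299, 0.453, 0.229, 0.012, 0.007))
  asa_grade <- sample(1:4, n, replace = TRUE, prob = c(0.067, 0.510, 0.407, 0.016))
  postop_location <- sample(c("cc_level2", "cc_level3", "recovery", "ward"),
                            n, replace = TRUE, prob = c(0.687, 0.112, 0.026, 0.175))
  renal_impairment <- stats::runif(n) < 0.052
  diabetes <- stats::runif(n) < 0.166
  cardioresp_risk <- stats::runif(n) < 0.322

  covs <- data.frame(age = age, renal_impairment = as.numeric(renal_impairment),
                     diabetes = as.numeric(diabetes),
                     cardioresp_risk = as.numeric(cardioresp_risk))
  lp_cost <- numeric(n)
  util_shift <- numeric(n)
  for (nm in names(design$covariate_effects)) {
    if (!nm %in% names(covs)) {
      stop("covariate_effects refers to unsupported covariate: ", nm)
    }
    x <- covs[[nm]] - mean(covs[[nm]])
    eff <- design$covariate_effects[[nm]]
    lp_cost <- lp_cost + x * eff[["cost"]]
    util_shift <- util_shift + x * eff[["utility"]]
  }

  site_b_cost <- stats::rnorm(design$n_sites, 0, design$site_sd_cost)
  site_b_util <- stats::rnorm(design$n_sites, 0, design$site_sd_utility)

  # --- survival ------------------------------------------------------------
  p_death <- design$baseline_mortality_6m[ifelse(arm == "intervention", 1, 2)]
  dies <- stats::runif(n) < p_death
  death_time_days <- rep(NA_real_, n)
  if (any(dies)) {
    p <- pmax(p_death[dies], 1e-12)
    lambda <- -log(1 - p) / SIX_MONTHS_DAYS
    u <- stats::runif(sum(dies))
    death_time_days[dies] <- -log(1 - u * (1 - exp(-lambda * SIX_MONTHS_DAYS))) /
      lambda
  }

  # --- utilities -----------------------------------------------------------
  is_int <- arm == "intervention"
  mu_base <- design$utility_means[ifelse(is_int, 1, 2), , drop = FALSE]
  pre_mean <- mu_base + util_shift + site_b_util[site_id]  # n x 3, pre-shift
  sdu <- design$utility_sd
  floor_u <- vs$floor

  t30 <- DAYS_PER_MONTH / DAYS_PER_YEAR
  w30 <- t30 + (0.5 - t30) / 2          # AUC weight on the 30-day value (7/24)
  w6m <- (0.5 - t30) / 2                # AUC weight on the 6-month value (5/24)
  # P(death after day 30 | death within 6 months), truncated-exponential times
  q_after30 <- vapply(design$baseline_mortality_6m, function(p) {
    if (p <= 0) return(0)
    lambda <- -log(1 - p) / SIX_MONTHS_DAYS
    (exp(-lambda * DAYS_PER_MONTH) - exp(-lambda * SIX_MONTHS_DAYS)) /
      (1 - exp(-lambda * SIX_MONTHS_DAYS))
  }, numeric(1))

  expected_qaly <- function(delta) {
    sh <- ifelse(is_int, delta, 0)
    m30 <- clipped_normal_mean(pre_mean[, 2] + sh, sdu, floor_u, 1)
    m6m <- clipped_normal_mean(pre_mean[, 3] + sh, sdu, floor_u, 1)
    p <- p_death
    q <- q_after30[ifelse(is_int, 1, 2)]
    (1 - p) * (w30 * m30 + w6m * m6m) + p * q * w30 * m30
  }
  gap <- function(delta) {
    eq <- expected_qaly(delta)
    mean(eq[is_int]) - mean(eq[!is_int]) - design$true_delta_qaly
  }
  delta_u <- stats::uniroot(gap, c(-0.6, 0.6), tol = 1e-12)$root

  rho <- design$utility_autocorrelation
  R <- rho^abs(outer(1:3, 1:3, "-"))
  L <- chol(R)
  eps <- matrix(stats::rnorm(3 * n), n, 3) %*% L * sdu
  raw <- pre_mean + eps
  raw[, 2:3] <- raw[, 2:3] + ifelse(is_int, delta_u, 0)
  util <- pmin(pmax(raw, floor_u), 1)

  # --- resource use and costs ---------------------------------------------
  procedure_code <- surgery_category
  monitor_used <- stats::runif(n) < ifelse(is_int, 0.989, 0.085)
  dopexamine_mg <- ifelse(is_int, pmax(0, stats::rnorm(n, 18.9, 8.4)), 0)
  tn <- function(mu, sd) pmax(0, stats::rnorm(n, mu, sd))
  crystalloid_intra_ml <- tn(ifelse(is_int, 1518, 2420), 1400)
  crystalloid_post_ml <- tn(ifelse(is_int, 565, 670), 310)
  colloid_intra_ml <- tn(ifelse(is_int, 1465, 708), 800)
  colloid_post_ml <- tn(ifelse(is_int, 642, 226), 430)
  zi <- function(p_pos, mean_pos) {
    ifelse(stats::runif(n) < p_pos, stats::rexp(n, 1 / mean_pos), 0)
  }
  blood_intra_ml <- zi(0.15, ifelse(is_int, 141, 95) / 0.15)
  blood_post_ml <- zi(0.08, ifelse(is_int, 80, 10) / 0.08)

  fixed_cost <- adjusted_surgery_cost(procedure_code, uc) +
    as.numeric(monitor_used) * uc$monitor_per_patient +
    dopexamine_mg * uc$dopexamine_per_mg +
    (crystalloid_intra_ml + crystalloid_post_ml) * uc$crystalloid_per_ml +
    (colloid_intra_ml + colloid_post_ml) * uc$colloid_per_ml +
    (blood_intra_ml + blood_post_ml) * uc$blood_per_ml

  target_mean <- ifelse(is_int, design$mean_cost_usual + design$true_delta_cost,
                        design$mean_cost_usual)
  w <- exp(lp_cost)
  bed_mean <- numeric(n)
  for (a in c(TRUE, FALSE)) {
    sel <- is_int == a
    A <- mean(target_mean[sel]) - mean(fixed_cost[sel]) -
      mean(site_b_cost[site_id[sel]])
    if (A <= 0) {
      stop("design infeasible: fixed cost components exceed the target mean ",
           "total cost; raise mean_cost_usual or lower unit costs")
    }
    bed_mean[sel] <- A * w[sel] / mean(w[sel]) + site_b_cost[site_id[sel]]
  }
  bed_mean <- pmax(bed_mean, 1)
  bed_cost <- stats::rgamma(n, shape = design$cost_shape,
                            scale = bed_mean / design$cost_shape)
  sh <- cbind(stats::rgamma(n, 1.0), stats::rgamma(n, 0.5), stats::rgamma(n, 1.55))
  sh <- sh / rowSums(sh)
  cc_level2_days <- sh[, 1] * bed_cost / uc$cc_level2_day
  cc_level3_days <- sh[, 2] * bed_cost / uc$cc_level3_day
  ward_days <- sh[, 3] * bed_cost / uc$ward_day

  # --- assessment availability and MAR masking ----------------------------
  alive_30 <- is.na(death_time_days) | death_time_days > DAYS_PER_MONTH
  alive_6m <- is.na(death_time_days)
  eq5d_random <- util[, 1]
  eq5d_30d <- ifelse(alive_30, util[, 2], NA_real_)
  eq5d_6m <- ifelse(alive_6m, util[, 3], NA_real_)
  if (mask_missing) {
    mar_mask <- function(p, alive) {
      if (p <= 0) return(rep(FALSE, n))
      lg <- stats::qlogis(p) + 0.4 * ((!is_int) - 0.5) + 0.03 * (age - mean(age))
      alive & stats::runif(n) < stats::plogis(lg)
    }
    eq5d_30d[mar_mask(design$missing_prob_30d, alive_30)] <- NA_real_
    eq5d_6m[mar_mask(design$missing_prob_6m, alive_6m)] <- NA_real_
  }
  if (profiles) {
    all_prof <- eq5d_all_profiles()
    prof_idx <- eq5d_index(all_prof, vs)
    to_prof <- function(u) {
      out <- rep(NA_character_, length(u))
      ok <- !is.na(u)
      out[ok] <- all_prof[vapply(u[ok], function(v) which.min(abs(prof_idx - v)),
                                 integer(1))]
      out
    }
    eq5d_random <- to_prof(eq5d_random)
    eq5d_30d <- to_prof(eq5d_30d)
    eq5d_6m <- to_prof(eq5d_6m)
  }

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    arm = arm, site_id = site_id,
    recruitment_order_in_site = recruitment_order,
    age = age, sex = sex, urgency = urgency,
    surgery_category = surgery_category, asa_grade = asa_grade,
    postop_location = postop_location,
    renal_impairment = renal_impairment, diabetes = diabetes,
    cardioresp_risk = cardioresp_risk,
    eq5d_random = eq5d_random, eq5d_30d = eq5d_30d, eq5d_6m = eq5d_6m,
    death_time_days = death_time_days, followup_days = SIX_MONTHS_DAYS,
    procedure_code = procedure_code,
    cc_level2_days = cc_level2_days, cc_level3_days = cc_level3_days,
    ward_days = ward_days, monitor_used = monitor_used,
    dopexamine_mg = dopexamine_mg,
    crystalloid_intra_ml = crystalloid_intra_ml,
    crystalloid_post_ml = crystalloid_post_ml,
    colloid_intra_ml = colloid_intra_ml, colloid_post_ml = colloid_post_ml,
    blood_intra_ml = blood_intra_ml, blood_post_ml = blood_post_ml,
    stringsAsFactors = FALSE
  )
  out$crystalloid_ml <- out$crystalloid_intra_ml + out$crystalloid_post_ml
  out$colloid_ml <- out$colloid_intra_ml + out$colloid_post_ml
  out$blood_ml <- out$blood_intra_ml + out$blood_post_ml
  attr(out, "calibration") <- list(utility_shift_intervention = delta_u)
  out
}

#' Write / read the patient-level trial CSV
#'
#' One row per patient; missing values as empty fields; times in days.
#'
#' @param trial trial data.frame.
#' @param path CSV path.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(trial, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  logicals <- c("renal_impairment", "diabetes", "cardioresp_risk",
                "monitor_used")
  for (cl in intersect(logicals, names(tr))) tr[[cl]] <- as.logical(tr[[cl]])
  tr
}
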