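#' @keywords internal
#' Calendar conventions used throughout: 1 month = 30.4375 days,
#' 6 months = 182.625 days = 0.5 years, 1 year = 365.25 days.
DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.4375
SIX_MONTHS_DAYS <- 182.625

#' Utility trajectory for one patient
#'
#' A piecewise-linear health-utility curve over follow-up, the object that the
#' area-under-the-curve QALY integrates.  Times are in years anchored at 0;
#' the 6-month trial schedule is (0, 1/12, 1/2).  Utilities at assessment
#' times after death must be zero.
#'
#' @param times strictly increasing numeric vector of assessment times (years).
#' @param utilities numeric vector of utility indices, same length as `times`.
#'   Values at times after `death_time` must be 0.
#' @param death_time death time in years, or `NULL` if the patient survived
#'   the horizon.
#' @param decedent_rule `"zero_at_timepoints"` (base case: a decedent scores
#'   zero at every assessment after death, and the curve interpolates between
#'   the last pre-death assessment and that zero) or `"interpolate_to_death"`
#'   (utility declines linearly from the last observed value to 0 at the death
#'   date, then stays 0).
#' @return Object of class `utility_trajectory`.
#' @export
utility_trajectory <- function(times, utilities, death_time = NULL,
                               decedent_rule = c("zero_at_timepoints",
                                                 "interpolate_to_death")) {
  decedent_rule <- match.arg(decedent_rule)
  if (length(times) != length(utilities)) {
    stop("times and utilities must have the same length")
  }
  if (length(times) < 1) stop("a trajectory needs at least one time point")
  if (any(diff(times) <= 0)) stop("trajectory times must be strictly increasing")
  if (any(!is.finite(times)) || times[1] < 0) {
    stop("trajectory times must be finite and start at or after 0")
  }
  if (!is.null(death_time)) {
    if (is.na(death_time) || death_time <= 0) {
      stop("death_time must be positive (or NULL for survivors)")
    }
    late <- times > death_time & !is.na(utilities)
    if (any(utilities[late] != 0)) {
      stop("utilities at assessment times after death must be 0")
    }
  }
  structure(
    list(times = times, utilities = utilities, death_time = death_time,
         decedent_rule = decedent_rule),
    class = "utility_trajectory"
  )
}

#' Nodes of the piecewise-linear curve a trajectory integrates
#'
#' Applies the decedent rule and horizon to produce the (time, utility) nodes
#' whose trapezoidal integral is the QALY.  Exposed so the numerical
#' behaviour is auditable.
#'
#' @param traj a [utility_trajectory()].
#' @param horizon integration horizon in years (0.5 for the 6-month analysis).
#' @return data.frame with columns `time`, `utility`.
#' @export
trajectory_nodes <- function(traj, horizon = 0.5) {
  stopifnot(inherits(traj, "utility_trajectory"))
  t <- traj$times
  u <- traj$utilities
  if (anyNA(u)) stop("trajectory contains unresolved missing utilities; impute first")
  dt <- traj$death_time
  if (!is.null(dt) && traj$decedent_rule == "interpolate_to_death" && dt < horizon) {
    keep <- t < dt
    t <- t[keep]; u <- u[keep]
    if (length(t) == 0) { t <- 0; u <- 0 }
    t <- c(t, dt); u <- c(u, 0)
    if (dt < horizon) { t <- c(t, horizon); u <- c(u, 0) }
  } else {
    # zero_at_timepoints: post-death zeros are already in the utilities
    if (t[length(t)] < horizon) {
      t <- c(t, horizon)
      u <- c(u, u[length(u)])
    }
  }
  keep <- t <= horizon + 1e-12
  data.frame(time = t[keep], utility = u[keep])
}

#' QALYs by the area-under-the-curve method
#'
#' Trapezoidal integral of the utility trajectory over `[0, horizon]` years,
#' i.e. survival time weighted by the concurrent utility index.  Negative
#' utilities (states worse than death) integrate negatively; the result is
#' not clipped.
#'
#' @inheritParams trajectory_nodes
#' @return QALYs (years) over the horizon.
#' @examples
#' tr <- utility_trajectory(c(0, 0.5), c(0.8, 0.8))
#' qaly_auc(tr)  # 0.4
#' @export
qaly_auc <- function(traj, horizon = 0.5) {
  nodes <- trajectory_nodes(traj, horizon = horizon)
  t <- nodes$time
  u <- nodes$utility
  if (length(t) == 1) return(u * horizon)
  sum(diff(t) * (utils::head(u, -1) + utils::tail(u, -1)) / 2)
}

#' Build the QALY trajectory for one patient record
#'
#' Maps one trial row to a [utility_trajectory()] on the (0, 1/12, 1/2)-year
#' schedule.  The base case anchors t = 0 at the day-30 utility
#' (`baseline_rule = "day30"`): surgery itself depresses the randomisation
#' score in both arms, so the 30-day value is taken as the post-operative
#' baseline.  The sensitivity analysis anchors at the randomisation value
#' (`"randomisation"`).  Decedents score zero at assessments after death
#' (base case) or interpolate linearly to zero at the death date
#' (`decedent_rule = "interpolate_to_death"`; for deaths before day 30 the
#' interpolation starts from the randomisation value, the only pre-death
#' observation).
#'
#' @param u_rand,u_30d,u_6m utility indices at randomisation, 30 days and
#'   6 months (`NA` when unobserved).
#' @param death_time_days death time in days since randomisation, `NA` for
#'   survivors.
#' @param baseline_rule `"day30"` (base case) or `"randomisation"`.
#' @param decedent_rule see [utility_trajectory()].
#' @return A `utility_trajectory`, or `NA` (a missing-trajectory marker) when
#'   a utility the rules need is unobserved for a live time point — flagged
#'   for the imputation stage, never silently filled.
#' @export
build_trajectory <- function(u_rand, u_30d, u_6m, death_time_days = NA,
                             baseline_rule = c("day30", "randomisation"),
                             decedent_rule = c("zero_at_timepoints",
                                               "interpolate_to_death")) {
  baseline_rule <- match.arg(baseline_rule)
  decedent_rule <- match.arg(decedent_rule)
  t30 <- DAYS_PER_MONTH / DAYS_PER_YEAR   # 1/12 year
  t6m <- SIX_MONTHS_DAYS / DAYS_PER_YEAR  # 0.5 year
  dead <- !is.na(death_time_days)
  death_time <- if (dead) death_time_days / DAYS_PER_YEAR else NULL
  alive_30 <- !dead || death_time > t30
  alive_6m <- !dead || death_time > t6m

  v30 <- if (alive_30) u_30d else 0
  v6m <- if (alive_6m) u_6m else 0
  anchor <- switch(baseline_rule,
    day30 = {
      if (!alive_30 && decedent_rule == "interpolate_to_death") u_rand else v30
    },
    randomisation = u_rand
  )
  # death before day 30 under the base-case anchor: the whole curve is zero
  if (!alive_30 && baseline_rule == "day30" &&
      decedent_rule == "zero_at_timepoints") {
    anchor <- 0
  }
  vals <- c(anchor, v30, v6m)
  if (anyNA(vals)) return(NA)
  utility_trajectory(times = c(0, t30, t6m), utilities = vals,
                     death_time = death_time, decedent_rule = decedent_rule)
}

#' Per-patient QALYs for a trial table
#'
#' Applies [build_trajectory()] and [qaly_auc()] row by row.  The trial table
#' must carry utility-index columns `eq5d_random`, `eq5d_30d`, `eq5d_6m`
#' (numeric indices, or 5-digit profile strings which are scored through
#' `vs`), and `death_time_days`.
#'
#' @param trial trial data.frame (see [generate_trial()] for the schema).
#' @param vs value set used when the EQ-5D columns hold profile strings.
#' @param baseline_rule,decedent_rule passed to [build_trajectory()].
#' @param horizon integration horizon in years.
#' @return data.frame with `patient_id`, `qaly`, and `qaly_missing` (TRUE when
#'   a needed utility is unobserved and the QALY awaits imputation).
#' @export
compute_qalys <- function(trial, vs = default_value_set(),
                          baseline_rule = c("day30", "randomisation"),
                          decedent_rule = c("zero_at_timepoints",
                                            "interpolate_to_death"),
                          horizon = 0.5) {
  baseline_rule <- match.arg(baseline_rule)
  decedent_rule <- match.arg(decedent_rule)
  cols <- c("eq5d_random", "eq5d_30d", "eq5d_6m")
  missing_cols <- setdiff(c(cols, "death_time_days"), names(trial))
  if (length(missing_cols) > 0) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  u <- lapply(cols, function(cl) {
    x <- trial[[cl]]
    if (is.character(x)) eq5d_index(x, vs) else as.numeric(x)
  })
  names(u) <- cols
  n <- nrow(trial)
  qaly <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- build_trajectory(u$eq5d_random[i], u$eq5d_30d[i], u$eq5d_6m[i],
                           death_time_days = trial$death_time_days[i],
                           baseline_rule = baseline_rule,
                           decedent_rule = decedent_rule)
    if (inherits(tr, "utility_trajectory")) qaly[i] <- qaly_auc(tr, horizon)
  }
  data.frame(patient_id = trial$patient_id, qaly = qaly,
             qaly_missing = is.na(qaly))
}
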