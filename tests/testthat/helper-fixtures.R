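# shared fixtures: built in code, no files

toy_value_set <- function() {
  eq5d_value_set(c(constant = 0.10, MO2 = 0.05, MO3 = 0.05,
                   SC2 = 0, SC3 = 0, UA2 = 0, UA3 = 0,
                   PD2 = 0, PD3 = 0, AD2 = 0, AD3 = 0, N3 = 0),
                 name = "toy")
}

toy_unit_costs <- function() {
  unit_cost_table(
    procedures = data.frame(
      code = c("upper_GI", "lower_GI", "small_bowel_pancreas", "uro_gynae",
               "none"),
      reference_cost = c(5000, 4000, 6000, 3500, 500),
      avg_los_days = c(10, 8, 12, 7, 0)),
    ward_day = 300, cc_level2_day = 800, cc_level3_day = 1200,
    recovery_day = 400, monitor_per_patient = 150, dopexamine_per_mg = 2,
    crystalloid_per_ml = 0.001, colloid_per_ml = 0.01, blood_per_ml = 0.4,
    nurse_hour = 30, price_year = "toy")
}

small_design <- function(seed = 11, ...) {
  args <- list(n_per_arm = 60, n_sites = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(trial_design, args)
}

# constant-hazard life table over ages 50..max_age (terminal qx = 1)
const_lifetable <- function(q, max_age = 100) {
  ages <- 50:max_age
  qx <- rep(q, length(ages)); qx[length(qx)] <- 1
  life_table(data.frame(age = rep(ages, 2),
                        sex = rep(c("M", "F"), each = length(ages)),
                        qx = rep(qx, 2)))
}

const_norms <- function(u, max_age = 110) {
  utility_norms(data.frame(age = 40:max_age, utility = u))
}

# trapezoidal integral of a piecewise-linear curve on a fine grid that
# includes the knots (exact for piecewise-linear integrands)
grid_integral <- function(x, y, from, to, n = 20000) {
  g <- sort(unique(c(seq(from, to, length.out = n), x[x >= from & x <= to])))
  f <- stats::approxfun(x, y, rule = 2)
  v <- f(g)
  sum(diff(g) * (head(v, -1) + tail(v, -1)) / 2)
}
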