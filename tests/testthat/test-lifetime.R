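test_that("exponential fit recovers the closed-form MLE and log-likelihood", {
  # 10 events, 100 person-years: rate 0.1, logLik = 10 log(0.1) - 10
  times <- c(rep(3, 10), rep(10, 7))
  events <- c(rep(1, 10), rep(0, 7))
  stopifnot(sum(times) == 100)
  f <- fit_parametric(times, events, "exponential")
  expect_true(f$converged)
  expect_equal(unname(f$parameters[["rate"]]), 0.1, tolerance = 1e-5)
  expect_equal(f$log_likelihood, 10 * log(0.1) - 10, tolerance = 1e-6)
  expect_equal(f$aic, 2 * 1 - 2 * f$log_likelihood)
  expect_error(fit_parametric(times, rep(0, 17)), "at least one event")
})

test_that("Weibull simulation recovers the generating shape within 10%", {
  set.seed(271)
  t_true <- rweibull(500, shape = 1.5, scale = 5)
  cens <- pmin(t_true, 6)
  ev <- as.numeric(t_true <= 6)
  f <- fit_parametric(cens, ev, "weibull")
  expect_lt(abs(f$parameters[["shape"]] - 1.5) / 1.5, 0.10)
  expect_equal(f$aic, 2 * 2 - 2 * f$log_likelihood)
})

test_that("AIC comparison behaves for nested exponential/Weibull models", {
  set.seed(5150)
  wins <- 0
  for (r in 1:10) {
    t_true <- rexp(300, 0.2)
    cens <- pmin(t_true, 8)
    ev <- as.numeric(t_true <= 8)
    fe <- fit_parametric(cens, ev, "exponential")
    fw <- fit_parametric(cens, ev, "weibull")
    if (fw$aic <= fe$aic + 2 + 1e-9) wins <- wins + 1
  }
  expect_gte(wins, 8)  # holds up to occasional boundary fits
})

test_that("model selection ranks by AIC with a deterministic tie-break", {
  times <- c(rep(3, 10), rep(10, 7)); events <- c(rep(1, 10), rep(0, 7))
  f1 <- fit_parametric(times, events, "exponential")
  sel1 <- select_model(list(f1))
  expect_identical(sel1$best$family, "exponential")

  # exact tie: deterministic preference by the fixed family order
  f2 <- f1; f2$family <- "lognormal"
  sel_tied <- select_model(list(lognormal = f2, exponential = f1))
  expect_identical(sel_tied$best$family, "exponential")
  expect_true(all(sel_tied$ranking$tied))
})

test_that("the plausibility screen equals direct hazard evaluation", {
  set.seed(11)
  t_true <- rweibull(400, shape = 1.3, scale = 8)
  cens <- pmin(t_true, 5); ev <- as.numeric(t_true <= 5)
  f <- fit_parametric(cens, ev, "weibull")
  lt <- make_synthetic_lifetable()
  sel <- select_model(list(weibull = f), lt = lt, age = rep(72, 10),
                      sex = rep(c("M", "F"), 5), landmark = 0.5,
                      horizon_years = 5)
  pl <- sel$plausibility
  sh <- f$parameters[["shape"]]; sc <- f$parameters[["scale"]]
  S <- function(t) exp(-(t / sc)^sh)
  for (k in 1:5) {
    expect_equal(pl$model_rate[pl$year == k],
                 1 - S(0.5 + k) / S(0.5 + k - 1), tolerance = 1e-10)
    ages <- floor(72.5) + (k - 1)
    expect_equal(pl$population_rate[pl$year == k],
                 mean(lt$qx[lt$age == ages]), tolerance = 1e-12)
  }
})

test_that("population-rate survival projection is a cumulative product of 1-qx", {
  lt <- const_lifetable(0.1)
  sv <- project_survival(60, "F", lt, projection_config())
  expect_equal(sv$surv[1:3], c(0.9, 0.81, 0.729))
  expect_true(all(diff(sv$surv) <= 1e-12))  # non-increasing
  # qx = 1 everywhere: dead after the first cycle
  sv1 <- project_survival(60, "M", const_lifetable(1), projection_config())
  expect_equal(sv1$surv[1], 0)
  # qx = 0 until the terminal age: survival 1 each cycle
  sv0 <- project_survival(60, "M", const_lifetable(0), projection_config())
  expect_true(all(sv0$surv[sv0$time < 40] == 1))
  # row order of the life table is irrelevant
  shuffled <- const_lifetable(0.1)
  shuffled <- life_table(shuffled[sample(nrow(shuffled)), ])
  expect_equal(project_survival(60, "F", shuffled, projection_config()), sv)
  expect_error(project_survival(20, "F", lt, projection_config()),
               "outside the life table")
})

test_that("an SMR multiplier scales the projected death rates", {
  lt <- const_lifetable(0.05)
  cfg2 <- projection_config(smr = 2)
  sv <- project_survival(60, "M", lt, cfg2)
  expect_equal(sv$surv[1], 1 - 0.1)
  expect_equal(sv$surv[2], (1 - 0.1)^2)
})

test_that("undiscounted full-survival projection counts utility-years exactly", {
  # S = 1 for exactly 2 cycles, u = 1, r = 0 -> adds 2.0
  surv <- data.frame(cycle = 1:2, time = c(1.5, 2.5), surv = c(1, 1))
  cfg <- projection_config(discount_rate = 0)
  q <- project_qaly(72, "M", 1, const_norms(1), surv, cfg)
  expect_equal(q, 2)
  # discounting strictly reduces it
  cfg_d <- projection_config(discount_rate = 0.035)
  expect_lt(project_qaly(72, "M", 1, const_norms(1), surv, cfg_d), q)
  # zero rows: nothing added
  expect_equal(project_qaly(72, "M", 1, const_norms(1), surv[0, ], cfg), 0)
})

test_that("projection matches fine-grid integration within half-cycle tolerance", {
  lt <- const_lifetable(0.08)
  cfg <- projection_config(discount_rate = 0.035)
  norms <- make_synthetic_utility_norms()
  age <- 72; u6m <- 0.72
  sv <- project_survival(age, "F", lt, cfg)
  q <- project_qaly(age, "F", u6m, norms, sv, cfg)
  # continuous-time oracle on a fine grid: S(t) = 0.92^(t - 0.5), u(t) as
  # documented, discounted from the landmark
  tt <- seq(0.5, 0.5 + nrow(sv), by = 1 / 512)
  S <- 0.92^(tt - 0.5)
  u_of_t <- ifelse(tt <= 1, u6m,
                   ifelse(tt < 2, u6m + (tt - 1) * (approx(norms$age,
                          norms$utility, age + 2)$y - u6m),
                          approx(norms$age, norms$utility, age + tt)$y))
  disc <- 1.035^(-(tt - 0.5))
  integrand <- S * u_of_t * disc
  oracle <- sum(diff(tt) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  expect_lt(abs(q - oracle) / oracle, 0.02)
})

test_that("frozen and norm-interpolated utility paths agree when norms equal u6m", {
  surv <- data.frame(cycle = 1:30, time = 0.5 + 1:30, surv = 0.9^(1:30))
  u6m <- 0.67
  q_interp <- project_qaly(72, "M", u6m, const_norms(u6m), surv,
                           projection_config(qol_mode = "interpolate_to_norms"))
  q_frozen <- project_qaly(72, "M", u6m, const_norms(u6m), surv,
                           projection_config(qol_mode = "frozen_6m"))
  expect_identical(q_interp, q_frozen)
})

test_that("zero post-landmark survival reproduces the 6-month estimate exactly", {
  tr <- generate_trial(small_design(seed = 19, missing_prob_30d = 0.1,
                                    missing_prob_6m = 0.1))
  cfg <- projection_config(half_cycle_correction = FALSE)
  est6 <- cea_6m(tr, m = 2, seed = 3)
  est_l <- lifetime_cea(tr, lt = const_lifetable(1),
                        norms = const_norms(0.7), cfg = cfg, m = 2, seed = 3)
  expect_equal(est_l$delta_cost, est6$delta_cost)
  expect_equal(est_l$delta_qaly, est6$delta_qaly)
  expect_equal(est_l$cov, est6$cov)
})

test_that("lifetime QALYs add projections only for 6-month survivors", {
  tr <- generate_trial(small_design(seed = 23, missing_prob_30d = 0,
                                    missing_prob_6m = 0))
  q6 <- compute_qalys(tr)$qaly
  lt <- make_synthetic_lifetable()
  norms <- make_synthetic_utility_norms()
  ql <- lifetime_qalys(tr, q6, lt, norms, projection_config())
  dead <- !is.na(tr$death_time_days)
  expect_identical(ql[dead], q6[dead])
  expect_true(all(ql[!dead] > q6[!dead]))
  # discounting monotonicity at the patient level
  ql0 <- lifetime_qalys(tr, q6, lt, norms,
                        projection_config(discount_rate = 0))
  expect_true(all(ql0[!dead] > ql[!dead]))
})

test_that("life-table and norms files validate and round-trip", {
  lt <- make_synthetic_lifetable()
  path <- tempfile(fileext = ".csv")
  write.csv(lt, path, row.names = FALSE)
  expect_equal(read_life_table(path)$qx, lt$qx)
  bad <- data.frame(age = c(50, 52), sex = "M", qx = c(0.1, 1))
  expect_error(life_table(bad), "contiguous")
  bad2 <- data.frame(age = 50:51, sex = "M", qx = c(0.1, 0.2))
  expect_error(life_table(bad2), "terminal age")
  expect_error(life_table(data.frame(age = 50:51, sex = "M", qx = c(2, 1))),
               "qx must be in")
})
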