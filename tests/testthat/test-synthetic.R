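test_that("design validation names the offending field", {
  expect_error(trial_design(n_per_arm = 0), "n_per_arm")
  expect_error(trial_design(baseline_mortality_6m = c(0.1, 1.2)),
               "baseline_mortality_6m")
  expect_error(trial_design(cost_shape = -1), "cost_shape")
  expect_error(trial_design(missing_prob_30d = 2), "missing_prob_30d")
  expect_error(trial_design(utility_autocorrelation = 1),
               "utility_autocorrelation")
})

test_that("ground truth echoes the generating parameters", {
  d <- trial_design(true_delta_cost = -400, true_delta_qaly = 0.01)
  gt <- ground_truth(d)
  expect_equal(gt$delta_cost, -400)
  expect_equal(gt$delta_qaly, 0.01)
  expect_equal(unname(gt$mortality_6m), c(0.076, 0.115))
  d0 <- trial_design(true_delta_cost = 0, true_delta_qaly = 0)
  expect_equal(ground_truth(d0)$delta_cost, 0)
  expect_equal(ground_truth(d0)$delta_qaly, 0)
  d2 <- trial_design(true_delta_cost = 123.4, true_delta_qaly = -0.02)
  expect_equal(ground_truth(d2)$delta_cost, 123.4)
  expect_equal(ground_truth(d2)$delta_qaly, -0.02)
})

test_that("identical seeds give byte-identical datasets", {
  d <- small_design(seed = 77)
  expect_identical(generate_trial(d), generate_trial(d))
  d2 <- small_design(seed = 78)
  expect_false(identical(generate_trial(d), generate_trial(d2)))
})

test_that("structure invariants hold: sizes, sites, recruitment order, arms", {
  d <- small_design(seed = 5)
  tr <- generate_trial(d)
  expect_equal(nrow(tr), 2 * d$n_per_arm)
  expect_true(all(tr$site_id %in% seq_len(d$n_sites)))
  expect_equal(sum(tr$arm == "intervention"), d$n_per_arm)
  for (s in unique(tr$site_id)) {
    ord <- sort(tr$recruitment_order_in_site[tr$site_id == s])
    expect_equal(ord, seq_along(ord))
  }
  expect_true(all(tr$age >= 50))
  expect_true(all(tr$dopexamine_mg[tr$arm == "usual_care"] == 0))
  qty <- c("cc_level2_days", "cc_level3_days", "ward_days", "dopexamine_mg",
           "crystalloid_ml", "colloid_ml", "blood_ml")
  for (cl in qty) expect_true(all(tr[[cl]] >= 0))
  dead <- !is.na(tr$death_time_days)
  expect_true(all(tr$death_time_days[dead] > 0 &
                    tr$death_time_days[dead] <= 182.625))
  # no EQ-5D observations after death
  expect_true(all(is.na(tr$eq5d_6m[dead])))
  expect_true(all(is.na(tr$eq5d_30d[dead & tr$death_time_days <= 30.4375])))
})

test_that("arm mortality matches the design within 3 binomial SEs", {
  d <- trial_design(seed = 2024)  # full size n = 734
  tr <- generate_trial(d)
  for (a in c("intervention", "usual_care")) {
    p_hat <- mean(!is.na(tr$death_time_days[tr$arm == a]))
    p <- d$baseline_mortality_6m[[a]]
    se <- sqrt(p * (1 - p) / d$n_per_arm)
    expect_lt(abs(p_hat - p), 3 * se)
  }
})

test_that("zero missingness probabilities leave survivors fully observed", {
  tr <- generate_trial(small_design(missing_prob_30d = 0, missing_prob_6m = 0))
  alive30 <- is.na(tr$death_time_days) | tr$death_time_days > 30.4375
  alive6m <- is.na(tr$death_time_days)
  expect_false(anyNA(tr$eq5d_30d[alive30]))
  expect_false(anyNA(tr$eq5d_6m[alive6m]))
  expect_false(anyNA(tr$eq5d_random))
})

test_that("missingness is MAR: independent of the masked value given arm and age", {
  d <- trial_design(n_per_arm = 1500, n_sites = 10, seed = 314,
                    missing_prob_30d = 0.2, missing_prob_6m = 0.2)
  masked <- generate_trial(d)
  full <- generate_trial(d, mask_missing = FALSE)
  alive6m <- is.na(full$death_time_days)
  miss <- as.numeric(is.na(masked$eq5d_6m[alive6m]))
  u_true <- full$eq5d_6m[alive6m]
  fit <- glm(miss ~ u_true + arm + age, family = binomial,
             data = data.frame(miss = miss, u_true = u_true,
                               arm = full$arm[alive6m],
                               age = full$age[alive6m]))
  z <- summary(fit)$coefficients["u_true", "z value"]
  expect_lt(abs(z), 3)
  # and missingness does depend on the observed predictors
  expect_gt(mean(miss), 0.1)
})

test_that("costs are right-skewed and utilities respect the value-set range", {
  tr <- generate_trial(trial_design(n_per_arm = 500, n_sites = 8, seed = 8))
  total <- compute_costs(tr)$total
  for (a in c("intervention", "usual_care")) {
    x <- total[tr$arm == a]
    skew <- mean((x - mean(x))^3) / sd(x)^3
    expect_gt(skew, 0)
  }
  vs <- default_value_set()
  for (cl in c("eq5d_random", "eq5d_30d", "eq5d_6m")) {
    expect_true(all(tr[[cl]] >= vs$floor - 1e-12, na.rm = TRUE))
    expect_true(all(tr[[cl]] <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("generated cost components reproduce the target arm means through costing", {
  d <- trial_design(n_per_arm = 4000, n_sites = 10, seed = 21,
                    missing_prob_30d = 0, missing_prob_6m = 0)
  tr <- generate_trial(d)
  total <- compute_costs(tr)$total
  m_int <- mean(total[tr$arm == "intervention"])
  m_uc <- mean(total[tr$arm == "usual_care"])
  se_diff <- sqrt(var(total[tr$arm == "intervention"]) / d$n_per_arm +
                    var(total[tr$arm == "usual_care"]) / d$n_per_arm)
  expect_lt(abs((m_int - m_uc) - d$true_delta_cost), 3 * se_diff)
  expect_lt(abs(m_uc - d$mean_cost_usual), 3 * sd(total) / sqrt(d$n_per_arm))
})

test_that("profile back-conversion yields valid profiles scoring close to the index", {
  tr <- generate_trial(small_design(), profiles = TRUE)
  vs <- default_value_set()
  ok <- !is.na(tr$eq5d_6m)
  expect_true(all(tr$eq5d_6m[ok] %in% eq5d_all_profiles()))
  tr_num <- generate_trial(small_design())
  rescored <- eq5d_index(tr$eq5d_6m[ok], vs)
  expect_lt(max(abs(rescored - tr_num$eq5d_6m[ok])), 0.15)
})

test_that("trial CSV round-trips with empty fields for missing values", {
  tr <- generate_trial(small_design())
  path <- tempfile(fileext = ".csv")
  write_trial(tr, path)
  tr2 <- read_trial(path)
  expect_equal(tr2$eq5d_6m, tr$eq5d_6m)
  expect_equal(tr2$death_time_days, tr$death_time_days)
  expect_identical(tr2$monitor_used, tr$monitor_used)
  expect_equal(nrow(tr2), nrow(tr))
})
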