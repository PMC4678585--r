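fake_fit <- function(dc, dq, vc = 1, vq = 1, cv = 0) {
  structure(list(delta_cost = dc, delta_qaly = dq,
                 cov = matrix(c(vc, cv, cv, vq), 2, 2),
                 resid_cor = 0, n = 100),
            class = "bivariate_fit")
}

test_that("Rubin pooling matches the closed form", {
  # m = 2, estimates 1 and 3, within-variance 1 each -> pooled 2, total 4
  pooled <- pool_estimates(list(fake_fit(1, 1), fake_fit(3, 3)))
  expect_equal(pooled$delta_cost, 2)
  expect_equal(pooled$delta_qaly, 2)
  expect_equal(pooled$cov[1, 1], 1 + 1.5 * 2)
  expect_equal(pooled$cov[2, 2], 4)
  # identical estimates: between-variance 0, total = within
  same <- pool_estimates(list(fake_fit(5, 0.1, vc = 2, vq = 3),
                              fake_fit(5, 0.1, vc = 2, vq = 3)))
  expect_equal(same$cov, matrix(c(2, 0, 0, 3), 2, 2))
})

test_that("Rubin pooling matches an independent element-wise recomputation", {
  set.seed(88)
  m <- 7
  fits <- lapply(seq_len(m), function(i) {
    cv <- runif(1, -0.3, 0.3)
    fake_fit(rnorm(1, 100, 50), rnorm(1, 0.02, 0.01),
             vc = runif(1, 0.5, 2), vq = runif(1, 0.5, 2), cv = cv)
  })
  pooled <- pool_estimates(fits)
  est <- sapply(fits, function(f) c(f$delta_cost, f$delta_qaly))
  q_bar <- rowMeans(est)
  w_bar <- Reduce(`+`, lapply(fits, function(f) f$cov)) / m
  b_mat <- matrix(0, 2, 2)
  for (i in seq_len(m)) {
    dev <- est[, i] - q_bar
    b_mat <- b_mat + outer(dev, dev)
  }
  b_mat <- b_mat / (m - 1)
  expect_equal(pooled$delta_cost, q_bar[1])
  expect_equal(pooled$delta_qaly, q_bar[2])
  expect_equal(pooled$cov, w_bar + (1 + 1 / m) * b_mat)
})

test_that("net benefit arithmetic and linearity in lambda are exact", {
  est <- ce_estimate(0, 0.2, diag(c(100, 1e-4)))
  expect_equal(inb(est, 20000)$mean, 4000)
  est2 <- ce_estimate(-404, 0.01, diag(c(100, 1e-4)))
  expect_equal(inb(est2, 20000)$mean, 604)  # rounded published inputs
  expect_equal(inb(est2, 0)$mean, 404)      # lambda = 0: INB = -delta cost
  # linearity: INB(l2) - INB(l1) = (l2 - l1) * delta QALY, exactly
  set.seed(3)
  for (i in 1:10) {
    e <- ce_estimate(rnorm(1, 0, 500), rnorm(1, 0, 0.1), diag(c(1, 1e-6)))
    l <- sort(runif(2, 0, 5e4))
    expect_equal(inb(e, l[2])$mean - inb(e, l[1])$mean,
                 (l[2] - l[1]) * e$delta_qaly)
  }
  # variance composition
  e <- ce_estimate(100, 0.02, matrix(c(400, 0.5, 0.5, 0.01), 2, 2))
  l <- 30000
  expect_equal(inb(e, l)$se,
               sqrt(l^2 * 0.01 + 400 - 2 * l * 0.5))
})

test_that("CEAC has the right limits, symmetry point and dominance behaviour", {
  e <- ce_estimate(200, 0.02, matrix(c(500^2, 2, 2, 0.01^2), 2, 2))
  cc <- ceac(e, c(0, 1e4, 2e4, 1e7))
  expect_true(all(cc$prob_ce >= 0 & cc$prob_ce <= 1))
  expect_equal(cc$prob_ce[1], pnorm(-e$delta_cost / 500))     # P(dCost < 0)
  expect_equal(cc$prob_ce[4], pnorm(e$delta_qaly / 0.01),
               tolerance = 1e-3)                               # P(dQALY > 0)
  # mean INB zero -> probability one half
  lam0 <- e$delta_cost / e$delta_qaly
  expect_equal(ceac(e, lam0)$prob_ce, 0.5)
  # dominance with tiny variances
  dom <- ce_estimate(-500, 0.05, diag(c(1e-6, 1e-12)))
  expect_true(all(ceac(dom, seq(0, 5e4, 1e4))$prob_ce > 1 - 1e-9))
  # degenerate variance: 0/1 step with a warning
  expect_warning(z <- ceac(ce_estimate(-10, 0, diag(c(0, 0))), c(0, 1e4)),
                 "zero INB variance")
  expect_equal(z$prob_ce, c(1, 1))
})

test_that("normal CEAC agrees with a 1e5-draw Monte-Carlo within 0.005", {
  e <- ce_estimate(-404, 0.01, matrix(c(464^2, -0.8, -0.8, 0.0051^2), 2, 2))
  set.seed(1234)
  L <- chol(e$cov)
  draws <- matrix(rnorm(2e5), ncol = 2) %*% L
  dc <- draws[, 1] + e$delta_cost
  dq <- draws[, 2] + e$delta_qaly
  grid <- seq(0, 5e4, by = 2500)
  mc <- vapply(grid, function(l) mean(l * dq - dc > 0), numeric(1))
  expect_lt(max(abs(ceac(e, grid)$prob_ce - mc)), 0.005)
})

test_that("independent outcomes show no spurious cross-equation correlation", {
  d <- trial_design(n_per_arm = 300, n_sites = 6, seed = 60,
                    missing_prob_30d = 0, missing_prob_6m = 0)
  tr <- generate_trial(d)
  tr$total_cost <- compute_costs(tr)$total
  tr$qaly <- compute_qalys(tr)$qaly
  f <- fit_bivariate(tr)
  expect_lt(abs(f$resid_cor), 3 / sqrt(nrow(tr)))
  expect_equal(dim(f$cov), c(2L, 2L))
  expect_equal(f$cov[1, 2], f$cov[2, 1])
})

test_that("collinear covariates produce an informative error", {
  tr <- generate_trial(small_design(missing_prob_30d = 0, missing_prob_6m = 0))
  tr$total_cost <- compute_costs(tr)$total
  tr$qaly <- compute_qalys(tr)$qaly
  tr$age_copy <- tr$age
  expect_error(
    fit_bivariate(tr, covariates = c("age", "age_copy", "eq5d_random")),
    "rank deficient.*age_copy")
})

test_that("an irrelevant covariate leaves treatment estimates essentially unchanged", {
  diffs <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    d <- trial_design(n_per_arm = 150, n_sites = 4, seed = 700 + r,
                      missing_prob_30d = 0, missing_prob_6m = 0)
    tr <- generate_trial(d)
    tr$total_cost <- compute_costs(tr)$total
    tr$qaly <- compute_qalys(tr)$qaly
    set.seed(r)
    tr$noise <- rnorm(nrow(tr))
    f0 <- fit_bivariate(tr, covariates = c("age", "sex", "eq5d_random"),
                        site_mode = "fixed_cluster")
    f1 <- fit_bivariate(tr, covariates = c("age", "sex", "eq5d_random",
                                           "noise"),
                        site_mode = "fixed_cluster")
    diffs[r, ] <- c(f1$delta_cost - f0$delta_cost,
                    f1$delta_qaly - f0$delta_qaly)
  }
  # pure-noise adjustment shifts estimates by far less than their scale
  expect_lt(abs(mean(diffs[, 1])), 50)
  expect_lt(abs(mean(diffs[, 2])), 0.002)
})

test_that("both site modes recover the design contrast on one large trial", {
  d <- trial_design(n_per_arm = 1000, n_sites = 10, seed = 4242,
                    missing_prob_30d = 0, missing_prob_6m = 0)
  tr <- generate_trial(d)
  tr$total_cost <- compute_costs(tr)$total
  tr$qaly <- compute_qalys(tr)$qaly
  for (mode in c("random_intercept", "fixed_cluster")) {
    f <- fit_bivariate(tr, site_mode = mode)
    expect_lt(abs(f$delta_cost - d$true_delta_cost),
              3 * sqrt(f$cov[1, 1]))
    expect_lt(abs(f$delta_qaly - d$true_delta_qaly),
              3 * sqrt(f$cov[2, 2]))
  }
})

test_that("ce_estimate validates its covariance", {
  expect_error(ce_estimate(1, 1, matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(ce_estimate(1, 1, matrix(c(-1, 0, 0, 1), 2, 2)),
               "non-negative")
  expect_error(ce_estimate(1, 1, matrix(c(1, 2, 2, 1), 2, 2)),
               "correlation")
})

test_that("subgroup levels partition the trial and a single level matches overall", {
  tr <- generate_trial(small_design(seed = 33, missing_prob_30d = 0.1,
                                    missing_prob_6m = 0.1))
  ests <- suppressWarnings(
    subgroup_cea(tr, "surgery_category", m = 2, seed = 9))
  sizes <- vapply(names(ests), function(l) sum(tr$surgery_category == l),
                  numeric(1))
  skipped <- setdiff(unique(tr$surgery_category), names(ests))
  expect_equal(sum(sizes) + sum(tr$surgery_category %in% skipped), nrow(tr))

  # a factor with one level reproduces the overall analysis
  tr1 <- tr
  tr1$urgency <- "elective"
  est_sub <- subgroup_cea(tr1, "urgency", m = 2, seed = 9)
  covs <- c("age", "sex", "surgery_category", "postop_location", "asa_grade",
            "renal_impairment", "diabetes", "cardioresp_risk", "eq5d_random")
  est_all <- cea_6m(tr1, m = 2, seed = 9, covariates = covs)
  expect_equal(est_sub$elective$delta_cost, est_all$delta_cost)
  expect_equal(est_sub$elective$delta_qaly, est_all$delta_qaly)
  expect_equal(est_sub$elective$cov, est_all$cov)
})

test_that("a built-in subgroup cost contrast is recovered with the right sign", {
  d <- trial_design(n_per_arm = 400, n_sites = 6, seed = 1001,
                    missing_prob_30d = 0, missing_prob_6m = 0)
  tr <- generate_trial(d)
  # inject an extra intervention cost only for upper-GI surgery
  bump <- tr$arm == "intervention" & tr$surgery_category == "upper_GI"
  tr$ward_days[bump] <- tr$ward_days[bump] + 3000 / default_unit_costs()$ward_day
  ests <- suppressWarnings(
    subgroup_cea(tr, "surgery_category", m = 2, seed = 10))
  expect_gt(ests$upper_GI$delta_cost, ests$lower_GI$delta_cost)
  expect_gt(ests$upper_GI$delta_cost - ests$lower_GI$delta_cost, 1000)
})
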