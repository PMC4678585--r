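#' Joint cost-effectiveness estimate
#'
#' The central result object: incremental mean cost and incremental mean QALY
#' for intervention vs usual care, together with the 2x2 covariance of the
#' two estimates.  Everything downstream — net monetary benefit, acceptability
#' curves, value of information — is a function of these five numbers.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qaly incremental QALYs.
#' @param cov 2x2 covariance matrix of `(delta_cost, delta_qaly)`.
#' @param n_imputations imputations pooled over (1 for complete data).
#' @param label analysis identifier.
#' @return Object of class `ce_estimate`.
#' @export
ce_estimate <- function(delta_cost, delta_qaly, cov, n_imputations = 1,
                        label = "cea") {
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(2, 2))) stop("cov must be a 2x2 matrix")
  if (max(abs(cov - t(cov))) > 1e-6 * max(1, max(abs(cov)))) {
    stop("cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  if (any(diag(cov) < 0)) stop("cov must have non-negative variances")
  denom <- sqrt(prod(diag(cov)))
  if (denom > 0 && abs(cov[1, 2]) > denom * (1 + 1e-8)) {
    stop("cov implies a correlation outside [-1, 1]")
  }
  structure(
    list(delta_cost = delta_cost, delta_qaly = delta_qaly, cov = cov,
         n_imputations = n_imputations, label = label),
    class = "ce_estimate"
  )
}

#' @export
print.ce_estimate <- function(x, lambda = 20000, ...) {
  ci_c <- x$delta_cost + c(-1, 1) * 1.959964 * sqrt(x$cov[1, 1])
  ci_q <- x$delta_qaly + c(-1, 1) * 1.959964 * sqrt(x$cov[2, 2])
  cat("Cost-effectiveness estimate [", x$label, "]\n", sep = "")
  cat(sprintf("  incremental cost : %8.0f (%.0f to %.0f) GBP\n",
              x$delta_cost, ci_c[1], ci_c[2]))
  cat(sprintf("  incremental QALY : %8.3f (%.3f to %.3f)\n",
              x$delta_qaly, ci_q[1], ci_q[2]))
  b <- inb(x, lambda)
  cat(sprintf("  INB at %0.0f/QALY: %8.0f (%.0f to %.0f) GBP\n",
              lambda, b$mean, b$ci_lower, b$ci_upper))
  invisible(x)
}

#' Bivariate regression of cost and QALY on treatment
#'
#' Fits the cost and QALY equations with identical regressors — treatment
#' arm, the pre-specified covariates and the site effect.  With identical
#' regressors the seemingly-unrelated-regression point estimates coincide
#' with per-equation least squares, so each equation is fitted separately and
#' the cross-equation covariance of the two treatment coefficients is
#' estimated from the residual cross-correlation:
#' `cov = r * se_cost * se_qaly`.
#'
#' @param data completed (no missing outcome) data.frame holding `total_cost`,
#'   `qaly`, `arm`, `site_id` and the covariate columns.
#' @param covariates character vector of adjustment columns.  The default is
#'   the trial's pre-specified set: age, sex, urgency, surgical category,
#'   post-operative location, ASA grade, renal impairment, diabetes,
#'   cardiac/respiratory risk and the randomisation EQ-5D score.
#' @param site_mode `"random_intercept"` (default): per-equation linear mixed
#'   models with a random intercept per site.  `"fixed_cluster"`: site fixed
#'   effects with cluster-robust (by site) standard errors.
#' @return list of class `bivariate_fit`: `delta_cost`, `delta_qaly`, `cov`,
#'   `resid_cor`, `n`.
#' @export
fit_bivariate <- function(data,
                          covariates = c("age", "sex", "urgency",
                                         "surgery_category", "postop_location",
                                         "asa_grade", "renal_impairment",
                                         "diabetes", "cardioresp_risk",
                                         "eq5d_random"),
                          site_mode = c("random_intercept", "fixed_cluster")) {
  site_mode <- match.arg(site_mode)
  need <- c("total_cost", "qaly", "arm", "site_id", covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data$total_cost) || anyNA(data$qaly)) {
    stop("both outcomes must be complete; run impute_trial() first")
  }
  data$..arm <- as.numeric(data$arm == "intervention")
  rhs_terms <- c("..arm", covariates)
  rhs <- paste(rhs_terms, collapse = " + ")
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[-seq_len(qrm$rank)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }

  if (site_mode == "random_intercept") {
    fit_one <- function(outcome) {
      f <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | site_id)"))
      fm <- lme4::lmer(f, data = data, REML = TRUE,
                       control = lme4::lmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = lme4::.makeCC(
                           action = "ignore", tol = 1e-4)))
      list(est = lme4::fixef(fm)[["..arm"]],
           se = sqrt(as.matrix(stats::vcov(fm))["..arm", "..arm"]),
           resid = stats::residuals(fm))
    }
  } else {
    fit_one <- function(outcome) {
      f <- stats::as.formula(paste(outcome, "~", rhs, "+ factor(site_id)"))
      fm <- stats::lm(f, data = data)
      vc <- sandwich::vcovCL(fm, cluster = data$site_id)
      list(est = stats::coef(fm)[["..arm"]],
           se = sqrt(vc["..arm", "..arm"]),
           resid = stats::residuals(fm))
    }
  }
  fc <- fit_one("total_cost")
  fq <- fit_one("qaly")
  r <- stats::cor(fc$resid, fq$resid)
  cov <- matrix(c(fc$se^2, r * fc$se * fq$se,
                  r * fc$se * fq$se, fq$se^2), 2, 2)
  structure(
    list(delta_cost = fc$est, delta_qaly = fq$est, cov = cov,
         resid_cor = r, n = nrow(data)),
    class = "bivariate_fit"
  )
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Point estimate = mean over imputations; total covariance = mean
#' within-imputation covariance + (1 + 1/m) x between-imputation covariance
#' of the point estimates, applied element-wise to the 2x2 matrix.
#'
#' @param fits list of [fit_bivariate()] results (length m >= 2, or 1 for a
#'   complete-data analysis).
#' @param label analysis identifier.
#' @return A [ce_estimate()].
#' @export
pool_estimates <- function(fits, label = "pooled") {
  m <- length(fits)
  est <- vapply(fits, function(f) c(f$delta_cost, f$delta_qaly), numeric(2))
  point <- rowMeans(est)
  within <- Reduce(`+`, lapply(fits, `[[`, "cov")) / m
  if (m >= 2) {
    centred <- est - point
    between <- tcrossprod(centred) / (m - 1)
    total <- within + (1 + 1 / m) * between
  } else {
    total <- within
  }
  ce_estimate(point[1], point[2], total, n_imputations = m, label = label)
}

#' Incremental net monetary benefit
#'
#' `INB(lambda) = lambda * deltaQALY - deltaCost`; its variance follows from
#' the joint covariance:
#' `lambda^2 var(dQ) + var(dC) - 2 lambda cov(dC, dQ)`.
#'
#' @param est a [ce_estimate()].
#' @param lambda willingness to pay per QALY (GBP), >= 0.
#' @return data.frame with `lambda`, `mean`, `se`, `ci_lower`, `ci_upper`
#'   (95% normal interval).
#' @export
inb <- function(est, lambda = 20000) {
  stopifnot(inherits(est, "ce_estimate"))
  if (any(lambda < 0)) stop("lambda must be >= 0")
  mean <- lambda * est$delta_qaly - est$delta_cost
  var <- lambda^2 * est$cov[2, 2] + est$cov[1, 1] - 2 * lambda * est$cov[1, 2]
  se <- sqrt(pmax(var, 0))
  data.frame(lambda = lambda, mean = mean, se = se,
             ci_lower = mean - 1.959964 * se,
             ci_upper = mean + 1.959964 * se)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective, `P(INB(lambda) > 0)`, under a bivariate-normal
#' approximation to the joint distribution of incremental cost and QALY:
#' `Phi(mean / se)`.  At `lambda = 0` this is `P(deltaCost < 0)`; as
#' `lambda` grows it tends to `P(deltaQALY > 0)`.
#'
#' @param est a [ce_estimate()].
#' @param lambdas willingness-to-pay grid (GBP/QALY), default £0–£50,000.
#' @return data.frame of class `ceac` with columns `lambda`, `prob_ce`.
#' @export
ceac <- function(est, lambdas = seq(0, 50000, by = 500)) {
  stopifnot(inherits(est, "ce_estimate"))
  if (any(lambdas < 0)) stop("lambda grid must be non-negative")
  b <- inb(est, lambdas)
  p <- ifelse(b$se > 0, stats::pnorm(b$mean / b$se),
              as.numeric(b$mean > 0))
  if (any(b$se == 0)) {
    warning("zero INB variance at some lambda; CEAC is a 0/1 step there")
  }
  structure(data.frame(lambda = lambdas, prob_ce = p),
            class = c("ceac", "data.frame"))
}

#' Bootstrap acceptability curve
#'
#' Non-parametric alternative to the normal-approximation [ceac()]: patients
#' are resampled with replacement within site, the bivariate fit is re-run on
#' each resample, and the curve is the proportion of resamples with positive
#' INB.  Used to check skew sensitivity; the normal curve is the base case.
#'
#' @param data completed analysis data.frame (as for [fit_bivariate()]).
#' @param lambdas willingness-to-pay grid.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param ... passed to [fit_bivariate()].
#' @return data.frame with `lambda`, `prob_ce`.
#' @export
ceac_bootstrap <- function(data, lambdas = seq(0, 50000, by = 2500),
                           B = 200, seed = 1L, ...) {
  set.seed(seed)
  idx_by_site <- split(seq_len(nrow(data)), data$site_id)
  draws <- matrix(NA_real_, nrow = B, ncol = 2)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_site, function(i) {
      sample(i, length(i), replace = TRUE)
    }))
    f <- fit_bivariate(data[idx, , drop = FALSE], ...)
    draws[b, ] <- c(f$delta_cost, f$delta_qaly)
  }
  prob <- vapply(lambdas, function(l) {
    mean(l * draws[, 2] - draws[, 1] > 0)
  }, numeric(1))
  data.frame(lambda = lambdas, prob_ce = prob)
}

#' Six-month cost-effectiveness pipeline
#'
#' Runs the within-trial analysis end to end: per-patient costs, multiple
#' imputation of missing utilities, per-imputation QALY construction and
#' bivariate fit, and Rubin pooling.
#'
#' @param trial trial data.frame.
#' @param uc unit-cost table.
#' @param vs value set.
#' @param m imputations.
#' @param seed master seed for the imputation.
#' @param baseline_rule,decedent_rule QALY construction rules, see
#'   [build_trajectory()].
#' @param sensitivity cost sensitivity options, see [compute_costs()].
#' @param site_mode,covariates passed to [fit_bivariate()].
#' @param imputations optionally, a pre-computed [impute_trial()] result to
#'   reuse (so sensitivity scenarios share the same imputations and differ
#'   only in the toggled assumption).
#' @param label analysis identifier.
#' @return A [ce_estimate()]; the imputation object is attached as
#'   `attr(, "imputations")` for reuse.
#' @export
cea_6m <- function(trial, uc = default_unit_costs(), vs = default_value_set(),
                   m = 20, seed = 1L,
                   baseline_rule = "day30",
                   decedent_rule = "zero_at_timepoints",
                   sensitivity = character(),
                   site_mode = "random_intercept",
                   covariates = NULL,
                   imputations = NULL, label = "6m") {
  costs <- compute_costs(trial, uc, sensitivity = sensitivity)
  if (is.null(imputations)) {
    base_costs <- compute_costs(trial, uc)  # predictor uses base-case cost
    imputations <- impute_trial(trial, m = m, seed = seed, costs = base_costs,
                                vs = vs)
  }
  fits <- lapply(imputations, function(comp) {
    q <- compute_qalys(comp, vs, baseline_rule = baseline_rule,
                       decedent_rule = decedent_rule)
    comp$qaly <- q$qaly
    comp$total_cost <- costs$total
    if (is.null(covariates)) fit_bivariate(comp, site_mode = site_mode)
    else fit_bivariate(comp, covariates = covariates, site_mode = site_mode)
  })
  est <- pool_estimates(fits, label = label)
  attr(est, "imputations") <- imputations
  est
}

#' Pre-specified subgroup analyses
#'
#' Re-runs the 6-month pipeline within levels of urgency of surgery, surgical
#' category, or recruitment timing (the first ten patients recruited at each
#' site versus all subsequent patients).  Imputation is performed once on the
#' full dataset and each subgroup is analysed on the corresponding subset of
#' every completed dataset, so subgroup contrasts are not distorted by
#' subgroup-specific imputation models.
#'
#' @param trial trial data.frame.
#' @param factor one of `"urgency"`, `"surgery_category"`,
#'   `"recruitment_timing"`.
#' @param ... passed to [cea_6m()].
#' @return named list of [ce_estimate()]s, one per retained level; levels
#'   with fewer than 2 patients in either arm are skipped with a warning.
#' @export
subgroup_cea <- function(trial, factor = c("urgency", "surgery_category",
                                           "recruitment_timing"), ...) {
  factor <- match.arg(factor)
  lev <- switch(factor,
    urgency = trial$urgency,
    surgery_category = trial$surgery_category,
    recruitment_timing = ifelse(trial$recruitment_order_in_site <= 10,
                                "first_ten", "subsequent"))
  args <- list(...)
  m <- if (!is.null(args$m)) args$m else 20
  seed <- if (!is.null(args$seed)) args$seed else 1L
  uc <- if (!is.null(args$uc)) args$uc else default_unit_costs()
  vs <- if (!is.null(args$vs)) args$vs else default_value_set()
  extra <- args[setdiff(names(args), c("m", "seed", "uc", "vs",
                                       "imputations", "covariates", "label"))]
  imps <- impute_trial(trial, m = m, seed = seed,
                       costs = compute_costs(trial, uc), vs = vs)
  # drop covariates that cannot be adjusted for inside a level of themselves
  covs <- c("age", "sex", "surgery_category", "postop_location", "asa_grade",
            "renal_impairment", "diabetes", "cardioresp_risk", "eq5d_random")
  if (factor != "surgery_category") covs <- c(covs, "urgency")
  covs <- setdiff(covs, factor)
  out <- list()
  for (l in unique(lev)) {
    sel <- lev == l
    tab <- table(trial$arm[sel])
    if (length(tab) < 2 || any(tab < 2)) {
      warning("subgroup level '", l, "' has fewer than 2 patients per arm; skipped")
      next
    }
    sub_imps <- structure(lapply(imps, function(d) d[sel, , drop = FALSE]),
                          m = attr(imps, "m"), seed = attr(imps, "seed"),
                          class = "imputed_trial")
    # a covariate constant within the level cannot be adjusted for
    drop_constant <- function(cv_set) {
      cv_set[vapply(cv_set, function(cv) {
        length(unique(trial[[cv]][sel])) >= 2
      }, logical(1))]
    }
    run_level <- function(cv_set) {
      do.call(cea_6m, c(
        list(trial[sel, , drop = FALSE], uc = uc, vs = vs, m = m, seed = seed,
             imputations = sub_imps, covariates = drop_constant(cv_set),
             label = paste0(factor, ":", l)),
        extra))
    }
    est <- tryCatch(run_level(covs), error = function(e) {
      # small level: fall back to a core adjustment set
      warning("subgroup level '", l, "' cannot support the full covariate ",
              "set (", conditionMessage(e), "); adjusted for age, sex and ",
              "baseline EQ-5D only")
      tryCatch(run_level(c("age", "sex", "eq5d_random")), error = function(e2) {
        warning("subgroup level '", l, "' could not be analysed: ",
                conditionMessage(e2))
        NULL
      })
    })
    if (!is.null(est)) out[[as.character(l)]] <- est
  }
  out
}
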