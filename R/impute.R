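#' Multiple imputation of missing EQ-5D utilities
#'
#' Chained-equation imputation assuming the utilities are missing at random.
#' Each incomplete utility column (`eq5d_random`, `eq5d_30d`, `eq5d_6m`,
#' restricted to patients alive at the assessment — post-death values are
#' structural, not missing) is imputed by Bayesian predictive mean matching:
#' the regression of the variable on arm, covariates, the other observed
#' utilities and total cost is fitted on the currently-complete rows, the
#' coefficients are drawn from their posterior, and each missing value takes
#' the observed value of a donor sampled from the `donors` cases whose
#' posterior-drawn predictions lie closest — so imputed utilities always lie
#' in the observed support of the value set.  The chain cycles `n_cycles`
#' sweeps, and the whole procedure is repeated `m` times with per-imputation
#' seeds derived from the master seed.
#'
#' @param trial trial data.frame with numeric EQ-5D index columns.
#' @param m number of imputations (>= 2).
#' @param seed master seed; imputation `j` uses `seed + j`.
#' @param costs optional per-patient cost data.frame from [compute_costs()]
#'   whose `total` enters the predictor set (recommended).
#' @param n_cycles chained-equation sweeps per imputation.
#' @param donors predictive-mean-matching donor pool size.
#' @param vs value set (retained for interface symmetry; donor values are
#'   observed indices and already lie in its range).
#' @return Object of class `imputed_trial`: a list of `m` completed trial
#'   data.frames, with attributes `m` and `seed`.
#' @export
impute_trial <- function(trial, m = 20, seed = 1L, costs = NULL,
                         n_cycles = 5, donors = 5,
                         vs = default_value_set()) {
  if (m < 2) stop("m must be >= 2 for multiple imputation")
  ucols <- c("eq5d_random", "eq5d_30d", "eq5d_6m")
  for (cl in ucols) {
    if (!is.numeric(trial[[cl]])) {
      stop("impute_trial needs numeric EQ-5D index columns; score profiles ",
           "through eq5d_index() first")
    }
  }
  dead <- !is.na(trial$death_time_days)
  alive_at <- cbind(
    eq5d_random = rep(TRUE, nrow(trial)),
    eq5d_30d = !dead | trial$death_time_days > DAYS_PER_MONTH,
    eq5d_6m = !dead
  )
  need <- lapply(ucols, function(cl) is.na(trial[[cl]]) & alive_at[, cl])
  names(need) <- ucols
  targets <- ucols[vapply(need, any, logical(1))]
  for (cl in targets) {
    if (all(is.na(trial[[cl]][alive_at[, cl]]))) {
      stop("cannot impute ", cl, ": no observed values among patients alive ",
           "at that assessment")
    }
  }

  pred_frame <- data.frame(
    arm = as.numeric(trial$arm == "intervention"),
    age = trial$age,
    sex = as.numeric(trial$sex == "M"),
    urgency = as.numeric(trial$urgency == "non_elective"),
    asa_grade = trial$asa_grade,
    renal = as.numeric(trial$renal_impairment),
    diabetes = as.numeric(trial$diabetes),
    cardioresp = as.numeric(trial$cardioresp_risk)
  )
  if (!is.null(costs)) pred_frame$total_cost <- costs$total / 1000

  draw_imputation <- function(j) {
    set.seed(as.integer(seed) + j)
    comp <- trial
    if (length(targets) == 0) return(comp)
    # initialise missing entries from the observed marginal distribution
    for (cl in targets) {
      obs <- comp[[cl]][!is.na(comp[[cl]])]
      comp[[cl]][need[[cl]]] <- sample(obs, sum(need[[cl]]), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (cl in targets) {
        others <- setdiff(ucols, cl)
        X <- as.matrix(cbind(1, pred_frame,
                             comp[others][, , drop = FALSE]))
        X[is.na(X)] <- 0  # structural post-death utilities enter as 0
        rows_fit <- alive_at[, cl] & !need[[cl]]
        y <- comp[[cl]][rows_fit]
        Xf <- X[rows_fit, , drop = FALSE]
        qrX <- qr(Xf)
        keep <- qrX$pivot[seq_len(qrX$rank)]
        Xf <- Xf[, keep, drop = FALSE]
        fit <- stats::lm.fit(Xf, y)
        res <- fit$residuals
        df <- length(y) - ncol(Xf)
        sigma2 <- sum(res^2) / stats::rchisq(1, df)
        XtXinv <- chol2inv(chol(crossprod(Xf)))
        beta <- fit$coefficients +
          drop(crossprod(chol(sigma2 * XtXinv), stats::rnorm(ncol(Xf))))
        # predictive mean matching: donors ranked by posterior-drawn predictions
        pred_obs <- drop(Xf %*% beta)
        pred_mis <- drop(X[need[[cl]], keep, drop = FALSE] %*% beta)
        k <- min(donors, length(y))
        comp[[cl]][need[[cl]]] <- vapply(pred_mis, function(p) {
          pool <- order(abs(pred_obs - p))[seq_len(k)]
          y[pool[sample.int(k, 1)]]
        }, numeric(1))
      }
    }
    comp
  }

  out <- lapply(seq_len(m), draw_imputation)
  structure(out, m = m, seed = seed, class = "imputed_trial")
}

#' @export
print.imputed_trial <- function(x, ...) {
  cat("Multiply-imputed trial:", attr(x, "m"), "completed datasets of",
      nrow(x[[1]]), "patients\n")
  invisible(x)
}
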