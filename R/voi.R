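#' Per-patient expected value of perfect information
#'
#' Under a normally distributed incremental net monetary benefit with mean
#' `mean` and standard deviation `sd`, the expected opportunity loss of
#' deciding now — the most a decision-maker should pay per patient for
#' perfect information — has the unit-normal-loss closed form
#'
#' \deqn{EVPI = \sigma [\phi(z) - z \Phi(-z)], \quad z = |\mu|/\sigma.}
#'
#' @param mean mean INB (GBP).
#' @param sd SD of the INB (GBP); a 95% CI converts via
#'   `sd = (upper - lower) / (2 * 1.959964)`.
#' @return EVPI in GBP (0 when `sd` is 0).
#' @examples
#' evpi_per_patient(0, 1000)    # 1000 * dnorm(0) = 398.9
#' @export
evpi_per_patient <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be >= 0")
  z <- ifelse(sd > 0, abs(mean) / sd, Inf)
  ifelse(sd > 0, sd * (stats::dnorm(z) - z * stats::pnorm(-z)), 0)
}

#' Discounted effective population
#'
#' Number of future patients who could benefit from resolving the decision
#' over the stated horizon, with later cohorts discounted:
#' `sum over t = 1..H of incidence / (1 + r)^(t - 1)`.  Where an external
#' estimate of the eligible population over the horizon already exists, it
#' can be used directly as the effective population instead.
#'
#' @param annual_incidence eligible patients per year.
#' @param horizon_years decision-relevance horizon (years).
#' @param discount_rate annual discount rate.
#' @return effective population (count, not rounded).
#' @export
effective_population <- function(annual_incidence, horizon_years,
                                 discount_rate = 0.035) {
  if (annual_incidence < 0 || horizon_years < 0 || discount_rate < 0) {
    stop("all arguments must be non-negative")
  }
  if (horizon_years == 0) return(0)
  sum(annual_incidence / (1 + discount_rate)^(seq_len(horizon_years) - 1))
}

#' Population expected value of perfect information
#'
#' @param per_patient per-patient EVPI (GBP).
#' @param population effective population (count).
#' @return population EVPI (GBP).
#' @export
population_evpi <- function(per_patient, population) {
  if (any(per_patient < 0) || any(population < 0)) {
    stop("per-patient EVPI and population must be >= 0")
  }
  per_patient * population
}

#' EVPI from a cost-effectiveness estimate
#'
#' Full value-of-information result at a willingness-to-pay threshold: the
#' INB mean and SD implied by the joint estimate, per-patient EVPI, and the
#' population EVPI over the effective population.
#'
#' @param est a [ce_estimate()].
#' @param lambda willingness to pay per QALY (GBP).
#' @param population effective population; either supplied directly or
#'   derived via [effective_population()] from `annual_incidence`.
#' @param annual_incidence,horizon_years,discount_rate used when `population`
#'   is not supplied directly.
#' @return list of class `evpi_result`.
#' @export
evpi <- function(est, lambda = 20000, population = NULL,
                 annual_incidence = NULL, horizon_years = 5,
                 discount_rate = 0.035) {
  stopifnot(inherits(est, "ce_estimate"))
  if (is.null(population)) {
    if (is.null(annual_incidence)) {
      stop("supply either population or annual_incidence")
    }
    population <- effective_population(annual_incidence, horizon_years,
                                       discount_rate)
  }
  b <- inb(est, lambda)
  pp <- evpi_per_patient(b$mean, b$se)
  structure(
    list(lambda = lambda, inb_mean = b$mean, inb_sd = b$se,
         evpi_per_patient = pp, effective_population = population,
         population_evpi = population_evpi(pp, population),
         horizon_years = horizon_years, discount_rate = discount_rate),
    class = "evpi_result"
  )
}

#' @export
print.evpi_result <- function(x, ...) {
  cat("Expected value of perfect information at",
      format(x$lambda, big.mark = ","), "GBP/QALY\n")
  cat(sprintf("  INB %0.0f (SD %0.0f) GBP\n", x$inb_mean, x$inb_sd))
  cat(sprintf("  per patient : %0.0f GBP\n", x$evpi_per_patient))
  cat(sprintf("  population  : %0.2f million GBP (%s patients)\n",
              x$population_evpi / 1e6,
              format(round(x$effective_population), big.mark = ",")))
  invisible(x)
}

#' EVPI across the willingness-to-pay grid
#'
#' Companion to the acceptability curve: per-patient (and optionally
#' population) EVPI at each threshold on the grid.
#'
#' @param est a [ce_estimate()].
#' @param lambdas willingness-to-pay grid.
#' @param population optional effective population.
#' @return data.frame with `lambda`, `evpi_per_patient` and (if `population`
#'   is given) `population_evpi`.
#' @export
evpi_curve <- function(est, lambdas = seq(0, 50000, by = 500),
                       population = NULL) {
  b <- inb(est, lambdas)
  out <- data.frame(lambda = lambdas,
                    evpi_per_patient = evpi_per_patient(b$mean, b$se))
  if (!is.null(population)) {
    out$population_evpi <- population_evpi(out$evpi_per_patient, population)
  }
  out
}
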