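#' Unit-cost table
#'
#' Holds the unit costs that turn recorded resource use into per-patient NHS
#' costs at a stated price year.  Procedure reference costs are national
#' average costs covering both the surgery and the associated hospital stay;
#' [adjusted_surgery_cost()] removes the stay component to avoid double
#' counting, since bed days are costed separately from the observed stay.
#'
#' @param procedures data.frame with columns `code`, `reference_cost` (GBP)
#'   and `avg_los_days` (the average length of stay embedded in the reference
#'   cost).
#' @param ward_day,cc_level2_day,cc_level3_day,recovery_day GBP per bed day by
#'   level of care.
#' @param monitor_per_patient GBP per patient in whom the cardiac output
#'   monitor was used (costed per use, not per day).
#' @param dopexamine_per_mg GBP per mg infused.
#' @param crystalloid_per_ml,colloid_per_ml,blood_per_ml GBP per ml; blood
#'   products are costed per ml (configurable — a per-unit tariff can be
#'   expressed by dividing by the unit volume).
#' @param nurse_hour GBP per nursing hour (used only by the staffing
#'   sensitivity analyses; the base case assumes delivery within existing
#'   resources).
#' @param price_year label, e.g. `"2012-2013"`.
#' @return Object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(procedures, ward_day, cc_level2_day, cc_level3_day,
                            recovery_day, monitor_per_patient, dopexamine_per_mg,
                            crystalloid_per_ml, colloid_per_ml, blood_per_ml,
                            nurse_hour, price_year = "unstated") {
  need <- c("code", "reference_cost", "avg_los_days")
  if (!is.data.frame(procedures) || !all(need %in% names(procedures))) {
    stop("procedures must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(procedures$code)) stop("duplicate procedure codes")
  scalars <- c(ward_day = ward_day, cc_level2_day = cc_level2_day,
               cc_level3_day = cc_level3_day, recovery_day = recovery_day,
               monitor_per_patient = monitor_per_patient,
               dopexamine_per_mg = dopexamine_per_mg,
               crystalloid_per_ml = crystalloid_per_ml,
               colloid_per_ml = colloid_per_ml, blood_per_ml = blood_per_ml,
               nurse_hour = nurse_hour)
  if (any(!is.finite(scalars)) || any(scalars < 0) ||
      any(procedures$reference_cost < 0) || any(procedures$avg_los_days < 0)) {
    stop("all unit costs and lengths of stay must be non-negative")
  }
  structure(
    c(as.list(scalars),
      list(procedures = procedures, price_year = price_year)),
    class = "unit_cost_table"
  )
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit-cost table (price year ", x$price_year, ")\n", sep = "")
  cat("  per-day rates: ward", x$ward_day, "| level 2", x$cc_level2_day,
      "| level 3", x$cc_level3_day, "| recovery", x$recovery_day, "\n")
  cat("  procedures:", nrow(x$procedures), "codes\n")
  invisible(x)
}

#' Read a unit-cost table from YAML
#'
#' The YAML mirrors the [unit_cost_table()] constructor: scalar rates at the
#' top level, a `price_year`, and a `procedures` list of `code`,
#' `reference_cost`, `avg_los_days` entries.
#'
#' @param path YAML file.
#' @return A `unit_cost_table`.
#' @export
read_unit_costs <- function(path) {
  y <- yaml::read_yaml(path)
  proc <- do.call(rbind, lapply(y$procedures, function(p) {
    data.frame(code = p$code, reference_cost = p$reference_cost,
               avg_los_days = p$avg_los_days)
  }))
  args <- y[setdiff(names(y), "procedures")]
  do.call(unit_cost_table, c(list(procedures = proc), args))
}

#' Write a unit-cost table to YAML
#' @param uc a `unit_cost_table`.
#' @param path output YAML file.
#' @export
write_unit_costs <- function(uc, path) {
  stopifnot(inherits(uc, "unit_cost_table"))
  y <- uc[setdiff(names(uc), "procedures")]
  y$procedures <- lapply(seq_len(nrow(uc$procedures)), function(i) {
    as.list(uc$procedures[i, ])
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Default (placeholder) unit costs
#'
#' Plausible 2012–2013-era NHS magnitudes for each rate, supplied so the
#' pipeline runs end to end; they are documented placeholders, not a
#' transcription of any published reference-cost schedule, and analyses of
#' real data should supply their own table via [read_unit_costs()].
#'
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  procedures <- data.frame(
    code = c("upper_GI", "lower_GI", "small_bowel_pancreas", "uro_gynae", "none"),
    reference_cost = c(7000, 5500, 8000, 5000, 400),
    avg_los_days = c(12, 10, 14, 9, 0)
  )
  unit_cost_table(
    procedures = procedures,
    ward_day = 300, cc_level2_day = 850, cc_level3_day = 1250,
    recovery_day = 400, monitor_per_patient = 175, dopexamine_per_mg = 2.5,
    crystalloid_per_ml = 0.001, colloid_per_ml = 0.015, blood_per_ml = 0.45,
    nurse_hour = 25, price_year = "2012-2013 (placeholder)"
  )
}

#' Surgery cost adjusted for double counting
#'
#' National reference costs average over both the procedure and the hospital
#' stay, but bed days are costed separately from each patient's observed
#' stay.  The stay component — the average length of stay at the ward-day
#' rate plus one post-anaesthetic recovery day — is therefore subtracted from
#' the reference cost.  A negative result is floored at zero with a warning.
#'
#' @param code character vector of procedure codes.
#' @param uc a [unit_cost_table()].
#' @return GBP per patient (vectorised over `code`).
#' @examples
#' uc <- default_unit_costs()
#' adjusted_surgery_cost("lower_GI", uc)
#' @export
adjusted_surgery_cost <- function(code, uc) {
  stopifnot(inherits(uc, "unit_cost_table"))
  i <- match(code, uc$procedures$code)
  if (anyNA(i)) {
    stop("unknown procedure code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  }
  adj <- uc$procedures$reference_cost[i] -
    uc$procedures$avg_los_days[i] * uc$ward_day -
    uc$recovery_day
  if (any(adj < 0)) {
    warning("adjusted surgery cost negative for code(s) ",
            paste(unique(code[adj < 0]), collapse = ", "),
            "; floored at 0")
    adj <- pmax(adj, 0)
  }
  adj
}

#' Per-patient cost breakdown
#'
#' Assembles each patient's 6-month NHS cost from resource use:
#' double-counting-adjusted surgery cost, critical-care days costed by level
#' (2 and 3), general-ward days, intervention equipment and drugs (monitor
#' use and dopexamine), and fluids and blood products (intra-operative and
#' 6-h post-operative volumes costed at the same per-ml rates).  The base
#' case adds no staff time.  Two staffing sensitivity analyses are available:
#'
#' * `"s1"` — adds one level-2 critical-care day plus one hour of recovery
#'   nurse time for patients not transferred directly to critical care after
#'   surgery.
#' * `"s2"` — adds 4.5 hours of nurse time for every intervention-arm
#'   patient, the time needed to deliver the haemodynamic algorithm.
#'
#' @param trial trial data.frame (schema of [generate_trial()]).
#' @param uc a [unit_cost_table()].
#' @param sensitivity character vector, any of `"s1"`, `"s2"`.
#' @return data.frame, one row per patient: `patient_id`, component columns
#'   (`surgery_adjusted`, `critical_care`, `ward`,
#'   `intervention_equipment_drugs`, `fluids_blood`, `sensitivity_addons`)
#'   and `total` = their exact sum.
#' @export
compute_costs <- function(trial, uc = default_unit_costs(),
                          sensitivity = character()) {
  stopifnot(inherits(uc, "unit_cost_table"))
  bad <- setdiff(sensitivity, c("s1", "s2"))
  if (length(bad) > 0) stop("unknown sensitivity option(s): ",
                            paste(bad, collapse = ", "))
  qty_cols <- c("cc_level2_days", "cc_level3_days", "ward_days",
                "dopexamine_mg", "crystalloid_ml", "colloid_ml", "blood_ml")
  for (cl in qty_cols) {
    if (any(trial[[cl]] < 0, na.rm = TRUE)) {
      stop("negative resource quantity in column ", cl)
    }
  }
  surgery <- adjusted_surgery_cost(trial$procedure_code, uc)
  critical <- trial$cc_level2_days * uc$cc_level2_day +
    trial$cc_level3_days * uc$cc_level3_day
  ward <- trial$ward_days * uc$ward_day
  equip <- as.numeric(trial$monitor_used) * uc$monitor_per_patient +
    trial$dopexamine_mg * uc$dopexamine_per_mg
  fluids <- trial$crystalloid_ml * uc$crystalloid_per_ml +
    trial$colloid_ml * uc$colloid_per_ml +
    trial$blood_ml * uc$blood_per_ml
  addons <- numeric(nrow(trial))
  if ("s1" %in% sensitivity) {
    not_direct_cc <- trial$postop_location %in% c("recovery", "ward")
    addons <- addons + not_direct_cc * (uc$cc_level2_day + 1 * uc$nurse_hour)
  }
  if ("s2" %in% sensitivity) {
    addons <- addons + (trial$arm == "intervention") * 4.5 * uc$nurse_hour
  }
  out <- data.frame(
    patient_id = trial$patient_id,
    surgery_adjusted = surgery,
    critical_care = critical,
    ward = ward,
    intervention_equipment_drugs = equip,
    fluids_blood = fluids,
    sensitivity_addons = addons
  )
  out$total <- rowSums(out[, -1])
  out
}

#' Cost breakdown for a single patient record
#'
#' Convenience wrapper around [compute_costs()] for one row.
#'
#' @param rec single-row data.frame (one patient).
#' @inheritParams compute_costs
#' @return One-row cost-breakdown data.frame of class `cost_breakdown`.
#' @export
patient_cost <- function(rec, uc = default_unit_costs(),
                         sensitivity = character()) {
  stopifnot(nrow(rec) == 1)
  out <- compute_costs(rec, uc, sensitivity)
  class(out) <- c("cost_breakdown", class(out))
  out
}
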