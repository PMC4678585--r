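#' EQ-5D-3L value sets
#'
#' A value set maps a five-digit EQ-5D-3L profile (one level in \{1,2,3\} for
#' each of mobility, self-care, usual activities, pain/discomfort and
#' anxiety/depression) to a single preference-based utility index anchored at
#' 1 for full health (profile 11111) and 0 for death.  The index for any other
#' profile is
#'
#' \deqn{1 - c - \sum_d \delta_{d,\ell_d} - N3 \cdot [\exists d: \ell_d = 3]}
#'
#' where `c` is a constant decrement applied whenever any dimension is worse
#' than level 1, `delta` are per-dimension level-2/level-3 decrements, and the
#' `N3` term applies once if any dimension is at level 3.  Decrements are
#' stored in a plain CSV so the scoring engine never hard-codes a tariff.
#'
#' @param decrements named numeric vector (or coercible list) with elements
#'   `constant`, `MO2`, `MO3`, `SC2`, `SC3`, `UA2`, `UA3`, `PD2`, `PD3`,
#'   `AD2`, `AD3`, `N3`.  All must be non-negative and each level-3 decrement
#'   must be at least its level-2 counterpart (this guarantees the index is
#'   non-increasing as any single dimension worsens).
#' @param name label carried along for reporting.
#' @return An object of class `eq5d_value_set`: the decrement table, the name
#'   and the `floor` (the minimum index over all 243 profiles).
#' @seealso [eq5d_index()], [read_value_set()], [default_value_set()]
#' @export
eq5d_value_set <- function(decrements, name = "custom") {
  terms <- c("constant", "MO2", "MO3", "SC2", "SC3", "UA2", "UA3",
             "PD2", "PD3", "AD2", "AD3", "N3")
  decrements <- unlist(decrements)
  missing_terms <- setdiff(terms, names(decrements))
  if (length(missing_terms) > 0) {
    stop("value set is missing term(s): ", paste(missing_terms, collapse = ", "))
  }
  decrements <- decrements[terms]
  if (any(!is.finite(decrements)) || any(decrements < 0)) {
    stop("value-set decrements must be finite and non-negative")
  }
  dims <- c("MO", "SC", "UA", "PD", "AD")
  for (d in dims) {
    if (decrements[paste0(d, "3")] < decrements[paste0(d, "2")]) {
      stop("level-3 decrement for ", d, " is smaller than the level-2 decrement; ",
           "the index would not be monotone")
    }
  }
  vs <- structure(
    list(decrements = decrements, name = name),
    class = "eq5d_value_set"
  )
  vs$floor <- min(eq5d_index(eq5d_all_profiles(), vs))
  vs
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set:", x$name, "\n")
  cat("  floor (worst profile):", format(x$floor), "\n")
  print(round(x$decrements, 4))
  invisible(x)
}

#' Read a value set from CSV
#'
#' The file must have columns `term` and `decrement` with the twelve terms
#' documented in [eq5d_value_set()].
#'
#' @param path CSV file path.
#' @param name label; defaults to the file name.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path, name = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "decrement") %in% names(tab))) {
    stop("value-set CSV must have columns 'term' and 'decrement'")
  }
  eq5d_value_set(stats::setNames(tab$decrement, tab$term), name = name)
}

#' The bundled UK general-population value set
#'
#' Transcription of the UK time-trade-off tariff (the "MVH" value set) used to
#' score EQ-5D-3L profiles on UK general-population preferences.  Its floor
#' (profile 33333) is -0.594, so states worse than death score negatively.
#'
#' @return An `eq5d_value_set`.
#' @export
default_value_set <- function() {
  path <- system.file("extdata", "uk_mvh_valueset.csv", package = "periopcea")
  read_value_set(path, name = "UK MVH (general population TTO)")
}

#' All 243 EQ-5D-3L profiles
#'
#' @return Character vector of the 243 five-digit profile strings, in
#'   lexicographic order.
#' @export
eq5d_all_profiles <- function() {
  g <- expand.grid(AD = 1:3, PD = 1:3, UA = 1:3, SC = 1:3, MO = 1:3)
  sort(paste0(g$MO, g$SC, g$UA, g$PD, g$AD))
}

profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (ncol(profiles) != 5) stop("profile matrix must have 5 columns")
    m <- profiles
  } else if (is.character(profiles)) {
    if (any(nchar(profiles) != 5 & !is.na(profiles))) {
      stop("EQ-5D profiles must be 5-character strings of levels, e.g. '21123'")
    }
    m <- matrix(NA_integer_, nrow = length(profiles), ncol = 5)
    ok <- !is.na(profiles)
    if (any(ok)) {
      m[ok, ] <- t(vapply(strsplit(profiles[ok], ""),
                          function(x) as.integer(x), integer(5)))
    }
  } else {
    stop("profiles must be 5-digit strings or a 5-column integer matrix")
  }
  bad <- !is.na(m) & !(m %in% 1:3)
  if (any(bad)) {
    stop("EQ-5D levels must be 1, 2 or 3; offending value(s): ",
         paste(unique(m[bad]), collapse = ", "))
  }
  colnames(m) <- c("MO", "SC", "UA", "PD", "AD")
  m
}

#' Score EQ-5D-3L profiles to a utility index
#'
#' @param profiles character vector of 5-digit profiles (e.g. `"21123"`), or a
#'   numeric matrix with 5 columns (mobility, self-care, usual activities,
#'   pain/discomfort, anxiety/depression).  `NA` profiles score `NA`.
#' @param vs an [eq5d_value_set()]; defaults to the bundled UK set.
#' @return Numeric vector of utility indices; 1 for full health, down to the
#'   value set's floor.
#' @examples
#' eq5d_index("11111")             # 1
#' eq5d_index(c("21111", "33333")) # decremented states
#' @export
eq5d_index <- function(profiles, vs = default_value_set()) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  m <- profile_matrix(profiles)
  d <- vs$decrements
  idx <- rep(NA_real_, nrow(m))
  complete <- stats::complete.cases(m)
  if (!any(complete)) return(idx)
  mm <- m[complete, , drop = FALSE]
  any_dysfunction <- rowSums(mm > 1) > 0
  any_level3 <- rowSums(mm == 3) > 0
  dims <- colnames(mm)
  dim_dec <- rep(0, nrow(mm))
  for (j in seq_along(dims)) {
    dim_dec <- dim_dec +
      ifelse(mm[, j] == 2, d[paste0(dims[j], "2")],
             ifelse(mm[, j] == 3, d[paste0(dims[j], "3")], 0))
  }
  idx[complete] <- 1 -
    d["constant"] * any_dysfunction -
    dim_dec -
    d["N3"] * any_level3
  unname(idx)
}
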