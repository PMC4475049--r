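#' Fit the linear development-rate regression for one species/stage
#'
#' Development rate is defined as the reciprocal of development time in days.
#' Over the ecologically relevant range (roughly 20 degrees wide) the rate is
#' virtually linear in temperature, `rate = a + b * T`; the lower developmental
#' threshold (LDT) is the x-intercept `-a/b` and the sum of effective
#' temperatures (SET) the reciprocal slope `1/b` (see
#' [derive_thermal_constants()]).
#'
#' @param observations data frame with columns `species_id`, `stage`,
#'   `temperature` (degrees C) and `development_time` (days); all rows must
#'   share one species and stage. Optional `population_id`/`study_id` columns
#'   are carried through untouched.
#' @param min_temperatures minimum number of distinct rearing temperatures
#'   required for a fit (default 3; two points give R^2 = 1 vacuously).
#' @param on_means if `TRUE`, regress per-temperature mean rates instead of
#'   per-observation rates. The default (`FALSE`) preserves replicate
#'   weighting; the switch reproduces studies that published treatment means.
#' @return an object of class `rate_regression`: intercept `intercept_a`
#'   (1/day), slope `slope_b` (1/(day*degC)), their standard errors, the
#'   coefficient covariance `cov_ab`, `r_squared`, `n_points` and
#'   `temperature_range`.
#' @seealso [derive_thermal_constants()], [aggregate_populations()]
#' @examples
#' obs <- data.frame(species_id = "sp", stage = "egg_to_adult",
#'                   temperature = c(15, 20, 25, 30),
#'                   development_time = 1 / (0.01 * (c(15, 20, 25, 30) - 10)))
#' fit_rate_regression(obs)
#' @export
fit_rate_regression <- function(observations, min_temperatures = 3,
                                on_means = FALSE) {
  stopifnot(is.data.frame(observations))
  req <- c("species_id", "stage", "temperature", "development_time")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols) > 0)
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "))
  sp <- unique(observations$species_id)
  st <- unique(observations$stage)
  if (length(sp) != 1L || length(st) != 1L)
    stop("fit_rate_regression expects a single species/stage; got ",
         length(sp), " species and ", length(st), " stages")
  if (any(!is.finite(observations$temperature)))
    stop("non-finite temperature for ", sp, "/", st)
  if (any(!is.finite(observations$development_time)) ||
      any(observations$development_time <= 0))
    stop("development_time must be finite and > 0 for ", sp, "/", st)

  n_temps <- length(unique(observations$temperature))
  if (n_temps < min_temperatures)
    stop("too few distinct temperatures (", n_temps, " < ", min_temperatures,
         ") for ", sp, "/", st)

  rate <- 1 / observations$development_time
  temp <- observations$temperature
  if (on_means) {
    rate <- tapply(rate, temp, mean)
    temp <- as.numeric(names(rate))
    rate <- as.numeric(rate)
  }

  fit <- stats::lm(rate ~ temp)
  # noise-free data triggers summary.lm's perfect-fit warning; it is a
  # legitimate input here (exact linear development tables)
  quiet_perfect <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- quiet_perfect(summary(fit))
  V <- quiet_perfect(stats::vcov(fit))
  structure(list(
    species_id = sp,
    stage = st,
    intercept_a = unname(stats::coef(fit)[1]),
    slope_b = unname(stats::coef(fit)[2]),
    se_a = unname(sm$coefficients[1, 2]),
    se_b = unname(sm$coefficients[2, 2]),
    cov_ab = V[1, 2],
    r_squared = sm$r.squared,
    n_points = length(rate),
    temperature_range = range(temp)
  ), class = "rate_regression")
}

#' Derive LDT and SET from a fitted rate regression
#'
#' LDT is the temperature at which the fitted development rate reaches zero,
#' `-a/b`; SET is the reciprocal slope `1/b`, in day-degrees above the LDT.
#' Standard errors are propagated to first order (delta method) from the
#' coefficient covariance; they are carried for reporting but never used to
#' weight downstream analyses, which average unweighted.
#'
#' @param fit a `rate_regression` from [fit_rate_regression()].
#' @return an object of class `thermal_requirement` with fields `species_id`,
#'   `stage`, `ldt` (degrees C), `set_dd` (day-degrees), `se_ldt`, `se_set`,
#'   `n_sources` and `source`.
#' @export
derive_thermal_constants <- function(fit) {
  stopifnot(inherits(fit, "rate_regression"))
  a <- fit$intercept_a
  b <- fit$slope_b
  if (!is.finite(b) || b <= 0)
    stop("no positive thermal response for ", fit$species_id, "/", fit$stage,
         " (slope = ", format(b), "); species excluded")
  ldt <- -a / b
  set_dd <- 1 / b
  # delta method: grad of -a/b is (-1/b, a/b^2); of 1/b is (0, -1/b^2)
  g <- c(-1 / b, a / b^2)
  var_ldt <- g[1]^2 * fit$se_a^2 + g[2]^2 * fit$se_b^2 +
    2 * g[1] * g[2] * fit$cov_ab
  var_set <- fit$se_b^2 / b^4
  new_thermal_requirement(
    species_id = fit$species_id, stage = fit$stage,
    ldt = ldt, set_dd = set_dd,
    se_ldt = sqrt(max(var_ldt, 0)), se_set = sqrt(max(var_set, 0)),
    n_sources = 1L, source = "single_study"
  )
}

new_thermal_requirement <- function(species_id, stage, ldt, set_dd,
                                    se_ldt = NA_real_, se_set = NA_real_,
                                    n_sources = 1L, source = "single_study",
                                    set_choice_required = FALSE) {
  structure(list(
    species_id = species_id, stage = stage,
    ldt = ldt, set_dd = set_dd, se_ldt = se_ldt, se_set = se_set,
    n_sources = as.integer(n_sources), source = source,
    set_choice_required = isTRUE(set_choice_required)
  ), class = "thermal_requirement")
}

#' @export
print.thermal_requirement <- function(x, ...) {
  cat(sprintf("Thermal requirement for %s (%s): LDT = %.3f degC, SET = %s D
  (n_sources = %d, %s)\n",
              x$species_id, x$stage, x$ldt,
              if (is.na(x$set_dd)) "NA" else sprintf("%.2f", x$set_dd),
              x$n_sources, x$source))
  invisible(x)
}

#' Average thermal requirements across populations, screening outliers
#'
#' Where several independently studied populations of a species are available,
#' the per-population estimates are averaged after discarding values that are
#' obviously too different from the rest. The screen is quantified as a
#' deviation from the cross-population median of more than
#' `outlier_k * 1.4826 * MAD` (LDT and SET screened independently by default).
#' Every discard is recorded in the `discards` attribute of the result.
#'
#' @param estimates list of `thermal_requirement` objects for one
#'   species/stage.
#' @param outlier_k multiplier on the scaled median absolute deviation
#'   (default 3).
#' @param joint if `TRUE`, a population flagged for either trait is dropped
#'   from both averages; the default screens each trait independently.
#' @return a single `thermal_requirement` with `source = "population_mean"`
#'   and `n_sources` equal to the survivor count; a singleton input is
#'   returned unchanged.
#' @export
aggregate_populations <- function(estimates, outlier_k = 3, joint = FALSE) {
  if (length(estimates) == 0L) stop("no estimates to aggregate")
  stopifnot(all(vapply(estimates, inherits, logical(1), "thermal_requirement")))
  sp <- unique(vapply(estimates, `[[`, character(1), "species_id"))
  st <- unique(vapply(estimates, `[[`, character(1), "stage"))
  if (length(sp) != 1L || length(st) != 1L)
    stop("aggregate_populations expects one species/stage")
  if (length(estimates) == 1L) return(estimates[[1]])

  ldt <- vapply(estimates, `[[`, numeric(1), "ldt")
  set <- vapply(estimates, `[[`, numeric(1), "set_dd")

  keep_trait <- function(x) {
    ok <- is.finite(x)
    if (sum(ok) < 2L) return(ok)
    med <- stats::median(x[ok])
    s <- stats::mad(x[ok])  # already scaled by 1.4826
    dev <- abs(x - med)
    ok & (dev <= outlier_k * s | dev == 0)
  }
  keep_ldt <- keep_trait(ldt)
  keep_set <- keep_trait(set)
  if (joint) {
    both <- keep_ldt & keep_set
    keep_ldt <- both
    keep_set <- both
  }
  stopifnot(any(keep_ldt))  # the median itself can never be discarded

  discards <- data.frame(
    index = seq_along(estimates),
    ldt = ldt, set_dd = set,
    kept_ldt = keep_ldt, kept_set = keep_set
  )[!(keep_ldt & keep_set), , drop = FALSE]

  out <- new_thermal_requirement(
    species_id = sp, stage = st,
    ldt = mean(ldt[keep_ldt]),
    set_dd = if (any(keep_set & is.finite(set)))
      mean(set[keep_set & is.finite(set)]) else NA_real_,
    se_ldt = if (sum(keep_ldt) > 1)
      stats::sd(ldt[keep_ldt]) / sqrt(sum(keep_ldt)) else NA_real_,
    se_set = if (sum(keep_set & is.finite(set)) > 1)
      stats::sd(set[keep_set & is.finite(set)]) /
        sqrt(sum(keep_set & is.finite(set))) else NA_real_,
    n_sources = max(sum(keep_ldt), sum(keep_set)),
    source = "population_mean"
  )
  attr(out, "discards") <- discards
  out
}

#' Select species-level LDT and SET across developmental stages
#'
#' SET for the total (egg to adult) pre-imaginal development is preferred;
#' when absent and a single stage is available, that stage is used. LDT
#' likewise prefers the whole development but otherwise takes the mean of
#' stage-specific LDTs, since all stages within a population are assumed to
#' share the same LDT.
#'
#' @param estimates list of `thermal_requirement` objects for one species,
#'   across stages.
#' @param set_stage optional stage label naming which stage-specific SET to
#'   use when several stages (and no egg-to-adult estimate) are available.
#'   Without it, SET is returned as `NA` with `set_choice_required = TRUE`.
#' @return a single `thermal_requirement` for the species.
#' @export
select_stage_values <- function(estimates, set_stage = NULL) {
  if (length(estimates) == 0L) stop("no estimates to select from")
  stopifnot(all(vapply(estimates, inherits, logical(1), "thermal_requirement")))
  sp <- unique(vapply(estimates, `[[`, character(1), "species_id"))
  if (length(sp) != 1L) stop("select_stage_values expects one species")
  stages <- vapply(estimates, `[[`, character(1), "stage")

  whole <- which(stages == "egg_to_adult")
  if (length(whole) >= 1L) return(estimates[[whole[1]]])
  if (length(estimates) == 1L) return(estimates[[1]])

  ldt <- mean(vapply(estimates, `[[`, numeric(1), "ldt"))
  set <- vapply(estimates, `[[`, numeric(1), "set_dd")
  has_set <- which(is.finite(set))
  if (!is.null(set_stage)) {
    pick <- which(stages == set_stage)
    if (length(pick) != 1L) stop("set_stage '", set_stage, "' not found")
    set_out <- set[pick]; stage_out <- set_stage; flag <- FALSE
  } else if (length(has_set) == 1L) {
    set_out <- set[has_set]; stage_out <- stages[has_set]; flag <- FALSE
  } else {
    set_out <- NA_real_; stage_out <- "other"; flag <- length(has_set) > 1L
  }
  new_thermal_requirement(
    species_id = sp, stage = stage_out, ldt = ldt, set_dd = set_out,
    n_sources = length(estimates), source = "population_mean",
    set_choice_required = flag
  )
}

#' Predicted development time at a temperature
#'
#' Under the linear rate model, development at temperature `T > LDT` takes
#' `SET / (T - LDT)` days.
#'
#' @param tr a `thermal_requirement`.
#' @param temperature rearing temperature(s), degrees C.
#' @return development time(s) in days; `Inf` at or below the LDT.
#' @export
predict_development_time <- function(tr, temperature) {
  stopifnot(inherits(tr, "thermal_requirement"))
  ifelse(temperature > tr$ldt, tr$set_dd / (temperature - tr$ldt), Inf)
}
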