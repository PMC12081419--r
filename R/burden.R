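#' Exact (Garwood) confidence interval for a Poisson count
#'
#' Central two-sided interval for the Poisson mean given an observed count,
#' computed from gamma quantiles: `low` solves `P(X >= n | low) = alpha/2`
#' and `high` solves `P(X <= n | high) = alpha/2`.  For `n = 0` the lower
#' bound is 0 and the upper bound keeps the central `alpha/2` tail, so the
#' interval's coverage never falls below the nominal level at any mean.
#' (Zero-count *results* are reported with a one-sided upper limit by
#' [fiber_burden()] instead, the natural summary for blanks.)
#'
#' @param n Observed count(s), non-negative integer(s).
#' @param level Confidence level in (0, 1).
#' @return A matrix with columns `low` and `high`, one row per element of
#'   `n` (dropped to a named vector for scalar `n`).
#' @export
poisson_interval <- function(n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop_invalid_input("level must be in (0, 1)")
  if (any(n < 0) || any(n != floor(n)))
    stop_invalid_input("n must be a non-negative integer")
  alpha <- 1 - level
  low <- ifelse(n == 0, 0, stats::qgamma(alpha / 2, shape = pmax(n, 1)))
  high <- stats::qgamma(1 - alpha / 2, shape = n + 1)
  out <- cbind(low = low, high = high)
  if (length(n) == 1L) out[1L, ] else out
}

#' Poisson counting coefficient of variation
#'
#' The counting contribution to uncertainty follows the Poisson law: the
#' standard deviation of a count `n` is `sqrt(n)`, so the relative
#' standard uncertainty is `100/sqrt(n)` percent (14.1% at the 50-fiber
#' stop, 28.3% when expanded with k = 2).
#'
#' @param n Fiber count(s) >= 1.
#' @param k Coverage factor (1 = standard uncertainty).
#' @return CV in percent.
#' @export
poisson_cv_percent <- function(n, k = 1) {
  if (any(n < 1)) stop_invalid_input("n must be >= 1")
  k * 100 / sqrt(n)
}

#' Analytical sensitivity of an examination
#'
#' The concentration that corresponds to finding exactly one countable
#' fiber over the examined fields: `AS = A / (N_fields * a * p_TS)`, with
#' `A` the active filtration area, `a` the calibrated field area and
#' `p_TS` the dry tissue mass on the filter.  Examining more fields lowers
#' (improves) the sensitivity in direct proportion.
#'
#' @param prep A [filter_prep()] record.
#' @param n_fields Number of fields examined or planned (>= 1).
#' @return Sensitivity in fibers per gram dry tissue.
#' @export
analytical_sensitivity <- function(prep, n_fields) {
  stopifnot(inherits(prep, "filter_prep"))
  if (any(n_fields < 1) || any(n_fields != floor(n_fields)))
    stop_invalid_input("n_fields must be an integer >= 1")
  p_ts <- tissue_mass_on_filter(prep)
  if (p_ts <= 0)
    stop_invalid_input("no tissue on filter (p_TS = 0); sensitivity undefined")
  prep$active_area_mm2 / (n_fields * prep$field_area_mm2 * p_ts)
}

#' Plan the number of fields for a target sensitivity
#'
#' Returns the smallest number of fields whose analytical sensitivity is
#' at or below `target_as` (i.e. at least as good as requested).  Because
#' `AS` is inversely proportional to the examined area, the plan is
#' `ceiling(A / (target_as * a * p_TS))`, verified against the
#' smallest-integer property.  A target so ambitious that the planned
#' fields would exceed the whole active area is infeasible for this
#' preparation; load less tissue per filter or examine a second filter.
#'
#' @param target_as Required analytical sensitivity, fibers per gram dry
#'   (the routine requirement is 0.1 mil ff/g dry = 1e5 ff/g).
#' @param prep A [filter_prep()] record.
#' @return Integer number of fields.
#' @export
plan_fields <- function(target_as, prep) {
  stopifnot(inherits(prep, "filter_prep"))
  if (!is.numeric(target_as) || length(target_as) != 1L || target_as <= 0)
    stop_invalid_input("target_as must be a single number > 0")
  p_ts <- tissue_mass_on_filter(prep)
  if (p_ts <= 0)
    stop_invalid_input("no tissue on filter (p_TS = 0); cannot plan")
  n_exact <- prep$active_area_mm2 / (target_as * prep$field_area_mm2 * p_ts)
  n_whole_filter <- floor(prep$active_area_mm2 / prep$field_area_mm2)
  if (ceiling(n_exact - 1e-9) > n_whole_filter)
    stop(errorCondition(
      sprintf(paste("target sensitivity %g ff/g needs ~%.3g fields,",
                    "more area than the filter offers; reduce the tissue",
                    "load per filter or relax the target"),
              target_as, ceiling(n_exact)),
      class = c("fiberburden_infeasible_plan", "fiberburden_error")))
  n <- as.integer(ceiling(n_exact - 1e-9))
  n <- max(n, 1L)
  # guard the boundary against floating-point rounding either way
  while (analytical_sensitivity(prep, n) > target_as) n <- n + 1L
  while (n > 1L && analytical_sensitivity(prep, n - 1L) <= target_as)
    n <- n - 1L
  if (n * prep$field_area_mm2 > prep$active_area_mm2)
    stop(errorCondition(
      sprintf(paste("target sensitivity %g ff/g needs %d fields,",
                    "more area than the filter offers; reduce the tissue",
                    "load per filter or relax the target"), target_as, n),
      class = c("fiberburden_infeasible_plan", "fiberburden_error")))
  n
}

#' Estimate the asbestos fiber burden of a tissue sample
#'
#' Fits the membrane-filter extrapolation model to a counting session:
#' with `n_f` countable fibers found over `N_fields` fields,
#' \deqn{C = n_f A / (N_{fields}\, a\, p_{TS})}
#' in fibers per gram of dry tissue, where `A` is the active filtration
#' area, `a` the calibrated field area and `p_TS` the dry tissue mass on
#' the filter.  The counting uncertainty is Poisson: `sd(C) = C/sqrt(n_f)`,
#' and the confidence interval is the exact (Garwood) Poisson interval for
#' the count scaled by the analytical sensitivity; a normal approximation
#' is available for comparison with legacy reports.  A session with no
#' countable fibers yields concentration 0 with a one-sided upper limit
#' and a below-sensitivity flag rather than an error, so blanks are
#' handled uniformly.
#'
#' @param session A [counting_session()].
#' @param prep The [filter_prep()] the session examined.
#' @param ci_level Confidence level for the interval.
#' @param interval `"garwood"` (exact, default) or `"normal"`
#'   (`C ± z sqrt(n_f) AS`, truncated at zero).
#' @param min_length_um Counting-rule length cut-off (strict), um.
#' @param as_requirement Sensitivity the examination should have reached,
#'   ff/g dry; the routine requirement is 0.1 mil ff/g = 1e5.  Only flags.
#' @return An object of class `"fiber_burden"` with components
#'   `concentration` (ff/g dry), `n_counted`, `n_fields`, `poisson_sd`,
#'   `poisson_cv_percent`, `ci_low`, `ci_high`, `ci_level`,
#'   `analytical_sensitivity`, `tissue_mass_g`, `ash_load`, flags, and the
#'   inputs.  Methods: [print()], [summary()], [coef()], [confint()],
#'   [simulate()].
#' @examples
#' prep <- filter_prep(100, 100, 20, 222, field_area_mm2 = 1e-4)
#' f <- data.frame(field_index = 0:8, length_um = 2, width_um = 0.3,
#'                 mineral_class = "amosite")
#' fit <- fiber_burden(counting_session(f, 100), prep)
#' fit
#' @export
fiber_burden <- function(session, prep, ci_level = 0.95,
                         interval = c("garwood", "normal"),
                         min_length_um = 1, as_requirement = 1e5) {
  stopifnot(inherits(session, "counting_session"),
            inherits(prep, "filter_prep"))
  interval <- match.arg(interval)
  if (ci_level <= 0 || ci_level >= 1)
    stop_invalid_input("ci_level must be in (0, 1)")
  p_ts <- tissue_mass_on_filter(prep)
  if (p_ts <= 0)
    stop_invalid_input("no tissue on filter (p_TS = 0); concentration undefined")
  n_fields <- session$n_fields_examined
  as_ffg <- analytical_sensitivity(prep, n_fields)
  n_f <- countable_fibers(session$fibers, min_length_um)
  conc <- n_f * as_ffg
  if (n_f > 0) {
    sd <- conc / sqrt(n_f)
    cv <- 100 / sqrt(n_f)
  } else {
    sd <- 0
    cv <- NA_real_
  }
  if (interval == "garwood") {
    ci <- if (n_f == 0L) {
      # blanks and clean samples: one-sided upper limit at the full level
      c(low = 0, high = stats::qgamma(ci_level, shape = 1) * as_ffg)
    } else {
      poisson_interval(n_f, ci_level) * as_ffg
    }
  } else {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    ci <- c(low = max(0, conc - z * sqrt(n_f) * as_ffg),
            high = conc + z * sqrt(n_f) * as_ffg)
  }
  al <- ash_load(prep)
  structure(
    list(concentration = conc,
         n_counted = n_f,
         n_fields = n_fields,
         poisson_sd = sd,
         poisson_cv_percent = cv,
         ci_low = unname(ci["low"]),
         ci_high = unname(ci["high"]),
         ci_level = ci_level,
         interval_method = interval,
         analytical_sensitivity = as_ffg,
         as_requirement = as_requirement,
         as_met = as_ffg <= as_requirement,
         below_as = n_f == 0L,
         tissue_mass_g = p_ts,
         ash_load = al,
         min_length_um = min_length_um,
         stop_reason = session$stop_reason,
         prep = prep,
         session = session),
    class = "fiber_burden")
}

MIL <- 1e6  # "mil ff/g dry" = 1e6 fibers per gram dry tissue

#' Working range reporting constant
#'
#' Upper end of the validated reporting range in ff/g dry (about 300 mil
#' ff/g).  Above it, the advice is to analyze a filter prepared with a
#' lower lung-tissue load, which rescales the whole range upward.
#' @export
working_range_upper <- function() 300 * MIL

fmt_mil <- function(x) sprintf("%.4g", x / MIL)

#' @export
print.fiber_burden <- function(x, ...) {
  cat("Asbestos fiber burden (SEM membrane-filter count)\n")
  cat(sprintf("  concentration : %s mil ff/g dry  (%d fibers over %d fields)\n",
              fmt_mil(x$concentration), x$n_counted, x$n_fields))
  cat(sprintf("  %.0f%% CI (%s): [%s, %s] mil ff/g dry\n",
              100 * x$ci_level, x$interval_method, fmt_mil(x$ci_low),
              fmt_mil(x$ci_high)))
  if (x$n_counted > 0)
    cat(sprintf("  Poisson sd    : %s mil ff/g dry (CV %.1f%%)\n",
                fmt_mil(x$poisson_sd), x$poisson_cv_percent))
  cat(sprintf("  analytical sensitivity: %s mil ff/g dry%s\n",
              fmt_mil(x$analytical_sensitivity),
              if (x$as_met) "" else "  [required sensitivity not reached]"))
  if (x$below_as)
    cat("  no countable fibers: result below analytical sensitivity\n")
  if (x$ash_load$over_limit)
    cat(sprintf("  NOTE: ash load %.3g mg/cm^2 exceeds the %g mg/cm^2 advisory limit\n",
                x$ash_load$mg_per_cm2, x$ash_load$limit_mg_cm2))
  if (x$concentration > working_range_upper())
    cat("  NOTE: above the validated working range; the range can be extended\n",
        "  by analyzing a filter with a lower lung tissue load\n", sep = "")
  invisible(x)
}

#' @export
summary.fiber_burden <- function(object, ...) {
  structure(list(fit = object), class = "summary.fiber_burden")
}

#' @export
print.summary.fiber_burden <- function(x, ...) {
  print(x$fit)
  cat("Preparation:\n")
  p <- x$fit$prep
  cat(sprintf("  %g mg dry tissue ashed, %g of %g mL filtered; p_TS = %g g\n",
              p$dry_mass_ashed_mg, p$filtered_volume_ml,
              p$suspension_volume_ml, x$fit$tissue_mass_g))
  cat(sprintf("  ash load %.3g mg/cm^2 (limit %g); A = %g mm^2, a = %g mm^2\n",
              x$fit$ash_load$mg_per_cm2, x$fit$ash_load$limit_mg_cm2,
              p$active_area_mm2, p$field_area_mm2))
  cat(sprintf("  counting rule: asbestos fibers > %g um; stop: %s\n",
              x$fit$min_length_um, x$fit$stop_reason))
  invisible(x)
}

#' @export
coef.fiber_burden <- function(object, ...) {
  c(concentration = object$concentration)
}

#' @export
confint.fiber_burden <- function(object, parm = "concentration",
                                 level = NULL, ...) {
  if (is.null(level) || isTRUE(all.equal(level, object$ci_level))) {
    ci <- c(object$ci_low, object$ci_high)
    level <- object$ci_level
  } else {
    ci <- poisson_interval(object$n_counted, level) *
      object$analytical_sensitivity
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("concentration",
                                sprintf("%.1f %%",
                                        100 * c((1 - level) / 2,
                                                1 - (1 - level) / 2))))
  out
}

#' Parametric-bootstrap sessions from a fitted burden
#'
#' Draws new counting sessions at the estimated concentration over the
#' same number of fields as the original examination (pure Poisson
#' deposition, no fiber cap), which is the parametric bootstrap for this
#' estimator.
#'
#' @param object A `fiber_burden` fit.
#' @param nsim Number of sessions.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [counting_session()] objects.
#' @export
simulate.fiber_burden <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- simulation_config(true_concentration = object$concentration,
                           prep = object$prep, fiber_cap = Inf,
                           target_as = object$analytical_sensitivity)
  lapply(seq_len(nsim), function(i) simulate_session_impl(cfg))
}

#' Turn a fitted burden into a plain report list
#'
#' @param fit A `fiber_burden` object.
#' @param units `"mil_ff_per_g"` (default) or `"ff_per_g"`.
#' @return A named list suitable for JSON serialisation; echoes every
#'   preparation parameter used.
#' @export
burden_report <- function(fit, units = c("mil_ff_per_g", "ff_per_g")) {
  stopifnot(inherits(fit, "fiber_burden"))
  units <- match.arg(units)
  s <- if (units == "mil_ff_per_g") 1 / MIL else 1
  list(
    units = units,
    concentration = fit$concentration * s,
    n_counted = fit$n_counted,
    n_fields = fit$n_fields,
    poisson_sd = fit$poisson_sd * s,
    poisson_cv_percent = fit$poisson_cv_percent,
    ci_level = fit$ci_level,
    ci_low = fit$ci_low * s,
    ci_high = fit$ci_high * s,
    interval_method = fit$interval_method,
    analytical_sensitivity = fit$analytical_sensitivity * s,
    as_requirement = fit$as_requirement * s,
    as_met = fit$as_met,
    below_as = fit$below_as,
    stop_reason = fit$stop_reason,
    tissue_mass_on_filter_g = fit$tissue_mass_g,
    ash_load_mg_cm2 = fit$ash_load$mg_per_cm2,
    ash_load_over_limit = fit$ash_load$over_limit,
    min_length_um = fit$min_length_um,
    prep = unclass(fit$prep))
}
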