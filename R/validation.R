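#' Standard uncertainty from a CRM's expanded uncertainty
#'
#' Reference-material certificates state an expanded uncertainty `U` (the
#' half-width of the 95% interval of the mean of laboratory means).  The
#' standard uncertainty used in trueness assessment is recovered by
#' dividing out the Student-t coverage factor printed on the certificate,
#' `u = U / t`.  For the lung-tissue CRMs the certificates imply
#' `t = 2.45` (two-sided 95% with 6 degrees of freedom).
#'
#' @param U Expanded uncertainty (same units as the certified value).
#' @param t_factor Coverage factor (> 0).
#' @return Standard uncertainty `u`.
#' @examples
#' u_from_expanded(16, 2.45)   # 6.53
#' u_from_expanded(1.5, 2.45)  # 0.61
#' @export
u_from_expanded <- function(U, t_factor) {
  if (any(U <= 0) || any(t_factor <= 0))
    stop_invalid_input("U and t_factor must be > 0")
  U / t_factor
}

#' Repeatability chi-squared statistic
#'
#' Compares the observed within-laboratory standard deviation `s_w` of
#' replicate measurements with the reference (specified) standard
#' deviation `sigma_w0`: the statistic is `(s_w / sigma_w0)^2`.  For a
#' fiber-counting method the natural reference is the Poisson counting
#' standard deviation (see [poisson_reference_sd()]).
#'
#' @param s_w Observed replicate SD.
#' @param sigma_w0 Specified (reference) SD, > 0.
#' @return The dimensionless statistic.
#' @export
precision_statistic <- function(s_w, sigma_w0) {
  if (any(sigma_w0 <= 0)) stop_invalid_input("sigma_w0 must be > 0")
  if (any(s_w < 0)) stop_invalid_input("s_w must be >= 0")
  (s_w / sigma_w0)^2
}

#' Critical value for the repeatability check
#'
#' The precision verdict compares the chi-squared statistic with the
#' upper quantile of the chi-squared distribution with `n - 1` degrees of
#' freedom divided by `n - 1`; with 8 replicates at the 95% level the
#' threshold is 2.01.
#'
#' @param n Number of replicate measurements (>= 2).
#' @param level Quantile level, default 0.95.
#' @return The threshold.
#' @export
chi2_threshold <- function(n, level = 0.95) {
  if (any(n < 2) || any(n != floor(n)))
    stop_invalid_input("n must be an integer >= 2")
  if (level <= 0 || level >= 1)
    stop_invalid_input("level must be in (0, 1)")
  stats::qchisq(level, df = n - 1) / (n - 1)
}

#' Trueness acceptance bound
#'
#' The difference between the replicate mean and the certified value is
#' acceptable when it does not exceed `k * sqrt(u_meas^2 + u_crm^2)`,
#' the expanded combined standard uncertainty of the comparison
#' (coverage factor `k = 2` for approximately 95% confidence).
#'
#' @param k Coverage factor, > 0.
#' @param u_meas Standard uncertainty of the measurement result.
#' @param u_crm Standard uncertainty of the certified value.
#' @return The bound, same units as the inputs.
#' @export
trueness_bound <- function(k, u_meas, u_crm) {
  if (any(k <= 0)) stop_invalid_input("k must be > 0")
  if (any(u_meas < 0) || any(u_crm < 0))
    stop_invalid_input("uncertainties must be >= 0")
  k * sqrt(u_meas^2 + u_crm^2)
}

#' Poisson reference standard deviation
#'
#' For a counting method stopped at `n_max` fibers, the counting
#' contribution to the replicate SD at concentration `C` is `C /
#' sqrt(n_max)`.  This helper makes the convention explicit; it is never
#' invoked silently — [validate_against_crm()] always takes `sigma_w0` as
#' an argument, because the reference SD is a method specification, not a
#' derived quantity.
#'
#' @param concentration Concentration at which replicates were measured.
#' @param n_max Fiber count at the stop rule (default 50).
#' @return Reference SD in the units of `concentration`.
#' @export
poisson_reference_sd <- function(concentration, n_max = 50) {
  if (any(concentration < 0) || any(n_max < 1))
    stop_invalid_input("concentration must be >= 0 and n_max >= 1")
  concentration / sqrt(n_max)
}

#' Replicate measurement set
#'
#' Holds replicate concentration measurements of one material, either as
#' raw values (via [summarize_replicates()]) or as the published summary
#' (mean, SD, n) when raw values are not available.
#'
#' @param mean Arithmetic mean of the replicates.
#' @param sd Sample standard deviation (n - 1 denominator).
#' @param n Number of replicates (>= 2).
#' @param measurements Optional raw values; when given, `mean`, `sd` and
#'   `n` are derived from them and must not disagree.
#' @return An object of class `"replicate_set"`.
#' @export
replicate_set <- function(mean, sd, n, measurements = NULL) {
  if (!is.null(measurements)) {
    rs <- summarize_replicates(measurements)
    if (!missing(mean) && !isTRUE(all.equal(mean, rs$mean)))
      stop_invalid_input("supplied mean disagrees with raw measurements")
    return(rs)
  }
  if (n < 2 || n != floor(n)) stop_invalid_input("n must be an integer >= 2")
  if (sd < 0) stop_invalid_input("sd must be >= 0")
  structure(list(measurements = NULL, n = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "replicate_set")
}

#' Summarise raw replicate measurements
#'
#' @param values Numeric vector of replicate concentrations, length >= 2.
#' @return A [replicate_set()] with the arithmetic mean and the sample
#'   standard deviation (n - 1 denominator).
#' @export
summarize_replicates <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values))
    stop_invalid_input("need at least 2 non-missing replicate values")
  structure(list(measurements = as.numeric(values),
                 n = length(values),
                 mean = mean(values),
                 sd = stats::sd(values)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set: n = %d, mean = %.4g, sd = %.4g\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Certified reference material descriptor
#'
#' @param name Material name, e.g. `"BCR-665"`.
#' @param certified_value Certified concentration (conventionally mil
#'   ff/g dry for the lung-tissue CRMs).
#' @param expanded_uncertainty Expanded uncertainty `U` of the certified
#'   value, same units.
#' @param t_factor Coverage factor printed on the certificate, used to
#'   recover the standard uncertainty (see [u_from_expanded()]).
#' @param analyte Certified analyte, e.g. `"amosite + crocidolite"`.
#' @return An object of class `"crm_spec"`.
#' @export
crm_spec <- function(name, certified_value, expanded_uncertainty,
                     t_factor = 2.45, analyte = "") {
  if (certified_value <= 0 || expanded_uncertainty <= 0)
    stop_invalid_input("certified value and uncertainty must be > 0")
  if (t_factor <= 1)
    stop_invalid_input("t_factor must be > 1")
  structure(list(name = as.character(name),
                 certified_value = as.numeric(certified_value),
                 expanded_uncertainty = as.numeric(expanded_uncertainty),
                 t_factor = as.numeric(t_factor),
                 analyte = as.character(analyte)),
            class = "crm_spec")
}

#' @export
print.crm_spec <- function(x, ...) {
  cat(sprintf("CRM %s (%s): certified %.4g +/- U = %.4g (t = %.3g)\n",
              x$name, x$analyte, x$certified_value,
              x$expanded_uncertainty, x$t_factor))
  invisible(x)
}

#' Precision and trueness verification against a CRM
#'
#' Assembles the conformity-assessment table for one reference material:
#' the repeatability check compares `(s_w / sigma_w0)^2` with the
#' chi-squared threshold (strict `<`), and the trueness check compares
#' `|mean - certified|` with `k * sqrt(u_meas^2 + u_crm^2)` (`<=`, so
#' boundary equality passes).  `sigma_w0` (the specified within-lab SD,
#' here the Poisson counting SD) and `u_meas` (the standard uncertainty
#' of the measurement result) are supplied values: their derivation is a
#' method-specification choice, and the function never substitutes one
#' silently.
#'
#' @param reps A [replicate_set()] (raw or summary form).
#' @param crm A [crm_spec()].
#' @param sigma_w0 Specified within-laboratory SD, same units.
#' @param u_meas Standard uncertainty of the measurement result, same
#'   units.
#' @param k Trueness coverage factor, default 2.
#' @param level Level for the chi-squared threshold, default 0.95.
#' @return An object of class `"crm_validation"` holding every statistic,
#'   threshold and verdict, plus the inputs used.
#' @examples
#' reps <- replicate_set(mean = 49.6, sd = 7.5, n = 8)
#' crm <- crm_spec("BCR-665", 49.0, 16, 2.45, "amosite + crocidolite")
#' validate_against_crm(reps, crm, sigma_w0 = 7.0, u_meas = 7.4)
#' @export
validate_against_crm <- function(reps, crm, sigma_w0, u_meas, k = 2,
                                 level = 0.95) {
  stopifnot(inherits(reps, "replicate_set"), inherits(crm, "crm_spec"))
  if (missing(sigma_w0) || is.null(sigma_w0) || !is.finite(sigma_w0))
    stop(errorCondition("sigma_w0 must be supplied (method specification)",
                        class = c("fiberburden_config_error",
                                  "fiberburden_error")))
  if (missing(u_meas) || is.null(u_meas) || !is.finite(u_meas))
    stop(errorCondition("u_meas must be supplied (method specification)",
                        class = c("fiberburden_config_error",
                                  "fiberburden_error")))
  u_crm <- u_from_expanded(crm$expanded_uncertainty, crm$t_factor)
  chi2_c <- precision_statistic(reps$sd, sigma_w0)
  chi2_thr <- chi2_threshold(reps$n, level)
  abs_diff <- abs(reps$mean - crm$certified_value)
  bound <- trueness_bound(k, u_meas, u_crm)
  structure(
    list(crm = crm, reps = reps,
         sigma_w0 = sigma_w0, u_meas = u_meas, u_crm = u_crm,
         k = k, level = level,
         chi2_c = chi2_c, chi2_threshold = chi2_thr,
         precision_pass = chi2_c < chi2_thr,
         abs_diff = abs_diff, trueness_bound = bound,
         trueness_pass = abs_diff <= bound),
    class = "crm_validation")
}

#' @export
print.crm_validation <- function(x, ...) {
  cat(sprintf("Method verification against %s (%s)\n",
              x$crm$name, x$crm$analyte))
  cat(sprintf("  replicates      : n = %d, mean = %.4g, s_w = %.4g\n",
              x$reps$n, x$reps$mean, x$reps$sd))
  cat(sprintf("  certified value : %.4g (U = %.4g, t = %.3g, u_CRM = %.3g)\n",
              x$crm$certified_value, x$crm$expanded_uncertainty,
              x$crm$t_factor, x$u_crm))
  cat(sprintf("  precision : chi2 = %.3g %s threshold %.3g  -> %s\n",
              x$chi2_c, if (x$precision_pass) "<" else ">=",
              x$chi2_threshold, if (x$precision_pass) "PASS" else "FAIL"))
  cat(sprintf("  trueness  : |mean - certified| = %.3g %s %g*sqrt(u_meas^2 + u_CRM^2) = %.3g  -> %s\n",
              x$abs_diff, if (x$trueness_pass) "<=" else ">", x$k,
              x$trueness_bound, if (x$trueness_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Read a CRM descriptor (optionally with replicate summary) from JSON
#'
#' Keys: `name`, `certified_value_mil_ffg`, `expanded_uncertainty_mil_ffg`,
#' `t_factor`, `analyte`; optionally a `replicates` object (either
#' `values` or `mean`/`sd`/`n`) and the method-specification values
#' `sigma_w0`, `u_meas`, `k`.
#'
#' @param path JSON file path.
#' @return A list with elements `crm` ([crm_spec()]), and when present
#'   `replicates` ([replicate_set()]), `sigma_w0`, `u_meas`, `k`.
#' @export
read_crm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "certified_value_mil_ffg",
            "expanded_uncertainty_mil_ffg")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_invalid_input(sprintf("%s: missing key(s): %s", path,
                               paste(miss, collapse = ", ")))
  crm <- crm_spec(x$name, x$certified_value_mil_ffg,
                  x$expanded_uncertainty_mil_ffg,
                  if (is.null(x$t_factor)) 2.45 else x$t_factor,
                  if (is.null(x$analyte)) "" else x$analyte)
  out <- list(crm = crm)
  if (!is.null(x$replicates)) {
    r <- x$replicates
    out$replicates <- if (!is.null(r$values))
      summarize_replicates(r$values)
    else replicate_set(mean = r$mean, sd = r$sd, n = r$n)
  }
  out$sigma_w0 <- x$sigma_w0
  out$u_meas <- x$u_meas
  out$k <- x$k
  out
}

#' Flatten a validation result to a report list
#'
#' Mirrors the verification table: every statistic, threshold and verdict,
#' plus the inputs used, ready for JSON serialisation.
#'
#' @param v A `crm_validation` object.
#' @return A named list.
#' @export
validation_report <- function(v) {
  stopifnot(inherits(v, "crm_validation"))
  list(crm_name = v$crm$name,
       analyte = v$crm$analyte,
       certified_value = v$crm$certified_value,
       expanded_uncertainty = v$crm$expanded_uncertainty,
       t_factor = v$crm$t_factor,
       u_crm = v$u_crm,
       n_replicates = v$reps$n,
       mean = v$reps$mean,
       sd = v$reps$sd,
       sigma_w0 = v$sigma_w0,
       u_meas = v$u_meas,
       chi2_c = v$chi2_c,
       chi2_threshold = v$chi2_threshold,
       precision_pass = v$precision_pass,
       abs_diff = v$abs_diff,
       k = v$k,
       trueness_bound = v$trueness_bound,
       trueness_pass = v$trueness_pass,
       level = v$level)
}
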