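#' Configuration for synthetic counting sessions
#'
#' Describes the generative model the uncertainty treatment assumes:
#' countable fibers deposit on the filter homogeneously, so the number
#' found in one SEM field is Poisson with rate `lambda =
#' true_concentration * p_TS * a / A`.  A positive `dispersion` mixes the
#' rate with a mean-one gamma variable per field, giving per-field
#' variance `lambda * (1 + dispersion * lambda)` — the failure mode of an
#' inhomogeneous filter.  Sessions honour the two stop rules: the planned
#' field count from the target sensitivity, or the fiber cap (normally
#' 50), whichever comes first; the field in which the cap is reached is
#' completed before stopping.
#'
#' @param true_concentration True burden, fibers per gram dry tissue.
#' @param prep A [filter_prep()] record.
#' @param dispersion Overdispersion parameter, >= 0 (0 = pure Poisson).
#' @param fiber_cap Stop counting once this many countable fibers have
#'   been recorded (default 50; `Inf` disables the cap).
#' @param target_as Target analytical sensitivity driving the planned
#'   field count, ff/g dry (default 1e5 = 0.1 mil ff/g dry).
#' @param length_meanlog,length_sdlog Log-normal parameters for fiber
#'   lengths in um, truncated just above the 1 um counting cut-off;
#'   cosmetic for count statistics.
#' @param sub_um_fraction Rate of additional sub-micrometre asbestos
#'   fibers, relative to the countable rate; these appear on the count
#'   sheet but must be removed by the counting rule.
#' @param seed Optional integer seed; every simulation entry point
#'   honours it for bit-reproducibility.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(true_concentration, prep, dispersion = 0,
                              fiber_cap = 50, target_as = 1e5,
                              length_meanlog = log(3), length_sdlog = 0.8,
                              sub_um_fraction = 0, seed = NULL) {
  stopifnot(inherits(prep, "filter_prep"))
  if (true_concentration < 0)
    stop_invalid_input("true_concentration must be >= 0")
  if (dispersion < 0) stop_invalid_input("dispersion must be >= 0")
  if (fiber_cap < 1) stop_invalid_input("fiber_cap must be >= 1")
  if (target_as <= 0) stop_invalid_input("target_as must be > 0")
  if (sub_um_fraction < 0 || sub_um_fraction > 1)
    stop_invalid_input("sub_um_fraction must be in [0, 1]")
  structure(list(true_concentration = true_concentration, prep = prep,
                 dispersion = dispersion, fiber_cap = fiber_cap,
                 target_as = target_as,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 sub_um_fraction = sub_um_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from JSON
#'
#' Keys mirror the arguments of [simulation_config()], with the
#' preparation either inline under `prep` or in a separate file named by
#' `prep_path`.
#'
#' @param path JSON file path.
#' @return A [simulation_config()].
#' @export
read_sim_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prep <- if (!is.null(x$prep_path)) {
    read_prep_json(file.path(dirname(path), x$prep_path))
  } else if (!is.null(x$prep)) {
    p <- x$prep
    filter_prep(p$dry_mass_ashed_mg, p$suspension_volume_ml,
                p$filtered_volume_ml, p$active_area_mm2, p$field_area_mm2,
                if (is.null(p$magnification)) 12000L else p$magnification)
  } else stop_invalid_input(sprintf("%s: no 'prep' or 'prep_path'", path))
  args <- x[intersect(names(x), c("true_concentration", "dispersion",
                                  "fiber_cap", "target_as",
                                  "length_meanlog", "length_sdlog",
                                  "sub_um_fraction", "seed"))]
  do.call(simulation_config, c(args, list(prep = prep)))
}

#' Expected countable fibers per microscope field
#'
#' Inverts the concentration formula: at true concentration `C`, one
#' field of area `a` sees on average `lambda = C * p_TS * a / A` fibers.
#'
#' @param config A [simulation_config()].
#' @return The per-field Poisson rate.
#' @export
fibers_per_field_rate <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$prep
  config$true_concentration * tissue_mass_on_filter(p) *
    p$field_area_mm2 / p$active_area_mm2
}

draw_field_counts <- function(n, lambda, dispersion) {
  if (lambda == 0) return(integer(n))
  if (dispersion > 0) {
    g <- stats::rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
    stats::rpois(n, lambda * g)
  } else {
    stats::rpois(n, lambda)
  }
}

# Draw many sessions at once, counts only (no per-fiber attributes).
# Returns n_f, n_fields, capped for each of R sessions.
sim_counts_block <- function(config, R) {
  p <- config$prep
  n_plan <- plan_fields(config$target_as, p)
  lambda <- fibers_per_field_rate(config)
  K <- matrix(draw_field_counts(R * n_plan, lambda, config$dispersion),
              nrow = n_plan, ncol = R)
  if (is.finite(config$fiber_cap) && lambda > 0) {
    CS <- apply(K, 2, cumsum)
    if (n_plan == 1L) CS <- matrix(CS, nrow = 1L)
    first <- colSums(CS < config$fiber_cap) + 1L
    capped <- first <= n_plan
    n_fields <- ifelse(capped, first, n_plan)
    n_f <- CS[cbind(n_fields, seq_len(R))]
  } else {
    capped <- rep(FALSE, R)
    n_fields <- rep(n_plan, R)
    n_f <- colSums(K)
  }
  list(n_f = as.integer(n_f), n_fields = as.integer(n_fields),
       capped = capped)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, min) {
  lo <- stats::plnorm(min, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, 1), meanlog, sdlog)
}

simulate_session_impl <- function(config) {
  p <- config$prep
  n_plan <- plan_fields(config$target_as, p)
  lambda <- fibers_per_field_rate(config)
  counts <- draw_field_counts(n_plan, lambda, config$dispersion)
  cs <- cumsum(counts)
  if (is.finite(config$fiber_cap) && any(cs >= config$fiber_cap)) {
    n_fields <- which(cs >= config$fiber_cap)[1L]
    stop_reason <- "fiber_cap_reached"
  } else {
    n_fields <- n_plan
    stop_reason <- "area_target_reached"
  }
  counts <- counts[seq_len(n_fields)]
  n <- sum(counts)
  field_index <- rep.int(seq_len(n_fields) - 1L, counts)
  # truncate just above the cut-off so printed lengths stay countable
  len <- rtrunc_lnorm(n, config$length_meanlog, config$length_sdlog,
                      min = 1.01)
  cls <- sample(c("amosite", "crocidolite"), n, replace = TRUE)
  if (config$sub_um_fraction > 0 && lambda > 0) {
    extra <- draw_field_counts(n_fields, lambda * config$sub_um_fraction,
                               config$dispersion)
    m <- sum(extra)
    if (m > 0) {
      field_index <- c(field_index, rep.int(seq_len(n_fields) - 1L, extra))
      len <- c(len, stats::runif(m, 0.3, 0.99))
      cls <- c(cls, sample(c("amosite", "crocidolite"), m, replace = TRUE))
      n <- n + m
    }
  }
  width <- pmin(len / stats::runif(n, 3, 20), len)
  fibers <- data.frame(field_index = field_index,
                       length_um = len, width_um = width,
                       mineral_class = cls, stringsAsFactors = FALSE)
  counting_session(fibers, n_fields, stop_reason)
}

#' Simulate one counting session
#'
#' Draws per-field countable-fiber counts under the configured model over
#' the planned field count, applies the stop rules, and attaches fiber
#' attributes (length, width, mineral class) so the session can be
#' written out and re-read like a real count sheet.
#'
#' @param config A [simulation_config()]; its `seed`, when set, makes the
#'   session reproducible.
#' @return A [counting_session()].
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_session_impl(config)
}

#' Simulate a replicate measurement campaign
#'
#' Draws `n_replicates` independent sessions (the CRM verification design
#' analyzed each material eight times) and pushes each through
#' [fiber_burden()].
#'
#' @param config A [simulation_config()]; `seed` governs the whole
#'   campaign.
#' @param n_replicates Number of replicate sessions, >= 1.
#' @param ci_level Confidence level passed to [fiber_burden()].
#' @return A list of `fiber_burden` fits, one per replicate.
#' @export
simulate_campaign <- function(config, n_replicates, ci_level = 0.95) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_replicates < 1) stop_invalid_input("n_replicates must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(n_replicates), function(i) {
    fiber_burden(simulate_session_impl(config), config$prep,
                 ci_level = ci_level, as_requirement = config$target_as)
  })
}

#' Empirical coverage of the concentration confidence interval
#'
#' Simulates many sessions at the configured truth, computes the exact
#' Poisson interval for each (scaled to concentration by the session's
#' analytical sensitivity) and reports the fraction that cover the true
#' concentration.  Works on counts only, which is the part of the model
#' the interval depends on.
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of simulated sessions; must keep the
#'   binomial standard error of the estimated coverage below 0.02.
#' @param level Interval confidence level.
#' @return The empirical coverage proportion.
#' @export
coverage_experiment <- function(config, n_replicates, level = 0.95) {
  stopifnot(inherits(config, "simulation_config"))
  if (sqrt(level * (1 - level) / n_replicates) >= 0.02)
    stop_invalid_input("n_replicates too small: binomial SE must be < 0.02")
  if (!is.null(config$seed)) set.seed(config$seed)
  blk <- sim_counts_block(config, n_replicates)
  as_ffg <- analytical_sensitivity(config$prep, 1) / blk$n_fields
  ci <- poisson_interval(blk$n_f, level)
  lo <- ci[, "low"] * as_ffg
  hi <- ci[, "high"] * as_ffg
  mean(lo <= config$true_concentration &
         config$true_concentration <= hi)
}
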