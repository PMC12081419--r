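#' Filter preparation record
#'
#' Describes how a lyophilized lung-tissue sample was ashed, suspended and
#' filtered onto the membrane examined at the SEM, together with the
#' geometry needed to extrapolate field counts to the whole filter: the
#' active filtration area `A` and the area `a` of one microscope field at
#' the working magnification.  The field area is an instrument calibration
#' value and must always be supplied; it is never assumed.
#'
#' @param dry_mass_ashed_mg Dry tissue mass ashed and suspended, in mg.
#'   Zero is permitted so that procedural blanks (no tissue) can be
#'   represented.
#' @param suspension_volume_ml Volume of water the ash was suspended in, mL.
#' @param filtered_volume_ml Aliquot of the suspension drawn through the
#'   membrane, mL.  Must not exceed `suspension_volume_ml`.
#' @param active_area_mm2 Effective filtration area of the filter holder,
#'   mm^2 (2.22 cm^2 = 222 mm^2 for a 25 mm membrane in a typical funnel).
#' @param field_area_mm2 Area of one SEM field at the working
#'   magnification, mm^2 (calibrated per instrument).
#' @param magnification Nominal magnification the field area was calibrated
#'   at; informational, default 12000.
#'
#' @return An object of class `"filter_prep"`.
#' @examples
#' prep <- filter_prep(100, 100, 20, active_area_mm2 = 222,
#'                     field_area_mm2 = 1e-4)
#' tissue_mass_on_filter(prep)  # 0.020 g
#' @export
filter_prep <- function(dry_mass_ashed_mg, suspension_volume_ml,
                        filtered_volume_ml, active_area_mm2 = 222,
                        field_area_mm2, magnification = 12000L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_invalid_prep(sprintf("'%s' must be a single finite number", nm))
    as.numeric(x)
  }
  dry_mass_ashed_mg   <- num1(dry_mass_ashed_mg, "dry_mass_ashed_mg")
  suspension_volume_ml <- num1(suspension_volume_ml, "suspension_volume_ml")
  filtered_volume_ml  <- num1(filtered_volume_ml, "filtered_volume_ml")
  active_area_mm2     <- num1(active_area_mm2, "active_area_mm2")
  field_area_mm2      <- num1(field_area_mm2, "field_area_mm2")

  if (dry_mass_ashed_mg < 0)
    stop_invalid_prep("dry_mass_ashed_mg must be >= 0")
  if (suspension_volume_ml <= 0)
    stop_invalid_prep("suspension_volume_ml must be > 0")
  if (filtered_volume_ml < 0)
    stop_invalid_prep("filtered_volume_ml must be >= 0")
  if (filtered_volume_ml > suspension_volume_ml)
    stop_invalid_prep("filtered_volume_ml must not exceed suspension_volume_ml")
  if (active_area_mm2 <= 0 || field_area_mm2 <= 0)
    stop_invalid_prep("areas must be > 0")
  if (field_area_mm2 >= active_area_mm2)
    stop_invalid_prep("field_area_mm2 must be smaller than active_area_mm2")

  structure(
    list(dry_mass_ashed_mg = dry_mass_ashed_mg,
         suspension_volume_ml = suspension_volume_ml,
         filtered_volume_ml = filtered_volume_ml,
         active_area_mm2 = active_area_mm2,
         field_area_mm2 = field_area_mm2,
         magnification = as.integer(magnification)),
    class = "filter_prep")
}

stop_invalid_prep <- function(msg) {
  stop(errorCondition(msg, class = c("fiberburden_invalid_prep",
                                     "fiberburden_error")))
}

#' @export
print.filter_prep <- function(x, ...) {
  cat("Filter preparation\n")
  cat(sprintf("  dry tissue ashed : %g mg in %g mL; %g mL filtered\n",
              x$dry_mass_ashed_mg, x$suspension_volume_ml,
              x$filtered_volume_ml))
  cat(sprintf("  tissue on filter : %g mg (p_TS = %g g)\n",
              1000 * tissue_mass_on_filter(x), tissue_mass_on_filter(x)))
  al <- ash_load(x)
  cat(sprintf("  ash load         : %.3g mg/cm^2%s\n", al$mg_per_cm2,
              if (al$over_limit) "  [exceeds advisory limit]" else ""))
  cat(sprintf("  active area A    : %g mm^2; field area a: %g mm^2 (x%d)\n",
              x$active_area_mm2, x$field_area_mm2, x$magnification))
  invisible(x)
}

#' Dry tissue mass deposited on the filter
#'
#' The ash from `dry_mass_ashed_mg` of tissue is suspended in
#' `suspension_volume_ml`; filtering an aliquot deposits a proportional
#' share of the tissue on the membrane (e.g. 100 mg in 100 mL with 20 mL
#' filtered puts 20 mg on the filter).
#'
#' @param prep A [filter_prep()] record.
#' @return Mass of dry tissue represented on the filter, in grams
#'   (`p_TS`).
#' @export
tissue_mass_on_filter <- function(prep) {
  stopifnot(inherits(prep, "filter_prep"))
  prep$dry_mass_ashed_mg *
    (prep$filtered_volume_ml / prep$suspension_volume_ml) / 1000
}

#' Ash load of the filter
#'
#' Dry-tissue equivalent deposited per unit filter area.  A routine
#' preparation (20 mg on 2.22 cm^2) runs at about 9 mg/cm^2; filters above
#' the advisory limit (default 15 mg/cm^2) tend to bury fibers under
#' particulate and are flagged, not rejected.
#'
#' @param prep A [filter_prep()] record.
#' @param limit_mg_cm2 Advisory loading limit, mg of dry lung per cm^2.
#' @return A list with `mg_per_cm2`, logical `over_limit`, and the
#'   `limit_mg_cm2` used.
#' @export
ash_load <- function(prep, limit_mg_cm2 = 15) {
  stopifnot(inherits(prep, "filter_prep"))
  area_cm2 <- prep$active_area_mm2 / 100
  if (area_cm2 <= 0) stop_invalid_prep("active area must be > 0")
  load <- 1000 * tissue_mass_on_filter(prep) / area_cm2
  list(mg_per_cm2 = load,
       over_limit = load > limit_mg_cm2,
       limit_mg_cm2 = limit_mg_cm2)
}

#' Read / write preparation records as JSON
#'
#' The on-disk form uses the keys `dry_mass_ashed_mg`,
#' `suspension_volume_ml`, `filtered_volume_ml`, `active_area_mm2`,
#' `field_area_mm2`, `magnification`.
#'
#' @param path File path.
#' @return `read_prep_json()` returns a [filter_prep()];
#'   `write_prep_json()` returns `path` invisibly.
#' @export
read_prep_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("dry_mass_ashed_mg", "suspension_volume_ml",
            "filtered_volume_ml", "active_area_mm2", "field_area_mm2")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_invalid_prep(sprintf("%s: missing key(s): %s", path,
                              paste(miss, collapse = ", ")))
  filter_prep(x$dry_mass_ashed_mg, x$suspension_volume_ml,
              x$filtered_volume_ml, x$active_area_mm2, x$field_area_mm2,
              if (is.null(x$magnification)) 12000L else x$magnification)
}

#' @param prep A [filter_prep()] record.
#' @rdname read_prep_json
#' @export
write_prep_json <- function(prep, path) {
  stopifnot(inherits(prep, "filter_prep"))
  jsonlite::write_json(unclass(prep), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
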