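# Shared fixtures: the routine preparation (100 mg dry tissue in 100 mL,
# 20 mL filtered, 2.22 cm^2 active area, calibrated field area 1e-4 mm^2)
# and quick builders for fiber tables and sessions.

default_prep <- function(...) {
  args <- utils::modifyList(
    list(dry_mass_ashed_mg = 100, suspension_volume_ml = 100,
         filtered_volume_ml = 20, active_area_mm2 = 222,
         field_area_mm2 = 1e-4, magnification = 12000L),
    list(...))
  do.call(filter_prep, args)
}

fiber_tbl <- function(length_um, mineral_class = "amosite",
                      field_index = 0L, width_um = NULL) {
  n <- max(length(length_um), length(mineral_class), length(field_index))
  length_um <- rep_len(length_um, n)
  if (is.null(width_um)) width_um <- pmin(0.2, length_um)
  data.frame(field_index = rep_len(field_index, n),
             length_um = length_um,
             width_um = rep_len(width_um, n),
             mineral_class = rep_len(mineral_class, n),
             stringsAsFactors = FALSE)
}

random_fiber_tbl <- function(n, n_fields = 10L) {
  len <- round(stats::rlnorm(n, log(1.2), 0.9), 3)
  len <- pmax(len, 0.05)
  data.frame(field_index = sample.int(n_fields, n, replace = TRUE) - 1L,
             length_um = len,
             width_um = pmin(len, round(stats::runif(n, 0.02, 1), 3)),
             mineral_class = sample(mineral_classes(), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

session_with_n <- function(n_f, n_fields = 100L, length_um = 2) {
  fibers <- if (n_f > 0)
    fiber_tbl(rep(length_um, n_f),
              field_index = rep_len(seq_len(min(n_f, n_fields)) - 1L, n_f))
  else NULL
  counting_session(fibers, n_fields)
}

bcr665_path <- function() system.file("extdata", "bcr665.json",
                                      package = "fiberburden")
bcr666_path <- function() system.file("extdata", "bcr666.json",
                                      package = "fiberburden")
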