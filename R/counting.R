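#' Mineral classes recognised on a count sheet
#'
#' The six regulated asbestos minerals plus a catch-all for structures
#' identified by EDS as something else (gypsum, talc, diatoms, ...).
#' @export
mineral_classes <- function() {
  c("chrysotile", "amosite", "crocidolite", "anthophyllite",
    "tremolite", "actinolite", "non_asbestos")
}

asbestos_classes <- function() setdiff(mineral_classes(), "non_asbestos")

validate_fibers <- function(fibers) {
  if (is.null(fibers))
    fibers <- empty_fiber_table()
  if (!is.data.frame(fibers))
    stop_invalid_input("fibers must be a data frame")
  need <- c("field_index", "length_um", "width_um", "mineral_class")
  miss <- setdiff(need, names(fibers))
  if (length(miss))
    stop_invalid_input(sprintf("fiber table missing column(s): %s",
                               paste(miss, collapse = ", ")))
  fibers <- fibers[need]
  if (nrow(fibers)) {
    if (any(fibers$field_index < 0) ||
        any(fibers$field_index != floor(fibers$field_index)))
      stop_invalid_input("field_index must be a non-negative integer")
    if (any(fibers$length_um <= 0) || any(fibers$width_um <= 0))
      stop_invalid_input("fiber length and width must be > 0")
    if (any(fibers$length_um < fibers$width_um))
      stop_invalid_input("fiber length must be >= width")
    bad <- setdiff(unique(fibers$mineral_class), mineral_classes())
    if (length(bad))
      stop_invalid_input(sprintf("unknown mineral_class: %s",
                                 paste(bad, collapse = ", ")))
  }
  fibers$field_index <- as.integer(fibers$field_index)
  fibers
}

empty_fiber_table <- function() {
  data.frame(field_index = integer(), length_um = numeric(),
             width_um = numeric(), mineral_class = character(),
             stringsAsFactors = FALSE)
}

stop_invalid_input <- function(msg) {
  stop(errorCondition(msg, class = c("fiberburden_invalid_input",
                                     "fiberburden_error")))
}

#' A counting session
#'
#' One SEM examination of a membrane filter: the number of fields fully
#' examined, every structure recorded on the count sheet, and why the
#' examination stopped — either the planned filter area was covered
#' (`"area_target_reached"`) or the fiber cap, normally 50, was hit first
#' (`"fiber_cap_reached"`).
#'
#' @param fibers Data frame with columns `field_index` (0-based),
#'   `length_um`, `width_um`, `mineral_class`; one row per recorded
#'   structure.  `NULL` or zero rows for a blank field series.
#' @param n_fields_examined Number of fields fully examined (`N_fields`).
#' @param stop_reason Why counting stopped.
#' @return An object of class `"counting_session"`.
#' @export
counting_session <- function(fibers = NULL, n_fields_examined,
                             stop_reason = c("area_target_reached",
                                             "fiber_cap_reached")) {
  stop_reason <- match.arg(stop_reason)
  fibers <- validate_fibers(fibers)
  if (!is.numeric(n_fields_examined) || length(n_fields_examined) != 1L ||
      n_fields_examined < 1 ||
      n_fields_examined != floor(n_fields_examined))
    stop_invalid_input("n_fields_examined must be an integer >= 1")
  n_fields_examined <- as.integer(n_fields_examined)
  if (nrow(fibers) && any(fibers$field_index >= n_fields_examined))
    stop_invalid_input("every field_index must be < n_fields_examined")
  structure(list(fibers = fibers,
                 n_fields_examined = n_fields_examined,
                 stop_reason = stop_reason),
            class = "counting_session")
}

#' @export
print.counting_session <- function(x, ...) {
  cat(sprintf("Counting session: %d field(s) examined, %d structure(s) recorded\n",
              x$n_fields_examined, nrow(x$fibers)))
  cat(sprintf("  countable asbestos fibers (>1 um): %d\n",
              countable_fibers(x$fibers)))
  cat(sprintf("  stopped because: %s\n", x$stop_reason))
  invisible(x)
}

#' Count fibers that satisfy the counting rule
#'
#' A recorded structure contributes to the fiber count `n_f` when it is an
#' asbestos mineral and strictly longer than the length cut-off.  The
#' default cut-off of 1 um matches the certification basis of the
#' available lung-tissue reference materials (amphibole fibers > 1 um);
#' a fiber of exactly 1 um is not counted.
#'
#' @param fibers A fiber table (see [counting_session()]) or a
#'   `counting_session`.
#' @param min_length_um Length cut-off in micrometres; fibers must exceed
#'   it strictly.
#' @return Integer count `n_f`.
#' @examples
#' f <- data.frame(field_index = 0L, length_um = c(0.8, 3, 5),
#'                 width_um = c(0.1, 0.2, 0.5),
#'                 mineral_class = c("chrysotile", "amosite", "non_asbestos"))
#' countable_fibers(f)  # 1
#' @export
countable_fibers <- function(fibers, min_length_um = 1) {
  if (inherits(fibers, "counting_session")) fibers <- fibers$fibers
  fibers <- validate_fibers(fibers)
  if (!nrow(fibers)) return(0L)
  sum(fibers$mineral_class %in% asbestos_classes() &
        fibers$length_um > min_length_um)
}

#' Read / write count sheets
#'
#' Count sheets are plain CSV files with header
#' `field_index,length_um,width_um,mineral_class` and one row per recorded
#' structure.  Fields examined without any structure appear only through
#' the session-level `n_fields_examined`, which travels separately.
#'
#' @param path File path.
#' @return `read_count_sheet()` returns a validated fiber table.
#' @export
read_count_sheet <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fibers(x)
}

#' @param fibers A fiber table.
#' @rdname read_count_sheet
#' @export
write_count_sheet <- function(fibers, path) {
  fibers <- validate_fibers(fibers)
  utils::write.csv(fibers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a full counting session (count sheet + session JSON)
#'
#' The companion JSON carries `n_fields_examined` and optionally
#' `stop_reason`; the CSV carries the per-structure records.
#'
#' @param counts_path Count-sheet CSV path.
#' @param session_path Session JSON path, or `NULL` if `n_fields` is given
#'   directly.
#' @param n_fields Number of fields examined, used when no session JSON is
#'   supplied.
#' @param stop_reason Stop reason override.
#' @return A [counting_session()].
#' @export
read_session <- function(counts_path, session_path = NULL, n_fields = NULL,
                         stop_reason = NULL) {
  fibers <- read_count_sheet(counts_path)
  if (!is.null(session_path)) {
    meta <- jsonlite::read_json(session_path, simplifyVector = TRUE)
    if (is.null(n_fields)) n_fields <- meta$n_fields_examined
    if (is.null(stop_reason)) stop_reason <- meta$stop_reason
  }
  if (is.null(n_fields))
    stop_invalid_input("n_fields_examined not given (flag or session JSON)")
  counting_session(fibers, n_fields,
                   if (is.null(stop_reason)) "area_target_reached"
                   else stop_reason)
}

#' @param session A [counting_session()].
#' @rdname read_session
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "counting_session"))
  jsonlite::write_json(list(n_fields_examined = session$n_fields_examined,
                            stop_reason = session$stop_reason),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
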