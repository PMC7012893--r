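#' Read the package's CSV dialects
#'
#' Thin readr wrappers for the tabular inputs the analyses consume:
#' particle coordinates (`x_nm`, `y_nm`, `species`), ACV measurement rows
#' (`i_avg_amps`, `n_electrons`, `f_hz`, `e_ac_v`, `t_k`, `area_cm2`),
#' calibration tables (`concentration_m`, `signal_a`, `replicate`; rows
#' with concentration 0 are blanks), and cohort tables (`sample_id`,
#' `group`, one column per marker).
#'
#' @param file Path to a CSV file.
#' @param region Optional rectangle for [point_pattern()].
#' @return A tibble (a `point_pattern` for `read_point_pattern()`).
#' @name behkit_io
NULL

#' @rdname behkit_io
#' @export
read_point_pattern <- function(file, region = NULL) {
  point_pattern(readr::read_csv(file, show_col_types = FALSE), region = region)
}

#' @rdname behkit_io
#' @export
read_acv_table <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' @rdname behkit_io
#' @export
read_calibration_table <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' @rdname behkit_io
#' @export
read_cohort <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}
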