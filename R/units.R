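#' Convert blood pressure from mmHg to kPa
#'
#' Exact conversion (1 mmHg = 0.1333224 kPa). The clinical literature usually
#' truncates to one decimal when quoting pressures in kPa, e.g. 110 mmHg is
#' quoted as 14.6 kPa; [kpa_1dp()] reproduces that convention.
#'
#' @param mmhg Pressure in millimetres of mercury.
#' @return Pressure in kPa.
#' @examples
#' mmhg_to_kpa(110)
#' kpa_1dp(mmhg_to_kpa(110)) # 14.6, the quoted mean intracoronary pressure
#' @export
mmhg_to_kpa <- function(mmhg) {
  mmhg * 0.1333224
}

#' @rdname mmhg_to_kpa
#' @param kpa Pressure in kPa.
#' @export
kpa_1dp <- function(kpa) {
  floor(kpa * 10) / 10
}
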