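#' Convert a mass concentration to a molar concentration
#'
#' Serum drug and albumin levels are conventionally reported in mg/L (or
#' g/dL), while mass-action binding kinetics require molar units. The
#' internal unit system of the package is micromolar (uM).
#'
#' @param c Concentration in mg/L. May be a vector.
#' @param mw Molecular weight in g/mol (scalar, > 0).
#' @return Concentration in uM.
#' @examples
#' mgL_to_uM(20, 252.27)   # 20 mg/L phenytoin, ~79.3 uM
#' @export
mgL_to_uM <- function(c, mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0) {
    stop("`mw` must be a single positive number (g/mol), got: ", mw)
  }
  1000 * c / mw
}

#' Convert a molar concentration to a mass concentration
#'
#' Inverse of [mgL_to_uM()].
#'
#' @param c Concentration in uM. May be a vector.
#' @param mw Molecular weight in g/mol (scalar, > 0).
#' @return Concentration in mg/L.
#' @export
uM_to_mgL <- function(c, mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0) {
    stop("`mw` must be a single positive number (g/mol), got: ", mw)
  }
  c * mw / 1000
}
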