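#' ANSI Z136.1 maximum permissible exposure for skin
#'
#' Long-exposure (continuous wave, duration > 10 s) skin MPE in the
#' 700-1400 nm band: `0.2 * CA` W/cm^2 with the spectral correction
#' `CA = 10^(2 (lambda - 0.700))` (lambda in micrometres) for
#' 0.700-1.050 um and `CA = 5` for 1.050-1.400 um. The limit is computed in
#' W/cm^2 per the standard and reported in mW/mm^2 (1 W/cm^2 = 10 mW/mm^2).
#' Shorter-exposure branches of the standard are out of scope and refused.
#'
#' @param wavelength_nm Wavelength, nm (700-1400).
#' @param duration_s Exposure duration, s (> 10).
#' @return Limit in mW/mm^2.
#' @examples
#' mpe_skin(810)   # 3.32 mW/mm^2
#' mpe_skin(1070)  # 10.0 mW/mm^2
#' @export
mpe_skin <- function(wavelength_nm, duration_s = 100) {
  .check_band(wavelength_nm)
  if (duration_s <= 10)
    stop("branch unsupported: only the long-exposure (> 10 s) skin MPE is implemented")
  ca <- .ansi_CA(wavelength_nm)
  limit_w_cm2 <- 0.2 * ca
  limit_w_cm2 * 10 # -> mW/mm^2
}

#' ANSI Z136.1 extended-source ocular maximum permissible exposure
#'
#' Long-exposure ocular MPE for an extended source of angular subtense
#' `alpha` in the 700-1400 nm band:
#' `CE = min(alpha, 100) / 1.5`,
#' `T2 = 10 * 10^((min(alpha, 100) - 1.5) / 98.5)` s (100 s at
#' alpha >= 100 mrad), and
#' limit `1.8 * CA * CE * T2^(-1/4)` mW/cm^2 for 700-1050 nm or
#' `9.0 * CC * CE * T2^(-1/4)` mW/cm^2 for 1050-1400 nm (CC = 1 for
#' 1050-1150 nm), reported in mW/mm^2. Exposures shorter than T2 and
#' point-source geometries (alpha < 1.5 mrad) are outside the implemented
#' branch and refused.
#'
#' @param wavelength_nm Wavelength, nm (700-1400; the 1050-1400 branch is
#'   implemented for 1050-1150 nm where CC = 1).
#' @param alpha_mrad Angular subtense of the source at the eye, mrad
#'   (>= 1.5; capped at 100).
#' @param duration_s Exposure duration, s (>= T2).
#' @return Limit in mW/mm^2.
#' @examples
#' mpe_ocular_extended(810, alpha_mrad = 100)   # 0.63 mW/mm^2
#' mpe_ocular_extended(1070, alpha_mrad = 100)  # 1.90 mW/mm^2
#' @export
mpe_ocular_extended <- function(wavelength_nm, alpha_mrad, duration_s = 100) {
  .check_band(wavelength_nm)
  if (alpha_mrad < 1.5)
    stop("point-source branch unsupported: alpha must be >= 1.5 mrad")
  alpha <- min(alpha_mrad, 100)
  ce <- alpha / 1.5
  t2 <- 10 * 10^((alpha - 1.5) / 98.5)
  if (duration_s < t2)
    stop(sprintf("branch unsupported: duration must be >= T2 = %.3g s", t2))
  limit_mw_cm2 <- if (wavelength_nm < 1050) {
    1.8 * .ansi_CA(wavelength_nm) * ce * t2^(-0.25)
  } else {
    if (wavelength_nm > 1150)
      stop("the 1150-1400 nm CC branch is not implemented")
    cc <- 1.0
    9.0 * cc * ce * t2^(-0.25)
  }
  limit_mw_cm2 / 100 # mW/cm^2 -> mW/mm^2
}

.check_band <- function(wavelength_nm) {
  if (wavelength_nm < 700 || wavelength_nm > 1400)
    stop("wavelength outside the supported 700-1400 nm band")
  invisible(wavelength_nm)
}

.ansi_CA <- function(wavelength_nm) {
  um <- wavelength_nm / 1000
  if (um < 1.050) 10^(2 * (um - 0.700)) else 5.0
}

#' Safety margin against an exposure limit
#'
#' Ratio of a measured (or simulated) fluence rate to an MPE limit; the
#' exposure passes when the margin does not exceed 1 (boundary inclusive).
#'
#' @param measured_mw_mm2 Measured fluence rate, mW/mm^2 (> 0).
#' @param limit_mw_mm2 MPE limit, mW/mm^2 (> 0).
#' @param basis Label for the limit ("skin" or "ocular_extended").
#' @return List of class `mpe_result`: `limit`, `measured`, `margin`,
#'   `pass`, `basis`.
#' @export
safety_margin <- function(measured_mw_mm2, limit_mw_mm2,
                          basis = c("skin", "ocular_extended")) {
  basis <- match.arg(basis)
  if (measured_mw_mm2 <= 0 || limit_mw_mm2 <= 0)
    stop("measured fluence and limit must be positive")
  margin <- measured_mw_mm2 / limit_mw_mm2
  structure(list(limit = limit_mw_mm2, measured = measured_mw_mm2,
                 margin = margin, pass = margin <= 1, basis = basis),
            class = "mpe_result")
}

#' @export
print.mpe_result <- function(x, ...) {
  cat(sprintf("MPE check (%s): measured %.4g / limit %.4g mW/mm^2 -> margin %.3g [%s]\n",
              x$basis, x$measured, x$limit, x$margin,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
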