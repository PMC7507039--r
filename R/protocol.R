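#' Acquisition and physiology constants for the DCE-MRI protocol
#'
#' Bundles the scanner and contrast-agent parameters needed by the
#' relaxometry and kinetics modules. The defaults describe a 3 T brain DCE
#' protocol with a spoiled gradient-echo (e-THRIVE type) dynamic sequence:
#' TR 3.2 ms, TE 1.6 ms, a seven-angle variable-flip-angle T1-mapping
#' acquisition (2, 5, 10, 15, 20, 25, 30 degrees), 45 dynamic frames, and a
#' single dose of 0.1 mmol/kg gadodiamide.
#'
#' Frame spacing (`dt`), the number of pre-contrast frames (`n_baseline`),
#' the gadodiamide longitudinal relaxivity and the hematocrit are not part
#' of the acquisition prescription and carry literature defaults: 8 s
#' frames (45 frames span about 6 minutes), 5 baseline frames, r1 = 3.6
#' /(s mM) at 3 T, hematocrit 0.45. All are overridable.
#'
#' @param tr Repetition time in seconds.
#' @param te Echo time in seconds (carried for provenance; not used by the
#'   T1-weighted signal model).
#' @param flip_angles Flip angles of the VFA T1-mapping acquisition, degrees.
#' @param flip_angle_dyn Flip angle of the dynamic series, degrees.
#' @param n_dynamics Number of dynamic frames.
#' @param dt Dynamic frame spacing in seconds.
#' @param n_baseline Number of pre-contrast (baseline) frames.
#' @param relaxivity_r1 Longitudinal relaxivity of the contrast agent,
#'   1/(s mM).
#' @param hematocrit Hematocrit fraction in `[0, 1)`; converts whole-blood
#'   to plasma concentration.
#' @param dose Contrast dose, mmol/kg body weight.
#' @return An object of class `scan_protocol` (a validated list).
#' @examples
#' p <- scan_protocol()
#' p$flip_angles
#' @export
scan_protocol <- function(tr = 0.0032,
                          te = 0.0016,
                          flip_angles = c(2, 5, 10, 15, 20, 25, 30),
                          flip_angle_dyn = 15,
                          n_dynamics = 45,
                          dt = 8,
                          n_baseline = 5,
                          relaxivity_r1 = 3.6,
                          hematocrit = 0.45,
                          dose = 0.1) {
  p <- list(tr = tr, te = te, flip_angles = as.numeric(flip_angles),
            flip_angle_dyn = flip_angle_dyn, n_dynamics = as.integer(n_dynamics),
            dt = dt, n_baseline = as.integer(n_baseline),
            relaxivity_r1 = relaxivity_r1, hematocrit = hematocrit, dose = dose)
  class(p) <- "scan_protocol"
  validate_scan_protocol(p)
}

validate_scan_protocol <- function(p) {
  stopifnot(
    "tr must be > 0" = p$tr > 0,
    "te must be >= 0" = p$te >= 0,
    "need at least 2 distinct flip angles" =
      length(unique(p$flip_angles)) >= 2,
    "flip angles must lie in (0, 90] degrees" =
      all(p$flip_angles > 0 & p$flip_angles <= 90),
    "dynamic flip angle must lie in (0, 90]" =
      p$flip_angle_dyn > 0 && p$flip_angle_dyn <= 90,
    "n_dynamics must be >= 2" = p$n_dynamics >= 2,
    "dt must be > 0" = p$dt > 0,
    "n_baseline must be >= 1 and < n_dynamics" =
      p$n_baseline >= 1 && p$n_baseline < p$n_dynamics,
    "relaxivity_r1 must be > 0" = p$relaxivity_r1 > 0,
    "hematocrit must be in [0, 1)" = p$hematocrit >= 0 && p$hematocrit < 1,
    "dose must be > 0" = p$dose > 0
  )
  p
}

#' Frame times of the dynamic series
#'
#' @param protocol A [scan_protocol()].
#' @return Numeric vector of `n_dynamics` acquisition times in seconds,
#'   starting at 0.
#' @export
frame_times <- function(protocol) {
  (seq_len(protocol$n_dynamics) - 1) * protocol$dt
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("DCE-MRI scan protocol\n")
  cat(sprintf("  TR %.2f ms, TE %.2f ms\n", x$tr * 1000, x$te * 1000))
  cat(sprintf("  VFA angles: %s deg; dynamic angle %g deg\n",
              paste(x$flip_angles, collapse = ", "), x$flip_angle_dyn))
  cat(sprintf("  %d dynamic frames at %.1f s (%d baseline)\n",
              x$n_dynamics, x$dt, x$n_baseline))
  cat(sprintf("  r1 %.2f /(s mM), Hct %.2f, dose %.2f mmol/kg\n",
              x$relaxivity_r1, x$hematocrit, x$dose))
  invisible(x)
}
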