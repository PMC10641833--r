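# Unit conventions used throughout the package:
#   length  : angstrom (A)
#   time    : ps
#   pressure: bar
#   tension : mN/m
#   diffusion coefficient: 1e-9 cm^2/s
#
# All conversion constants live here; nothing else in the package hard-codes
# a unit factor. Silent unit drift in the pressure-tensor route is the main
# failure mode, so the bar*A -> mN/m factor is written out once.

#' Unit-conversion constants
#'
#' Named vector of the fixed unit conversions used by the package:
#' \describe{
#'   \item{bar_A_to_mN_per_m}{1 bar * 1 A = 0.01 mN/m (1 bar = 1e5 Pa = 1e5
#'     N/m^2; times 1e-10 m gives 1e-5 N/m = 0.01 mN/m).}
#'   \item{A2_per_ps_to_1e9_cm2_per_s}{1 A^2/ps = 1e-16 cm^2 / 1e-12 s =
#'     1e-4 cm^2/s = 1e5 in units of 1e-9 cm^2/s.}
#'   \item{nm_to_A}{10.}
#' }
#'
#' @return Named numeric vector of conversion factors.
#' @examples
#' mm_units()[["bar_A_to_mN_per_m"]]
#' @export
mm_units <- function() {
  c(
    bar_A_to_mN_per_m = 0.01,
    A2_per_ps_to_1e9_cm2_per_s = 1e5,
    nm_to_A = 10
  )
}
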