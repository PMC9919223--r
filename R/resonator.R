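#' Thickness-shear resonator
#'
#' Describes an AT-cut quartz plate by its fundamental resonance frequency and
#' the shear-wave impedance of quartz. The areal mass of the plate follows as
#' `mq = Zq / (2 * f0)`.
#'
#' @param f0 Fundamental resonance frequency in Hz (default 5 MHz, the most
#'   common QCM-D crystal).
#' @param Zq Shear-wave impedance of AT-cut quartz in kg m^-2 s^-1. The default
#'   8.8e6 is the standard value and is consistent with the familiar mass
#'   sensitivity of 5.7 Hz per nm (density 1 g/cm^3) on a 5 MHz crystal.
#' @return An object of class `resonator` with fields `f0`, `Zq` and `mq`.
#' @examples
#' res <- resonator()
#' res$mq * 2 * res$f0 == res$Zq
#' @export
resonator <- function(f0 = 5e6, Zq = 8.8e6) {
  stopifnot(is.numeric(f0), length(f0) == 1L, is.finite(f0), f0 > 0,
            is.numeric(Zq), length(Zq) == 1L, is.finite(Zq), Zq > 0)
  structure(list(f0 = f0, Zq = Zq, mq = Zq / (2 * f0)), class = "resonator")
}

#' @export
print.resonator <- function(x, ...) {
  cat(sprintf("<resonator> f0 = %g MHz, Zq = %g kg m-2 s-1, mq = %g kg m-2\n",
              x$f0 / 1e6, x$Zq, x$mq))
  invisible(x)
}

#' Sauerbrey frequency shift of a rigid film
#'
#' For a rigid film the overtone-normalized frequency shift is proportional to
#' the areal mass: `df/n = -mf * f0 / mq = -2 f0^2 mf / Zq`, independent of the
#' overtone order.
#'
#' @param res A [resonator()].
#' @param m_f Areal mass of the film in kg m^-2 (>= 0). May be a vector.
#' @return Overtone-normalized frequency shift `df/n` in Hz (<= 0).
#' @seealso [sauerbrey_mass()] for the inverse.
#' @examples
#' sauerbrey(resonator(), 1e-6)  # 1 nm at 1 g/cm^3 -> about -5.7 Hz
#' @export
sauerbrey <- function(res, m_f) {
  stopifnot(inherits(res, "resonator"), is.numeric(m_f), all(m_f >= 0))
  -m_f * res$f0 / res$mq
}

#' Invert the Sauerbrey relation
#'
#' @param df_over_n Overtone-normalized frequency shift in Hz (<= 0 for a
#'   physical film).
#' @inheritParams sauerbrey
#' @return Areal mass in kg m^-2.
#' @export
sauerbrey_mass <- function(res, df_over_n) {
  stopifnot(inherits(res, "resonator"), is.numeric(df_over_n))
  -df_over_n * res$mq / res$f0
}

#' Convert a dissipation-factor shift to a half-bandwidth shift
#'
#' The half-bandwidth is related to the dissipation factor by
#' `Gamma = D * f_res / 2`, so `dGamma/n = dD * f0 / 2` independent of the
#' overtone order. For a 5 MHz crystal this is 2.5 Hz per ppm of dD.
#'
#' @param dD Dissipation-factor shift, in the units declared by `unit`.
#' @param res A [resonator()].
#' @param unit Either `"ppm"` (dD given in parts per million, the common
#'   instrument convention) or `"absolute"`.
#' @return Overtone-normalized half-bandwidth shift `dGamma/n` in Hz.
#' @examples
#' dissipation_to_bandwidth(1, resonator())  # 2.5 Hz
#' @export
dissipation_to_bandwidth <- function(dD, res, unit = c("ppm", "absolute")) {
  stopifnot(inherits(res, "resonator"), is.numeric(dD))
  unit <- match.arg(unit)
  scale <- if (unit == "ppm") 1e-6 else 1
  dD * scale * res$f0 / 2
}

#' Convert a half-bandwidth shift to a dissipation-factor shift
#'
#' Inverse of [dissipation_to_bandwidth()].
#'
#' @param dG_over_n Overtone-normalized half-bandwidth shift in Hz.
#' @inheritParams dissipation_to_bandwidth
#' @return Dissipation shift in the requested units.
#' @export
bandwidth_to_dissipation <- function(dG_over_n, res, unit = c("ppm", "absolute")) {
  stopifnot(inherits(res, "resonator"), is.numeric(dG_over_n))
  unit <- match.arg(unit)
  scale <- if (unit == "ppm") 1e-6 else 1
  dG_over_n * 2 / res$f0 / scale
}
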