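#' Power-law viscoelastic material
#'
#' In the roughly one decade of frequency covered by a QCM-D experiment,
#' viscoelastic spectra are smooth and are well approximated by power laws.
#' A material is therefore described by two values at a reference frequency
#' `f_cen` together with two power-law exponents, in any of four equivalent
#' representations:
#'
#' * `"compliance"`: shear compliance `J = J' - i J''` (Pa^-1); the natural
#'   choice for QCM-D because the rigid (Sauerbrey) limit is `J = 0`.
#' * `"modulus"`: shear modulus `G = G' + i G''` (Pa).
#' * `"viscosity"`: complex viscosity `eta = G/(i omega) = eta' - i eta''`
#'   (Pa s); natural for nearly Newtonian layers.
#' * `"magnitude_loss"`: modulus magnitude `|G|` (Pa) and loss tangent
#'   `tan delta = G''/G' = J''/J' = eta'/eta''` (dimensionless).
#'
#' The two power laws act on the representation's own pair:
#' `value1(f) = value1_cen * (f/f_cen)^beta1` and likewise for `value2`.
#' Evaluating the material at `f = f_cen` therefore returns the stored values
#' unchanged.
#'
#' A material with both compliance values zero is the rigid (Sauerbrey) limit
#' and is handled exactly throughout the package.
#'
#' @param representation One of `"compliance"`, `"modulus"`, `"viscosity"`,
#'   `"magnitude_loss"`.
#' @param value1,value2 The two material values at `f_cen`, in the units of the
#'   chosen representation (see above). Must be >= 0; `value2 > 0` is required
#'   for `"magnitude_loss"` with nonzero `value1` (a lossless material should
#'   use another representation).
#' @param beta1,beta2 Dimensionless power-law exponents (0 = no dispersion).
#' @param f_cen Reference frequency in Hz; 30 MHz sits in the middle of the
#'   overtone range of a 5 MHz crystal and is the customary choice.
#' @param rho Density in kg m^-3.
#' @return An object of class `power_law_material`.
#' @examples
#' # the soft-adsorbate film used throughout the examples
#' soft <- power_law_material("compliance", 0.29e-6, 1.68e-6,
#'                            beta1 = -1.61, beta2 = -0.91)
#' evaluate_material(soft, 15e6)
#' @export
power_law_material <- function(representation = c("compliance", "modulus",
                                                  "viscosity", "magnitude_loss"),
                               value1, value2, beta1 = 0, beta2 = 0,
                               f_cen = 30e6, rho = 1000) {
  representation <- match.arg(representation)
  stopifnot(is.numeric(value1), length(value1) == 1L, is.finite(value1),
            is.numeric(value2), length(value2) == 1L, is.finite(value2),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1),
            is.numeric(beta2), length(beta2) == 1L, is.finite(beta2),
            is.numeric(f_cen), f_cen > 0, is.numeric(rho), rho > 0)
  if (value1 < 0 || value2 < 0)
    stop("material values must be non-negative")
  rigid <- representation == "compliance" && value1 == 0 && value2 == 0
  if (!rigid && representation != "compliance" && value1 == 0 && value2 == 0)
    stop("zero stiffness is only meaningful in the compliance representation ",
         "(the rigid limit J = 0)")
  structure(list(representation = representation,
                 value1 = value1, value2 = value2,
                 beta1 = beta1, beta2 = beta2,
                 f_cen = f_cen, rho = rho, rigid = rigid),
            class = "power_law_material")
}

#' @export
print.power_law_material <- function(x, ...) {
  lab <- switch(x$representation,
                compliance = c("J'", "J''", "Pa-1"),
                modulus = c("G'", "G''", "Pa"),
                viscosity = c("eta'", "eta''", "Pa s"),
                magnitude_loss = c("|G|", "tan delta", "Pa / -"))
  cat(sprintf("<power_law_material> %s: %s = %g, %s = %g [%s] at %g MHz\n",
              x$representation, lab[1], x$value1, lab[2], x$value2, lab[3],
              x$f_cen / 1e6))
  cat(sprintf("  beta1 = %g, beta2 = %g, rho = %g kg m-3%s\n",
              x$beta1, x$beta2, x$rho, if (x$rigid) " (rigid)" else ""))
  invisible(x)
}

#' Convert a pair of viscoelastic values between representations
#'
#' Applies the identities `G = 1/J`, `eta = G/(i omega)` and
#' `tan delta = G''/G' = J''/J' = eta'/eta''`. The loss tangent is independent
#' of the representation. Round trips are identities to floating-point
#' tolerance.
#'
#' @param values Numeric vector of length 2: the pair in `from` convention
#'   (`c(J1, J2)`, `c(G1, G2)`, `c(eta1, eta2)` or `c(Gabs, tand)`).
#' @param from,to Representation tags as in [power_law_material()].
#' @param omega Angular frequency in rad s^-1; required whenever `from` or
#'   `to` is `"viscosity"`.
#' @return Numeric vector of length 2 in the `to` convention.
#' @examples
#' convert_representation(c(1, 0), "modulus", "compliance")  # c(1, 0)
#' @export
convert_representation <- function(values, from, to, omega = NULL) {
  reps <- c("compliance", "modulus", "viscosity", "magnitude_loss")
  from <- match.arg(from, reps)
  to <- match.arg(to, reps)
  stopifnot(is.numeric(values), length(values) == 2L, all(is.finite(values)))
  if ((from == "viscosity" || to == "viscosity") && is.null(omega))
    stop("omega is required for viscosity conversions")
  G <- complex_modulus_from_pair(values, from, omega)
  pair_from_complex_modulus(G, to, omega)
}

# pair in a named representation -> complex shear modulus G' + iG''
complex_modulus_from_pair <- function(values, representation, omega = NULL) {
  v1 <- values[[1]]; v2 <- values[[2]]
  switch(representation,
    modulus = complex(real = v1, imaginary = v2),
    compliance = {
      J <- complex(real = v1, imaginary = -v2)
      if (Mod(J) == 0) stop("cannot invert a zero compliance")
      1 / J
    },
    viscosity = {
      eta <- complex(real = v1, imaginary = -v2)
      1i * omega * eta
    },
    magnitude_loss = {
      # G' = |G|/sqrt(1+t^2), G'' = G' * t
      t <- v2
      G1 <- v1 / sqrt(1 + t^2)
      complex(real = G1, imaginary = G1 * t)
    })
}

pair_from_complex_modulus <- function(G, representation, omega = NULL) {
  switch(representation,
    modulus = c(Re(G), Im(G)),
    compliance = {
      if (Mod(G) == 0) stop("cannot invert a zero modulus")
      J <- 1 / G
      c(Re(J), -Im(J))
    },
    viscosity = {
      eta <- G / (1i * omega)
      c(Re(eta), -Im(eta))
    },
    magnitude_loss = {
      if (Re(G) == 0) c(Mod(G), Inf) else c(Mod(G), Im(G) / Re(G))
    })
}

#' Evaluate a material at a frequency
#'
#' Applies the two power laws in the material's native representation at
#' frequency `f`, converts to a complex shear modulus, and derives all acoustic
#' quantities: the complex wavenumber `k = omega * rho / Z`, the shear-wave
#' impedance `Z = sqrt(rho * G)` on the passivity branch (`Re(Z) > 0`), the
#' penetration depth `delta = -1/Im(k)` and the shear wavelength
#' `lambda = 2 pi / Re(k)`.
#'
#' @param material A [power_law_material()].
#' @param f Frequency in Hz (> 0); for overtone work this is `n * f0`.
#' @return An object of class `acoustic_state`: a list with `f`, `omega`,
#'   `values` (the native pair at `f`), `G` (complex modulus, Pa), `Z` (complex
#'   impedance), `k` (complex wavenumber, m^-1), `delta_pen` (m) and
#'   `lambda_shear` (m). For a rigid material `G`, `Z` are `Inf` and `k = 0`.
#' @export
evaluate_material <- function(material, f) {
  stopifnot(inherits(material, "power_law_material"),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (f <= 0) stop("frequency must be positive")
  omega <- 2 * pi * f
  scale <- f / material$f_cen
  v1 <- material$value1 * scale^material$beta1
  v2 <- material$value2 * scale^material$beta2
  if (material$rigid) {
    st <- list(f = f, omega = omega, values = c(0, 0),
               G = complex(real = Inf, imaginary = Inf),
               Z = complex(real = Inf, imaginary = 0),
               k = 0 + 0i, delta_pen = Inf, lambda_shear = Inf, rigid = TRUE)
    class(st) <- "acoustic_state"
    return(st)
  }
  G <- complex_modulus_from_pair(c(v1, v2), material$representation, omega)
  st <- acoustic_state_from_modulus(G, material$rho, omega)
  st$f <- f
  st$values <- c(v1, v2)
  st$rigid <- FALSE
  st
}

# shared constructor: modulus + density + angular frequency -> wave quantities
acoustic_state_from_modulus <- function(G, rho, omega) {
  Z <- sqrt(rho * as.complex(G))
  if (Re(Z) < 0) Z <- -Z                      # passivity branch
  k <- omega * rho / Z                        # k = omega/c = omega sqrt(rho/G)
  st <- list(omega = omega, G = G, Z = Z, k = k,
             delta_pen = if (Im(k) < 0) -1 / Im(k) else Inf,
             lambda_shear = if (Re(k) > 0) 2 * pi / Re(k) else Inf)
  class(st) <- "acoustic_state"
  st
}

#' @export
print.acoustic_state <- function(x, ...) {
  cat(sprintf("<acoustic_state> omega = %g rad/s\n  G = %g%+gi Pa, Z = %g%+gi kg m-2 s-1\n",
              x$omega, Re(x$G), Im(x$G), Re(x$Z), Im(x$Z)))
  cat(sprintf("  delta_pen = %g nm, lambda_shear = %g nm\n",
              x$delta_pen * 1e9, x$lambda_shear * 1e9))
  invisible(x)
}
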