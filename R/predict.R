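#' Planar film layer
#'
#' @param material A [power_law_material()].
#' @param d Film thickness in m (>= 0). The areal mass is `material$rho * d`.
#' @return An object of class `qcm_layer`.
#' @export
layer <- function(material, d) {
  stopifnot(inherits(material, "power_law_material"),
            is.numeric(d), length(d) == 1L, is.finite(d), d >= 0)
  structure(list(material = material, d = d, m_f = material$rho * d),
            class = "qcm_layer")
}

#' @export
print.qcm_layer <- function(x, ...) {
  cat(sprintf("<qcm_layer> d = %g nm, m_f = %g kg m-2\n", x$d * 1e9, x$m_f))
  print(x$material)
  invisible(x)
}

#' Semi-infinite ambient medium
#'
#' The medium terminating the layer stack: vacuum (or air, acoustically
#' equivalent at these impedances), a Newtonian liquid, or a general
#' viscoelastic half-space.
#'
#' @param kind `"vacuum"`, `"newtonian"` or `"viscoelastic"`.
#' @param rho Density in kg m^-3 (newtonian only; taken from `material` for
#'   viscoelastic media).
#' @param eta Newtonian viscosity in Pa s (newtonian only; `eta'' = 0` by
#'   definition).
#' @param material A [power_law_material()] (viscoelastic only).
#' @return An object of class `bulk_medium`.
#' @examples
#' water <- bulk_medium("newtonian", rho = 1000, eta = 1e-3)
#' @export
bulk_medium <- function(kind = c("vacuum", "newtonian", "viscoelastic"),
                        rho = NULL, eta = NULL, material = NULL) {
  kind <- match.arg(kind)
  if (kind == "newtonian") {
    stopifnot(is.numeric(rho), rho > 0, is.numeric(eta), eta >= 0)
  } else if (kind == "viscoelastic") {
    stopifnot(inherits(material, "power_law_material"))
    rho <- material$rho
  }
  structure(list(kind = kind, rho = rho, eta = eta, material = material),
            class = "bulk_medium")
}

#' @export
print.bulk_medium <- function(x, ...) {
  cat(switch(x$kind,
             vacuum = "<bulk_medium> vacuum/air\n",
             newtonian = sprintf("<bulk_medium> Newtonian liquid, rho = %g kg m-3, eta = %g Pa s\n",
                                 x$rho, x$eta),
             viscoelastic = "<bulk_medium> viscoelastic half-space\n"))
  invisible(x)
}

# complex shear-wave impedance of the ambient at angular frequency omega
bulk_impedance <- function(bulk, omega) {
  switch(bulk$kind,
    vacuum = 0 + 0i,
    newtonian = {
      if (bulk$eta == 0) return(0 + 0i)
      Z <- sqrt(1i * omega * bulk$rho * bulk$eta)
      if (Re(Z) < 0) Z <- -Z
      Z
    },
    viscoelastic = evaluate_material(bulk$material, omega / (2 * pi))$Z)
}

# Overflow-safe complex tangent.  tan(z) = -i (1 - w)/(1 + w) with
# w = exp(-2iz) for Im(z) <= 0 (|w| <= 1), mirrored for Im(z) > 0, so the
# thick-film limit saturates smoothly at -i instead of overflowing.
tan_stable <- function(z) {
  out <- z
  lo <- Im(z) <= 0
  if (any(lo)) {
    w <- exp(-2i * z[lo])
    out[lo] <- -1i * (1 - w) / (1 + w)
  }
  if (any(!lo)) {
    w <- exp(2i * z[!lo])
    out[!lo] <- 1i * (1 - w) / (1 + w)
  }
  out
}

# Transfer the terminating impedance through one layer (impedance looking into
# a slab of impedance Zf, wavenumber kf, thickness d, terminated by Z_term).
# A rigid layer (G -> Inf) adds pure inertia: Z_term + i omega rho d.
transfer_layer <- function(Z_term, st, d, omega, rho) {
  if (isTRUE(st$rigid)) return(Z_term + 1i * omega * rho * d)
  tkd <- tan_stable(st$k * d)
  st$Z * (Z_term + 1i * st$Z * tkd) / (st$Z + 1i * Z_term * tkd)
}

# small-load approximation: complex frequency shift from the load impedance
small_load <- function(res, Z_load) 1i * res$f0 / (pi * res$Zq) * Z_load

#' Exact complex frequency shift of a viscoelastic film
#'
#' Evaluates the standard acoustic-load model for a planar viscoelastic film
#' on a thickness-shear resonator, with no expansion in film thickness (only
#' the small-load approximation is used):
#' `(df + i dGamma)/f0 = -(Zf/(pi Zq)) * (Zf tan(kf df) - i Zbulk) /
#'  (Zf + i Zbulk tan(kf df))`.
#' Material properties are evaluated at `f = n * f0` on each overtone. Complex
#' square roots are taken on the passivity branch `Re(Z) > 0`, and the complex
#' tangent is computed in an overflow-safe form so the thick-film limit
#' saturates at the bulk value of the film material.
#'
#' @param res A [resonator()].
#' @param film A [layer()].
#' @param bulk A [bulk_medium()].
#' @param n Vector of odd overtone orders (>= 1).
#' @param reference `"bare"` returns shifts relative to the unloaded resonator;
#'   `"bulk"` subtracts the `d = 0` (bulk-only) prediction, matching adsorption
#'   experiments referenced to the pure-liquid baseline.
#' @return Complex vector `df + i dGamma` in Hz (total shift, not divided by
#'   `n`), one element per overtone.
#' @examples
#' soft <- power_law_material("compliance", 0.29e-6, 1.68e-6, -1.61, -0.91)
#' water <- bulk_medium("newtonian", rho = 1000, eta = 1e-3)
#' predict_film(resonator(), layer(soft, 9.8e-9), water, n = c(3, 5, 7))
#' @export
predict_film <- function(res, film, bulk, n, reference = c("bare", "bulk")) {
  stopifnot(inherits(res, "resonator"), inherits(film, "qcm_layer"),
            inherits(bulk, "bulk_medium"))
  predict_multilayer(res, list(film), bulk, n, reference = reference)
}

#' Exact complex frequency shift of a layer stack
#'
#' Recursive acoustic-impedance transfer through an ordered stack of planar
#' layers (first element adjacent to the resonator surface) terminated by the
#' ambient half-space. For a single layer this is identical to
#' [predict_film()]; for an empty stack it returns the bulk-only load (the
#' Kanazawa-Gordon value for a Newtonian liquid).
#'
#' @param res A [resonator()].
#' @param layers List of [layer()] objects, ordered from the resonator surface
#'   outward.
#' @param bulk A [bulk_medium()].
#' @inheritParams predict_film
#' @return Complex vector `df + i dGamma` in Hz per overtone.
#' @export
predict_multilayer <- function(res, layers, bulk, n, reference = c("bare", "bulk")) {
  stopifnot(inherits(res, "resonator"), is.list(layers),
            inherits(bulk, "bulk_medium"),
            is.numeric(n), all(n >= 1), all(n %% 2 == 1))
  reference <- match.arg(reference)
  if (length(layers) == 0L && bulk$kind == "vacuum" && reference == "bare")
    return(complex(length(n)))
  shift <- vapply(n, function(nn) {
    omega <- 2 * pi * nn * res$f0
    Z <- bulk_impedance(bulk, omega)
    for (ly in rev(layers)) {
      st <- evaluate_material(ly$material, nn * res$f0)
      Z <- transfer_layer(Z, st, ly$d, omega, ly$material$rho)
    }
    small_load(res, Z)
  }, complex(1))
  if (reference == "bulk") {
    base <- vapply(n, function(nn) {
      small_load(res, bulk_impedance(bulk, 2 * pi * nn * res$f0))
    }, complex(1))
    shift <- shift - base
  }
  shift
}

#' Kanazawa-Gordon shift of a bare resonator in a Newtonian liquid
#'
#' Equal to [predict_film()] with zero film thickness: `df < 0`, `dGamma > 0`,
#' `dGamma = -df` exactly, and `df/n` scales as `n^(-1/2)`.
#'
#' @param res A [resonator()].
#' @param bulk A Newtonian [bulk_medium()] (a vacuum returns 0).
#' @param n Vector of odd overtone orders.
#' @return Complex vector `df + i dGamma` in Hz per overtone.
#' @export
kanazawa <- function(res, bulk, n) {
  stopifnot(inherits(res, "resonator"), inherits(bulk, "bulk_medium"),
            is.numeric(n), all(n >= 1), all(n %% 2 == 1))
  if (bulk$kind == "vacuum") return(complex(length(n)))
  if (bulk$kind != "newtonian") stop("kanazawa() requires a Newtonian bulk")
  vapply(n, function(nn) {
    small_load(res, bulk_impedance(bulk, 2 * pi * nn * res$f0))
  }, complex(1))
}

#' Third-order thin-film approximation in air
#'
#' Taylor expansion of the film-in-air load to third order in thickness.
#' Variant `"eq5"` is the plain expansion
#' `(df + i dGamma)/n = -(mf/mq) f0 [1 + (n pi)^2/3 (J Zq^2/rho_f) (mf/mq)^2]`
#' with `J = J' - i J''` evaluated at `n * f0`; variant `"eq6"` subtracts an
#' additional 1 from the compliance bracket (a small correction beyond the
#' small-load approximation) and is the default used by the air recipe. The
#' deviation of `"eq5"` from the exact model is fourth order in `d/lambda`.
#'
#' @param res A [resonator()].
#' @param film A [layer()].
#' @param n Vector of odd overtone orders.
#' @param variant `"eq6"` (default) or `"eq5"`.
#' @return Complex vector `df + i dGamma` in Hz (total shift) per overtone.
#' @export
taylor_air <- function(res, film, n, variant = c("eq6", "eq5")) {
  stopifnot(inherits(res, "resonator"), inherits(film, "qcm_layer"),
            is.numeric(n), all(n >= 1), all(n %% 2 == 1))
  variant <- match.arg(variant)
  mat <- film$material
  mr <- film$m_f / res$mq
  extra <- if (variant == "eq6") -1 else 0
  vapply(n, function(nn) {
    J <- material_compliance(mat, nn * res$f0)
    bracket <- 1 + (nn * pi)^2 / 3 *
      (complex(real = J[1], imaginary = -J[2]) * res$Zq^2 / mat$rho + extra) * mr^2
    -nn * mr * res$f0 * bracket
  }, complex(1))
}

# native power-law evaluation -> compliance pair c(J', J'') at frequency f
material_compliance <- function(material, f) {
  if (material$rigid) return(c(0, 0))
  st <- evaluate_material(material, f)
  pair_from_complex_modulus(st$G, "compliance")
}

#' First-order thin-film approximation in a liquid
#'
#' Taylor expansion of the exact model to first order in thickness with a
#' nonzero bulk impedance, referenced to the bulk-loaded baseline:
#' `(df + i dGamma)/n = -(2 f0^2/Zq) rho_f d [1 - i omega eta_bulk
#'  (rho_bulk/rho_f) J]` with `J = J' - i J''` at `n * f0`. Setting
#' `equal_density = TRUE` replaces the density ratio by 1. The rigid film
#' (`J = 0`) reproduces the Sauerbrey value; a soft film lowers `-df/n` below
#' it (the missing-mass effect). The deviation from the exact model is second
#' order in thickness.
#'
#' @param res A [resonator()].
#' @param film A [layer()].
#' @param bulk A Newtonian [bulk_medium()].
#' @param n Vector of odd overtone orders.
#' @param equal_density Assume `rho_f = rho_bulk` in the viscoelastic
#'   correction (the common simplification); default keeps the exact ratio.
#' @return Complex vector `df + i dGamma` in Hz (total shift) per overtone,
#'   referenced to the bulk-loaded baseline.
#' @export
taylor_liquid <- function(res, film, bulk, n, equal_density = FALSE) {
  stopifnot(inherits(res, "resonator"), inherits(film, "qcm_layer"),
            inherits(bulk, "bulk_medium"),
            is.numeric(n), all(n >= 1), all(n %% 2 == 1))
  if (bulk$kind != "newtonian") stop("taylor_liquid() requires a Newtonian bulk")
  mat <- film$material
  kappa <- if (equal_density) 1 else bulk$rho / mat$rho
  vapply(n, function(nn) {
    omega <- 2 * pi * nn * res$f0
    J <- material_compliance(mat, nn * res$f0)
    bracket <- 1 - 1i * omega * bulk$eta * kappa *
      complex(real = J[1], imaginary = -J[2])
    -nn * (2 * res$f0^2 / res$Zq) * film$m_f * bracket
  }, complex(1))
}
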