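# Graphical recipes: closed-form extraction of {m_f, J', J'', beta', beta''}
# from offsets, slopes and curvatures of overtone plots.
#
# Both recipes share one structure. The generating approximation puts the
# frequency channel in the form
#     y(x) = c0 + c_lin * x + s * W * x^q ,   x = n^2 (air) or n (liquid),
# where the power-law term carries the compliance dispersion. The observables
# are the OLS quadratic coefficients (a0, a1, a2) in x ("a line, possibly with
# a slight curvature"). Because 1 and x lie in the quadratic basis, the
# noiseless coefficients are exactly
#     a0 = c0 + s W g0(q),  a1 = c_lin + s W g1(q),  a2 = s W g2(q),
# with g(q) the OLS projection of x^q onto {1, x, x^2} over the design points.
# Solving the one-dimensional root problem in q therefore inverts the recipe
# exactly on data generated by its own approximation (the round-trip is an
# identity), while the quadratic coefficients and their standard errors remain
# the recipe's diagnostics.

# OLS projection of x^q onto {1, x, x^2}; returns c(g0, g1, g2)
power_projection <- function(x, q) {
  X <- cbind(1, x, x^2)
  as.numeric(solve(crossprod(X), crossprod(X, x^q)))
}

# Solve a2/a1-type consistency for the power-law exponent q.
# gfun(q) must be monotone-ish with a sign change in the bracket.
solve_power_exponent <- function(gfun, side, q_min = -0.45, q_max = 2.45,
                                 eps = 0.02) {
  bracket <- if (side > 0) c(1 + eps, q_max) else c(q_min, 1 - eps)
  g_lo <- tryCatch(gfun(bracket[1]), error = function(e) NA_real_)
  g_hi <- tryCatch(gfun(bracket[2]), error = function(e) NA_real_)
  if (!is.finite(g_lo) || !is.finite(g_hi) || g_lo * g_hi > 0) return(NA_real_)
  stats::uniroot(gfun, bracket, tol = 1e-14)$root
}

# OLS quadratic with standard errors.  If sigma (per-point, known) is given,
# the coefficient covariance uses it; otherwise the residual variance is used
# (flagged upstream).  Returns coef, covariance, fitted.
quad_ols <- function(x, y, sigma = NULL) {
  k <- if (length(x) >= 3) 2L else 1L
  X <- cbind(1, x, if (k == 2L) x^2)
  XtXi <- solve(crossprod(X))
  coef <- as.numeric(XtXi %*% crossprod(X, y))
  fitted <- as.numeric(X %*% coef)
  if (!is.null(sigma)) {
    H <- XtXi %*% t(X)
    cov <- H %*% diag(sigma^2, nrow = length(x)) %*% t(H)
  } else {
    dof <- length(x) - ncol(X)
    s2 <- if (dof > 0) sum((y - fitted)^2) / dof else NA_real_
    cov <- XtXi * s2
  }
  if (k == 1L) {  # pad the curvature slot
    coef <- c(coef, 0)
    cov <- rbind(cbind(cov, 0), 0)
    cov[3, 3] <- NA_real_
  }
  list(coef = coef, cov = cov, fitted = fitted)
}

# Analytic standard error of the power-law exponent recovered from the OLS
# curvature: the curvature coefficient is a2 = s * W * g2(q), so
# se(q) = se(a2) / (W * |dg2/dq|), evaluated at the estimate.
exponent_se <- function(x, q, W, se_a2, dq_scale = 1) {
  if (!is.finite(W) || W == 0 || !is.finite(se_a2)) return(NA_real_)
  h <- 1e-4
  g2p <- (power_projection(x, q + h)[3] - power_projection(x, q - h)[3]) / (2 * h)
  if (g2p == 0) return(NA_real_)
  dq_scale * se_a2 / abs(W * g2p)
}

# central-difference jacobian of f: R^m -> R^k
num_jacobian <- function(f, x, rel = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel * max(abs(x[j]), 1e-12)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# weighted log-log line fit of z > 0 against n; returns slope/intercept + SEs
loglog_fit <- function(n, z, sigma = NULL) {
  ok <- is.finite(z) & z > 0
  if (sum(ok) < 2) return(NULL)
  lx <- log(n[ok]); ly <- log(z[ok])
  sl <- if (!is.null(sigma)) sigma[ok] / z[ok] else NULL
  fit <- quad_ols_line(lx, ly, sl)
  fit$n_used <- sum(ok)
  fit
}

quad_ols_line <- function(x, y, sigma = NULL) {
  X <- cbind(1, x)
  XtXi <- solve(crossprod(X))
  coef <- as.numeric(XtXi %*% crossprod(X, y))
  if (!is.null(sigma)) {
    H <- XtXi %*% t(X)
    cov <- H %*% diag(sigma^2, nrow = length(x)) %*% t(H)
  } else {
    dof <- length(x) - 2L
    s2 <- if (dof > 0) sum((y - X %*% coef)^2) / dof else NA_real_
    cov <- XtXi * s2
  }
  list(intercept = coef[1], slope = coef[2],
       se_intercept = sqrt(abs(cov[1, 1])), se_slope = sqrt(abs(cov[2, 2])))
}

new_recipe_estimate <- function(method, m_f, rho_f, J1, J2, beta1, beta2,
                                f_cen, diagnostics, validity) {
  structure(list(method = method, m_f = m_f, d_f = m_f / rho_f, rho_f = rho_f,
                 J1 = J1, J2 = J2, beta1 = beta1, beta2 = beta2,
                 f_cen = f_cen, diagnostics = diagnostics, validity = validity),
            class = "recipe_estimate")
}

#' @export
print.recipe_estimate <- function(x, ...) {
  cat(sprintf("<recipe_estimate> (%s recipe; approximate -- accurate values come from fit_viscoelastic)\n",
              x$method))
  se <- x$diagnostics$se
  fmt <- function(v, s, scl = 1, unit = "") {
    if (is.na(v)) return("NA")
    sprintf("%.4g%s%s", v * scl, unit,
            if (!is.null(s) && is.finite(s)) sprintf(" (se %.2g)", s * scl) else "")
  }
  cat("  m_f  =", fmt(x$m_f, se[["m_f"]], 1e6, " mg/m^2"),
      sprintf(" -> d_f = %.4g nm (rho_f = %g kg/m^3)\n", x$d_f * 1e9, x$rho_f))
  cat("  J'   =", fmt(x$J1, se[["J1"]], 1e6, " 1/MPa"),
      " beta' =", fmt(x$beta1, se[["beta1"]]), "\n")
  cat("  J''  =", fmt(x$J2, se[["J2"]], 1e6, " 1/MPa"),
      " beta'' =", fmt(x$beta2, se[["beta2"]]), "\n")
  flags <- x$validity[vapply(x$validity, isTRUE, logical(1))]
  if (length(flags)) cat("  flags:", paste(names(flags), collapse = ", "), "\n")
  invisible(x)
}

#' Thin-film-in-air recipe
#'
#' Extracts the full parameter set `{m_f (d_f), J', beta', J'', beta''}` from
#' overtone data of a film in air or vacuum, following the graphical rules:
#' the intercept of `df/n` versus `n^2` gives the areal mass
#' (`m_f = -df_intercept/(n f0) * mq`), the slope gives the elastic compliance
#' `J'`, and the (usually poorly determined) curvature gives the exponent
#' `beta'`. The viscous compliance `J''` and its exponent `beta''` come from
#' the bandwidth channel, whose generating form is
#' `dGamma/n = (pi^2/3) (mf/mq)^2 (J''(n f0) Zq^2/rho_f) * n^2 * (mf/mq) f0`
#' (equivalently the acoustic ratio of Eq-8 type, reported in diagnostics).
#' Point estimates invert the generating approximation exactly, so the
#' noiseless round trip through [taylor_air()] is an identity; standard errors
#' come from the OLS quadratic observables.
#'
#' @param shifts An [overtone_shifts()] object (vacuum/air ambient, reference
#'   `"bare"`). The fundamental (n = 1) is dropped unless
#'   `include_fundamental = TRUE`.
#' @param res A [resonator()].
#' @param rho_f Film density in kg m^-3 (default 1000).
#' @param f_cen Reference frequency for the power laws (Hz).
#' @param variant Which thin-film approximation generated the data: `"eq6"`
#'   (default, with the additional -1 term) or `"eq5"`.
#' @param include_fundamental Keep n = 1 if present (default drops it).
#' @return A `recipe_estimate`.
#' @export
estimate_film_in_air <- function(shifts, res, rho_f = 1000, f_cen = 30e6,
                                 variant = c("eq6", "eq5"),
                                 include_fundamental = FALSE) {
  stopifnot(inherits(shifts, "overtone_shifts"), inherits(res, "resonator"))
  variant <- match.arg(variant)
  keep <- if (include_fundamental) rep(TRUE, length(shifts$n)) else shifts$n > 1
  n <- shifts$n[keep]
  y <- shifts$df_over_n[keep]
  z <- shifts$dG_over_n[keep]
  sf <- shifts$sigma_f[keep]
  sG <- shifts$sigma_G[keep]
  if (length(n) < 2) stop("at least 2 overtones required")
  if (all(y >= 0)) stop("non-negative df/n on all overtones: no film detected")
  validity <- list(curvature_unidentifiable = length(n) < 3,
                   sigma_estimated = is.null(sf))

  u <- n^2
  quad <- quad_ols(u, y, sf)
  a <- quad$coef
  extra <- if (variant == "eq6") -1 else 0

  # invert (a0, a1, a2) -> (m_f, J1, beta1); exact on noiseless recipe data
  invert <- function(a) {
    a0 <- a[1]; a1 <- a[2]; a2 <- a[3]
    cterm <- function(A) if (variant == "eq6") pi^2 * A^3 / (3 * res$f0^2) else 0
    q <- NA_real_
    if (length(n) >= 3 && abs(a2) > 1e-13 * max(abs(a1), abs(a0) / max(u))) {
      gfun <- function(q) {
        g <- power_projection(u, q)
        A <- -a0 + a2 * g[1] / g[3]
        cterm(A) - a1 + a2 * g[2] / g[3]
      }
      # sign of the curvature selects the side of q = 1 (term is -P u^q, P > 0)
      q <- solve_power_exponent(gfun, side = -sign(a2))
    }
    if (is.na(q)) {  # degrade: no usable curvature, beta1 = 0
      A <- -a0
      P <- cterm(A) - a1
      q <- 1
    } else {
      g <- power_projection(u, q)
      P <- -a2 / g[3]
      A <- -a0 + a2 * g[1] / g[3]
    }
    C <- pi^2 * A^3 / (3 * res$f0^2)
    beta1 <- 2 * (q - 1)
    J1 <- (P / C) * (rho_f / res$Zq^2) * (f_cen / res$f0)^beta1
    c(m_f = A * res$mq / res$f0, J1 = J1, beta1 = beta1)
  }
  est <- invert(a)
  if (is.na(est["beta1"]) || abs(est["beta1"]) < 1e-12)
    validity$curvature_unidentifiable <- validity$curvature_unidentifiable ||
      length(n) < 3

  # delta-method standard errors through the full inversion
  se <- c(m_f = NA_real_, J1 = NA_real_, beta1 = NA_real_)
  if (all(is.finite(quad$cov))) {
    J <- tryCatch(num_jacobian(invert, a), error = function(e) NULL)
    if (!is.null(J) && all(is.finite(J)))
      se <- sqrt(pmax(0, diag(J %*% quad$cov %*% t(J))))
    names(se) <- c("m_f", "J1", "beta1")
  }

  # bandwidth channel: dGamma/n = C (Zq^2/rho_f) J''(n f0) n^2  (power law in n)
  A <- est[["m_f"]] * res$f0 / res$mq
  C <- pi^2 * A^3 / (3 * res$f0^2)

  # analytic exponent error from the curvature observable (beta1 = 2(q - 1));
  # the often-large value here is the recipe's honest uncertainty on beta'
  P_hat <- C * est[["J1"]] * res$Zq^2 / rho_f * (res$f0 / f_cen)^est[["beta1"]]
  se["beta1"] <- exponent_se(u, 1 + est[["beta1"]] / 2, P_hat,
                             sqrt(abs(quad$cov[3, 3])), dq_scale = 2)
  ll <- loglog_fit(n, z, sG)
  if (!is.null(ll)) {
    beta2 <- ll$slope - 2
    J2 <- exp(ll$intercept) * rho_f / (C * res$Zq^2 * (res$f0 / f_cen)^beta2)
    se_beta2 <- ll$se_slope
    se_J2 <- J2 * sqrt(ll$se_intercept^2 + (log(res$f0 / f_cen) * ll$se_slope)^2)
  } else {
    beta2 <- NA_real_
    J2 <- max(0, mean(z) * rho_f / (C * res$Zq^2 * mean(n)^2))
    se_beta2 <- NA_real_; se_J2 <- NA_real_
    validity$bandwidth_nonpositive <- TRUE
  }

  acoustic8 <- z / (-y)  # Eq-8-type acoustic ratio, scales as m_f^2
  diagnostics <- list(
    quad = list(coef = a, se = sqrt(abs(diag(quad$cov))), abscissa = "n^2"),
    loglog_bandwidth = ll,
    acoustic_ratio = stats::setNames(acoustic8, paste0("n", n)),
    se = c(se, J2 = se_J2, beta2 = se_beta2),
    variant = variant)
  new_recipe_estimate("film-in-air", est[["m_f"]], rho_f,
                      est[["J1"]], J2, est[["beta1"]], beta2,
                      f_cen, diagnostics, validity)
}

#' Stiff-film-in-liquid recipe
#'
#' For a thin film in a Newtonian liquid that is much stiffer than the liquid
#' (`J''_f << J''_bulk`, equivalently `eta'_f >> eta_bulk`), the first-order
#' expansion gives
#' `df/n = -(2 f0^2/Zq) m_f [1 - omega eta_bulk (rho_b/rho_f) J''(n f0)]` and
#' `dGamma/n = (2 f0^2/Zq) m_f omega eta_bulk (rho_b/rho_f) J'(n f0)`.
#' The intercept of `df/n` versus `n` gives the thickness, the slope the
#' viscous compliance `J''`, the curvature its exponent `beta''`; the elastic
#' compliance `J'` and `beta'` come from the bandwidth channel (the acoustic
#' ratio `omega eta_bulk J'` of Eq-12 type, thickness-independent, is reported
#' per overtone in diagnostics). Point estimates invert the generating
#' approximation exactly; the stiffness assumption is checked and flagged, not
#' enforced.
#'
#' @param shifts An [overtone_shifts()] with reference `"bulk"`.
#' @param res A [resonator()].
#' @param bulk A Newtonian [bulk_medium()].
#' @inheritParams estimate_film_in_air
#' @return A `recipe_estimate`.
#' @export
estimate_stiff_film_in_liquid <- function(shifts, res, bulk, rho_f = 1000,
                                          f_cen = 30e6,
                                          include_fundamental = FALSE) {
  stopifnot(inherits(shifts, "overtone_shifts"), inherits(res, "resonator"),
            inherits(bulk, "bulk_medium"))
  if (bulk$kind != "newtonian") stop("recipe requires a Newtonian bulk")
  if (shifts$reference != "bulk")
    warning("stiff-film recipe expects shifts referenced to the bulk baseline")
  keep <- if (include_fundamental) rep(TRUE, length(shifts$n)) else shifts$n > 1
  n <- shifts$n[keep]
  y <- shifts$df_over_n[keep]
  z <- shifts$dG_over_n[keep]
  sf <- shifts$sigma_f[keep]
  sG <- shifts$sigma_G[keep]
  if (length(n) < 2) stop("at least 2 overtones required")
  if (all(y >= 0)) stop("non-negative df/n on all overtones: no film detected")
  validity <- list(curvature_unidentifiable = length(n) < 3,
                   sigma_estimated = is.null(sf))
  kappa <- bulk$rho / rho_f

  quad <- quad_ols(n, y, sf)
  a <- quad$coef

  # y = -B + Q n^q with B = (2 f0^2/Zq) m_f, q = 1 + beta'' (term +Q n^q, Q > 0)
  invert <- function(a) {
    a0 <- a[1]; a1 <- a[2]; a2 <- a[3]
    q <- NA_real_
    if (length(n) >= 3 && abs(a2) > 1e-13 * max(abs(a1), abs(a0) / max(n))) {
      gfun <- function(q) {
        g <- power_projection(n, q)
        a1 - a2 * g[2] / g[3]
      }
      q <- solve_power_exponent(gfun, side = sign(a2))
    }
    if (is.na(q)) {
      q <- 1
      Q <- a1
      B <- -a0
    } else {
      g <- power_projection(n, q)
      Q <- a2 / g[3]
      B <- -a0 + Q * g[1]
    }
    beta2 <- q - 1
    m_f <- B * res$Zq / (2 * res$f0^2)
    J2 <- Q / (B * 2 * pi * res$f0 * bulk$eta * kappa) * (f_cen / res$f0)^beta2
    c(m_f = m_f, J2 = J2, beta2 = beta2)
  }
  est <- invert(a)

  se <- c(m_f = NA_real_, J2 = NA_real_, beta2 = NA_real_)
  if (all(is.finite(quad$cov))) {
    J <- tryCatch(num_jacobian(invert, a), error = function(e) NULL)
    if (!is.null(J) && all(is.finite(J)))
      se <- sqrt(pmax(0, diag(J %*% quad$cov %*% t(J))))
    names(se) <- c("m_f", "J2", "beta2")
  }

  # bandwidth channel: dGamma/n = B 2 pi f0 eta kappa J'(n f0) n^(1+beta')
  B <- est[["m_f"]] * 2 * res$f0^2 / res$Zq
  Q_hat <- B * 2 * pi * res$f0 * bulk$eta * kappa * est[["J2"]] *
    (res$f0 / f_cen)^est[["beta2"]]
  se["beta2"] <- exponent_se(n, 1 + est[["beta2"]], Q_hat,
                             sqrt(abs(quad$cov[3, 3])))
  ll <- loglog_fit(n, z, sG)
  if (!is.null(ll)) {
    beta1 <- ll$slope - 1
    J1 <- exp(ll$intercept) /
      (B * 2 * pi * res$f0 * bulk$eta * kappa * (res$f0 / f_cen)^beta1)
    se_beta1 <- ll$se_slope
    se_J1 <- J1 * sqrt(ll$se_intercept^2 + (log(res$f0 / f_cen) * ll$se_slope)^2)
  } else {
    beta1 <- NA_real_; J1 <- 0
    se_beta1 <- NA_real_; se_J1 <- NA_real_
    validity$bandwidth_nonpositive <- TRUE
  }

  # Eq-12-type per-overtone J' (thickness-independent acoustic ratio)
  ratio <- z / (-y)
  J1_eq12 <- ratio / (2 * pi * n * res$f0 * bulk$eta)
  # stiffness check from the recipe's own estimate: J''_f vs J''_bulk at f_cen
  J2_bulk_cen <- 1 / (2 * pi * f_cen * bulk$eta)
  validity$stiffness_violated <-
    is.finite(est[["J2"]]) && est[["J2"]] / J2_bulk_cen > 0.1

  diagnostics <- list(
    quad = list(coef = a, se = sqrt(abs(diag(quad$cov))), abscissa = "n"),
    loglog_bandwidth = ll,
    acoustic_ratio = stats::setNames(ratio, paste0("n", n)),
    J1_eq12 = stats::setNames(J1_eq12, paste0("n", n)),
    se = c(se, J1 = se_J1, beta1 = se_beta1))
  new_recipe_estimate("stiff-film-in-liquid", est[["m_f"]], rho_f,
                      J1, est[["J2"]], beta1, est[["beta2"]],
                      f_cen, diagnostics, validity)
}

#' Check the stiff-film assumption
#'
#' The stiff-film recipe requires `J''_f << J''_bulk`, equivalently
#' `eta'_f >> eta_bulk`. Returns both ratios and a boolean verdict at a
#' configurable threshold (default: valid when `J''_f/J''_bulk < 1/threshold`).
#'
#' @param material The film [power_law_material()].
#' @param bulk A Newtonian [bulk_medium()].
#' @param f Frequency in Hz at which to evaluate the check.
#' @param threshold Separation factor (default 10).
#' @return A list with `ratio_J` (= J''_f/J''_bulk), `ratio_eta`
#'   (= eta'_f/eta_bulk) and `valid`.
#' @export
validate_stiffness <- function(material, bulk, f, threshold = 10) {
  stopifnot(inherits(material, "power_law_material"),
            inherits(bulk, "bulk_medium"), bulk$kind == "newtonian",
            is.numeric(f), f > 0, threshold > 0)
  omega <- 2 * pi * f
  J2_bulk <- 1 / (omega * bulk$eta)
  if (material$rigid)
    return(list(ratio_J = 0, ratio_eta = Inf, valid = TRUE))
  st <- evaluate_material(material, f)
  J <- pair_from_complex_modulus(st$G, "compliance")
  eta1_f <- Im(st$G) / omega    # eta' = G''/omega
  list(ratio_J = J[2] / J2_bulk,
       ratio_eta = eta1_f / bulk$eta,
       valid = J[2] / J2_bulk <= 1 / threshold)
}

#' Thin-film acoustic ratio from compliances
#'
#' Closed form for a thin film in a Newtonian liquid:
#' `dGamma/(-df) = omega eta_bulk J' / (1 - omega eta_bulk J'')`
#' (with an optional density ratio `kappa = rho_bulk/rho_f` multiplying
#' `eta_bulk`). With `approx = "stiff"` the denominator is replaced by 1,
#' valid when `J''_f << J''_bulk`; the ratio is then independent of film
#' thickness.
#'
#' @param J1,J2 Elastic and viscous compliance of the film (Pa^-1) at the
#'   frequency of interest.
#' @param eta_bulk Bulk viscosity (Pa s).
#' @param omega Angular frequency (rad s^-1).
#' @param kappa Density ratio `rho_bulk/rho_f` (default 1).
#' @param approx `"full"` or `"stiff"`.
#' @return The dimensionless acoustic ratio.
#' @export
acoustic_ratio_compliance <- function(J1, J2, eta_bulk, omega, kappa = 1,
                                      approx = c("full", "stiff")) {
  approx <- match.arg(approx)
  num <- omega * eta_bulk * kappa * J1
  if (approx == "stiff") num else num / (1 - omega * eta_bulk * kappa * J2)
}

#' Thin-film acoustic ratio from viscosity magnitude and loss tangent
#'
#' The same closed form as [acoustic_ratio_compliance()], rewritten by exact
#' algebraic substitution in terms of the film's viscosity magnitude
#' `|eta_f|` and loss tangent `t = tan delta = eta'/eta''`:
#' `dGamma/(-df) = (r / sqrt(1 + t^2)) / (1 - r t / sqrt(1 + t^2))` with
#' `r = eta_bulk/|eta_f|`. In the nearly Newtonian limit (`t -> infinity`)
#' this tends to `(1/t) / (|eta_f|/eta_bulk - 1)` for `|eta_f| > eta_bulk`,
#' and to `2 t` at exactly `|eta_f| = eta_bulk` (where the frequency shift is
#' second order in the inverse loss tangent).
#'
#' @param eta_abs Film viscosity magnitude `|eta_f|` (Pa s).
#' @param tan_delta Film loss tangent (dimensionless, > 0).
#' @param eta_bulk Bulk viscosity (Pa s).
#' @param kappa Density ratio `rho_bulk/rho_f` (default 1).
#' @return The dimensionless acoustic ratio.
#' @export
acoustic_ratio_loss <- function(eta_abs, tan_delta, eta_bulk, kappa = 1) {
  stopifnot(eta_abs > 0, tan_delta > 0)
  r <- kappa * eta_bulk / eta_abs
  s <- sqrt(1 + tan_delta^2)
  (r / s) / (1 - r * tan_delta / s)
}

#' Viscosity-increment (double-layer) interpretation
#'
#' For a thin near-surface layer that is almost a Newtonian liquid
#' (`eta_f = eta_bulk + delta_eta`, `|delta_eta| << eta_bulk`), the shifts
#' referenced to the bulk baseline reduce to
#' `(df + i dGamma)/n = -(2 f0^2/Zq) rho d [delta_eta / eta_bulk]`.
#' Only the products `d * delta_eta'` (from `df/n`) and `d * delta_eta''`
#' (from `dGamma/n`) are observable: a statement on layer thickness cannot be
#' made from a single shift set. Sauerbrey-type behavior
#' (`-df >> dGamma`, `df/n` constant in n) occurs when `delta_eta` is mostly
#' real.
#'
#' The layer's inverse loss tangent `eta''_f/eta'_f` is recovered as
#' `delta_eta''/(eta_bulk + delta_eta')` when a thickness is supplied. Without
#' a thickness, an estimate is reported under the additional assumption
#' `|eta_f| ~ eta_bulk`, where the thin-film limit gives acoustic ratio
#' `= 2 tan delta`, i.e. inverse loss tangent `= 2/ratio`.
#'
#' @param shifts An [overtone_shifts()] referenced to the bulk baseline.
#' @param res A [resonator()].
#' @param bulk A Newtonian [bulk_medium()].
#' @param d_f Optional layer thickness in m; unlocks the complex viscosity
#'   increment itself.
#' @param ratio_bound Flag the result when `|acoustic ratio|` exceeds this
#'   bound on some overtone and no thickness is supplied (the layer is then
#'   not in the near-Newtonian-increment regime for the no-thickness
#'   estimator); default 0.2 on `1/ratio` scale, see Details.
#' @return An object of class `double_layer_result` with per-overtone
#'   `visc_mass` (`d * delta_eta'`, Pa s m), `diss_mass` (`d * delta_eta''`),
#'   `acoustic_ratio`, `tan_delta_inv`, and (given `d_f`) `delta_eta`
#'   (complex, Pa s).
#' @export
double_layer_analysis <- function(shifts, res, bulk, d_f = NULL,
                                  ratio_bound = 0.2) {
  stopifnot(inherits(shifts, "overtone_shifts"), inherits(res, "resonator"),
            inherits(bulk, "bulk_medium"), bulk$kind == "newtonian")
  n <- shifts$n
  fac <- res$Zq * bulk$eta / (2 * res$f0^2 * bulk$rho)
  visc_mass <- -shifts$df_over_n * fac     # d * delta_eta'
  diss_mass <- shifts$dG_over_n * fac      # d * delta_eta''
  ratio <- acoustic_ratio(shifts)

  flagged <- FALSE
  if (!is.null(d_f)) {
    stopifnot(is.numeric(d_f), d_f > 0)
    d_eta1 <- visc_mass / d_f
    d_eta2 <- diss_mass / d_f
    delta_eta <- complex(real = d_eta1, imaginary = -d_eta2)
    tdi <- d_eta2 / (bulk$eta + d_eta1)
    flagged <- any(Mod(delta_eta) > 0.5 * bulk$eta)  # increment not small
  } else {
    delta_eta <- NULL
    # assumes |eta_f| ~ eta_bulk: ratio = 2 tan delta  =>  inv loss tan = 2/ratio
    tdi <- 2 / ratio
    flagged <- any(is.finite(tdi) & abs(tdi) > ratio_bound)
  }
  structure(list(n = n, visc_mass = visc_mass, diss_mass = diss_mass,
                 acoustic_ratio = ratio, tan_delta_inv = tdi,
                 delta_eta = delta_eta, d_f = d_f,
                 regime_flagged = flagged),
            class = "double_layer_result")
}

#' @export
print.double_layer_result <- function(x, ...) {
  cat("<double_layer_result> (near-Newtonian layer interpretation)\n")
  df <- data.frame(n = x$n, visc_mass = x$visc_mass, diss_mass = x$diss_mass,
                   acoustic_ratio = x$acoustic_ratio,
                   tan_delta_inv = x$tan_delta_inv)
  print(df, row.names = FALSE)
  if (x$regime_flagged)
    cat("  flag: layer outside the small-increment / near-Newtonian regime\n")
  invisible(x)
}
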