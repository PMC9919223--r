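# Five-parameter chi-square fitting of the exact acoustic-load model and
# profile-likelihood (chi-square landscape) identifiability analysis.

PARAM_NAMES <- c("d_f", "value1", "value2", "beta1", "beta2")

default_bounds <- function(representation) {
  vb <- switch(representation,
    compliance = c(1e-10, 1e-3),
    modulus = c(1e2, 1e10),
    viscosity = c(1e-7, 1e2),
    magnitude_loss = NULL)
  b <- list(d_f = c(1e-11, 1e-6),
            value1 = if (is.null(vb)) c(1e2, 1e10) else vb,
            value2 = if (representation == "magnitude_loss") c(1e-3, 1e3) else vb,
            beta1 = c(-3, 3), beta2 = c(-3, 3))
  b
}

#' Define a viscoelastic fitting problem
#'
#' Bundles the data, the instrument, the ambient, the viscoelastic
#' representation and the parameter treatment for [fit_viscoelastic()] and
#' [chi2_landscape()]. The five model parameters are the film thickness `d_f`
#' and the material's `value1`, `value2` (the representation pair at `f_cen`)
#' and power-law exponents `beta1`, `beta2`.
#'
#' @param shifts An [overtone_shifts()] object. Its `reference` tag decides
#'   whether the model is referenced to the bare resonator or to the
#'   bulk-loaded baseline.
#' @param res A [resonator()].
#' @param bulk A [bulk_medium()].
#' @param representation Viscoelastic representation for the fit parameters
#'   (see [power_law_material()]); the chi-square minimum is invariant under
#'   this choice, the parameter coordinates are not.
#' @param free Character vector of free parameters (subset of
#'   `c("d_f", "value1", "value2", "beta1", "beta2")`).
#' @param fixed Named list of values for the non-free parameters (defaults:
#'   betas 0; values at the center of their bounds must be given explicitly if
#'   fixed).
#' @param bounds Named list of length-2 intervals overriding the defaults.
#' @param init Named numeric vector of starting values (defaults derived from
#'   the data: Sauerbrey thickness, mid-range stiffness, zero exponents).
#' @param sigma_f,sigma_G Per-overtone noise scales in Hz used as chi-square
#'   weights; default 0.1 Hz (the magnitude of per-crystal irregularities), or
#'   the scales stored in `shifts`.
#' @param rho_f Film density (kg m^-3).
#' @param f_cen Power-law reference frequency (Hz).
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(shifts, res, bulk,
                        representation = c("compliance", "modulus",
                                           "viscosity", "magnitude_loss"),
                        free = PARAM_NAMES, fixed = list(),
                        bounds = list(), init = NULL,
                        sigma_f = NULL, sigma_G = NULL,
                        rho_f = 1000, f_cen = 30e6) {
  stopifnot(inherits(shifts, "overtone_shifts"), inherits(res, "resonator"),
            inherits(bulk, "bulk_medium"))
  representation <- match.arg(representation)
  stopifnot(all(free %in% PARAM_NAMES), !anyDuplicated(free))
  fixed_names <- setdiff(PARAM_NAMES, free)
  for (nm in fixed_names) {
    if (is.null(fixed[[nm]])) {
      if (nm %in% c("beta1", "beta2")) fixed[[nm]] <- 0
      else stop("fixed value required for parameter ", nm)
    }
  }
  if (length(setdiff(names(fixed), fixed_names)))
    stop("fixed values given for free parameters: ",
         paste(intersect(names(fixed), free), collapse = ", "))
  b <- default_bounds(representation)
  for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]

  sf <- if (!is.null(sigma_f)) rep_len(sigma_f, length(shifts$n))
        else if (!is.null(shifts$sigma_f)) shifts$sigma_f
        else rep(0.1, length(shifts$n))
  sG <- if (!is.null(sigma_G)) rep_len(sigma_G, length(shifts$n))
        else if (!is.null(shifts$sigma_G)) shifts$sigma_G
        else rep(0.1, length(shifts$n))
  if (any(sf <= 0) || any(sG <= 0)) stop("noise scales must be positive")

  if (is.null(init)) init <- numeric(0)
  init <- as.list(init)
  if (is.null(init$d_f)) {
    d0 <- max(sauerbrey_mass(res, mean(shifts$df_over_n)), 1e-10) / rho_f
    init$d_f <- min(max(d0, b$d_f[1] * 2), b$d_f[2] / 2)
  }
  gm <- function(iv) sqrt(iv[1] * iv[2])
  if (is.null(init$value1))
    init$value1 <- if (representation == "compliance") 1e-6 else gm(b$value1)
  if (is.null(init$value2))
    init$value2 <- if (representation == "compliance") 1e-6
                   else if (representation == "magnitude_loss") 1 else gm(b$value2)
  if (is.null(init$beta1)) init$beta1 <- 0
  if (is.null(init$beta2)) init$beta2 <- 0
  for (nm in PARAM_NAMES) {
    if (nm %in% free && (init[[nm]] < b[[nm]][1] || init[[nm]] > b[[nm]][2]))
      stop("init for ", nm, " outside bounds")
  }
  structure(list(shifts = shifts, res = res, bulk = bulk,
                 representation = representation, free = free,
                 fixed = fixed, bounds = b, init = init,
                 sigma_f = sf, sigma_G = sG,
                 rho_f = rho_f, f_cen = f_cen),
            class = "fit_problem")
}

# ---- fast forward model ---------------------------------------------------

# Precompute per-overtone constants for repeated model evaluation.
model_context <- function(problem) {
  res <- problem$res; bulk <- problem$bulk
  n <- problem$shifts$n
  omega <- 2 * pi * n * res$f0
  Zb <- vapply(omega, function(om) bulk_impedance(bulk, om), complex(1))
  base <- if (problem$shifts$reference == "bulk")
    1i * res$f0 / (pi * res$Zq) * Zb else complex(length(n))
  list(n = n, omega = omega, Zb = Zb, base = base,
       fscale = n * res$f0 / problem$f_cen,
       f0 = res$f0, Zq = res$Zq, rho = problem$rho_f,
       rep = problem$representation)
}

# complex modulus at every overtone from the five parameters (vectorized)
modulus_vec <- function(ctx, v1c, v2c, b1, b2) {
  v1 <- v1c * ctx$fscale^b1
  v2 <- v2c * ctx$fscale^b2
  switch(ctx$rep,
    modulus = complex(real = v1, imaginary = v2),
    compliance = 1 / complex(real = v1, imaginary = -v2),
    viscosity = 1i * ctx$omega * complex(real = v1, imaginary = -v2),
    magnitude_loss = {
      G1 <- v1 / sqrt(1 + v2^2)
      complex(real = G1, imaginary = G1 * v2)
    })
}

# per-n-normalized complex shift df/n + i dGamma/n for the parameter set
model_shifts <- function(ctx, par) {
  G <- modulus_vec(ctx, par[["value1"]], par[["value2"]],
                   par[["beta1"]], par[["beta2"]])
  Z <- sqrt(ctx$rho * G)
  flip <- Re(Z) < 0
  Z[flip] <- -Z[flip]
  k <- ctx$omega * ctx$rho / Z
  tkd <- tan_stable(k * par[["d_f"]])
  Zload <- Z * (ctx$Zb + 1i * Z * tkd) / (Z + 1i * ctx$Zb * tkd)
  (1i * ctx$f0 / (pi * ctx$Zq) * Zload - ctx$base) / ctx$n
}

# ---- parameter transforms -------------------------------------------------

is_log_param <- function(nm) nm %in% c("d_f", "value1", "value2")

to_transformed <- function(x, nms) {
  L <- is_log_param(nms)
  x[L] <- log(x[L])
  x
}
from_transformed <- function(t, nms) {
  L <- is_log_param(nms)
  t[L] <- exp(t[L])
  t
}

full_par <- function(theta_nat, problem) {
  par <- unlist(problem$fixed[setdiff(PARAM_NAMES, problem$free)])
  par <- c(par, stats::setNames(theta_nat, problem$free))
  par[PARAM_NAMES]
}

residual_fun <- function(problem, ctx) {
  data_f <- problem$shifts$df_over_n
  data_G <- problem$shifts$dG_over_n
  sf <- problem$sigma_f; sG <- problem$sigma_G
  free <- problem$free
  function(theta) {
    par <- full_par(from_transformed(theta, free), problem)
    m <- model_shifts(ctx, par)
    c((Re(m) - data_f) / sf, (Im(m) - data_G) / sG)
  }
}

# deterministic Latin-hypercube start fractions (n_extra x k), plus user init
start_matrix <- function(problem, n_starts) {
  free <- problem$free
  k <- length(free)
  lo <- to_transformed(vapply(free, function(nm) problem$bounds[[nm]][1], 0), free)
  hi <- to_transformed(vapply(free, function(nm) problem$bounds[[nm]][2], 0), free)
  init <- to_transformed(unlist(problem$init[free]), free)
  m <- n_starts - 1L
  starts <- matrix(init, nrow = 1)
  if (m > 0) {
    primes <- c(1, 2, 3, 4, 5)[seq_len(k)]
    fr <- outer(seq_len(m), primes, function(i, p) (((i * p - 1) %% m) + 0.5) / m)
    starts <- rbind(starts, sweep(sweep(fr, 2, hi - lo, "*"), 2, lo, "+"))
  }
  colnames(starts) <- free
  list(starts = starts, lower = lo, upper = hi)
}

run_lm <- function(fn, theta0, lower, upper, maxiter = 200) {
  theta0 <- pmin(pmax(theta0, lower), upper)
  out <- tryCatch(
    minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(theta = out$par, deviance = out$deviance,
       converged = out$info %in% 1:3, info = out$info)
}

#' Fit the five-parameter viscoelastic model
#'
#' Minimizes the weighted chi-square
#' `sum_n [(df/n|model - df/n|data)^2/sigma_f^2 +
#' (dGamma/n|model - dGamma/n|data)^2/sigma_G^2]`
#' with the exact acoustic-load model as forward predictor, by bounded
#' Levenberg-Marquardt on transformed parameters (log for thickness and the
#' positive stiffness values, identity for the exponents). A deterministic
#' Latin-hypercube of starting points over the bounds, plus the user start, is
#' used because the chi-square landscape can have shallow valleys; the best
#' converged solution is returned.
#'
#' @param problem A [fit_problem()].
#' @param n_starts Number of starts (user init + deterministic lattice).
#' @return An object of class `qcm_fit`: fitted `params` (natural units),
#'   `chi2` (unnormalized), `chi2_reduced`, `stderr`, per-overtone
#'   `residuals` (Hz), `n_obs`, `converged`, `n_starts_used`.
#' @export
fit_viscoelastic <- function(problem, n_starts = 8) {
  stopifnot(inherits(problem, "fit_problem"))
  n_obs <- 2L * length(problem$shifts$n)
  if (n_obs < length(problem$free))
    stop("fewer observations than free parameters")
  if (all(problem$shifts$df_over_n == 0) && all(problem$shifts$dG_over_n == 0))
    stop("degenerate data: all shifts zero")
  ctx <- model_context(problem)
  fn <- residual_fun(problem, ctx)
  sm <- start_matrix(problem, n_starts)
  best <- NULL
  for (i in seq_len(nrow(sm$starts))) {
    out <- run_lm(fn, sm$starts[i, ], sm$lower, sm$upper)
    if (is.null(out)) next
    if (is.null(best) || (out$deviance < best$deviance - 1e-12 * best$deviance) ||
        (!best$converged && out$converged && out$deviance <= best$deviance))
      best <- out
  }
  if (is.null(best)) stop("all optimizer starts failed")
  finish_fit(problem, ctx, fn, best, n_starts)
}

finish_fit <- function(problem, ctx, fn, best, n_starts) {
  free <- problem$free
  theta <- best$theta
  par <- full_par(from_transformed(theta, free), problem)
  m <- model_shifts(ctx, par)
  resid <- cbind(df_over_n = problem$shifts$df_over_n - Re(m),
                 dG_over_n = problem$shifts$dG_over_n - Im(m))
  rownames(resid) <- paste0("n", problem$shifts$n)
  chi2 <- best$deviance
  n_obs <- 2L * length(problem$shifts$n)
  dof <- n_obs - length(free)

  # local standard errors from the weighted jacobian (svd pseudo-inverse so
  # degenerate directions show up as very large errors, not failures)
  J <- num_jacobian(fn, theta)
  sv <- svd(crossprod(J))
  pos <- sv$d > max(sv$d) * 1e-12
  cov_t <- sv$v[, pos, drop = FALSE] %*%
    diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  se_t <- sqrt(pmax(0, diag(cov_t)))
  nat <- from_transformed(theta, free)
  stderr <- ifelse(is_log_param(free), abs(nat) * se_t, se_t)
  names(stderr) <- free

  structure(list(params = par, free = free, stderr = stderr,
                 chi2 = chi2,
                 chi2_reduced = if (dof > 0) chi2 / dof else NA_real_,
                 residuals = resid, n_obs = n_obs,
                 converged = best$converged, n_starts_used = n_starts,
                 representation = problem$representation,
                 problem = problem),
            class = "qcm_fit")
}

#' @export
print.qcm_fit <- function(x, ...) {
  cat(sprintf("<qcm_fit> representation: %s, chi2 = %.6g (reduced %.4g), %s\n",
              x$representation, x$chi2, x$chi2_reduced,
              if (x$converged) "converged" else "NOT converged"))
  v <- x$params
  se <- stats::setNames(rep(NA_real_, length(v)), names(v))
  se[names(x$stderr)] <- x$stderr
  tab <- data.frame(value = v, stderr = se,
                    free = names(v) %in% x$free)
  print(tab)
  invisible(x)
}

#' Fitted material and layer from a fit result
#'
#' @param fit A `qcm_fit`.
#' @return A [layer()] carrying the fitted [power_law_material()].
#' @export
fitted_layer <- function(fit) {
  stopifnot(inherits(fit, "qcm_fit"))
  p <- fit$params
  mat <- power_law_material(fit$representation, p[["value1"]], p[["value2"]],
                            p[["beta1"]], p[["beta2"]],
                            f_cen = fit$problem$f_cen, rho = fit$problem$rho_f)
  layer(mat, p[["d_f"]])
}

#' Chi-square landscape (profile likelihood) over one parameter
#'
#' Prescribes values for one parameter over a grid, refits the remaining free
#' parameters at each grid point (warm-started from the neighboring solution,
#' sweeping outward from the free-fit optimum), and returns the chi-square
#' curve together with the co-fitted parameters. Because the profiled
#' parameter is no longer free, the curve lies at or above the free-fit
#' chi-square everywhere; a sharp, narrow valley means the parameter is well
#' determined by the data, a flat valley means it is not.
#'
#' @param problem A [fit_problem()]; the profiled parameter must be free in it.
#' @param param One of the five parameter names.
#' @param grid Numeric grid of prescribed values (within bounds).
#' @param n_starts Starts for the initial free fit.
#' @return An object of class `chi2_profile` with `grid`, `chi2`,
#'   `co_fitted` (matrix), `converged`, `chi2_min` (free fit), `argmin`,
#'   and the free `fit`.
#' @export
chi2_landscape <- function(problem, param, grid, n_starts = 8) {
  stopifnot(inherits(problem, "fit_problem"), param %in% problem$free,
            is.numeric(grid), length(grid) >= 2)
  b <- problem$bounds[[param]]
  if (any(grid < b[1] | grid > b[2])) stop("grid outside bounds for ", param)
  free_fit <- fit_viscoelastic(problem, n_starts = n_starts)
  rest <- setdiff(problem$free, param)

  sub_problem <- function(value, init) {
    fx <- problem$fixed; fx[[param]] <- value
    for (nm in names(init))  # warm starts may sit on a bound; clamp inside
      init[[nm]] <- min(max(init[[nm]], problem$bounds[[nm]][1]),
                        problem$bounds[[nm]][2])
    fit_problem(problem$shifts, problem$res, problem$bulk,
                representation = problem$representation,
                free = rest, fixed = fx, bounds = problem$bounds,
                init = init, sigma_f = problem$sigma_f,
                sigma_G = problem$sigma_G,
                rho_f = problem$rho_f, f_cen = problem$f_cen)
  }
  fit_at <- function(value, warm_list) {
    pb <- sub_problem(value, as.list(warm_list[[1]][rest]))
    ctx <- model_context(pb)
    fn <- residual_fun(pb, ctx)
    best <- NULL
    for (w in warm_list) {
      theta0 <- to_transformed(w[rest], rest)
      lo <- to_transformed(vapply(rest, function(nm) pb$bounds[[nm]][1], 0), rest)
      hi <- to_transformed(vapply(rest, function(nm) pb$bounds[[nm]][2], 0), rest)
      out <- run_lm(fn, theta0, lo, hi)
      if (!is.null(out) && (is.null(best) || out$deviance < best$deviance))
        best <- out
    }
    if (is.null(best)) return(NULL)
    list(fit = finish_fit(pb, ctx, fn, best, length(warm_list)), pb = pb)
  }

  k <- length(grid)
  chi2 <- rep(NA_real_, k)
  conv <- logical(k)
  co <- matrix(NA_real_, k, length(rest), dimnames = list(NULL, rest))
  opt_par <- free_fit$params
  i0 <- which.min(abs(grid - opt_par[[param]]))
  sweep_order <- c(rev(seq_len(i0)), if (i0 < k) (i0 + 1):k)
  warm <- list(opt_par)
  prev_left <- opt_par
  for (idx in seq_along(sweep_order)) {
    i <- sweep_order[idx]
    if (idx > 1 && i == i0 + 1) warm <- list(opt_par)  # restart at center
    r <- fit_at(grid[i], unique(list(warm[[1]], opt_par)))
    if (is.null(r)) next
    chi2[i] <- r$fit$chi2
    conv[i] <- r$fit$converged
    co[i, ] <- r$fit$params[rest]
    warm <- list(r$fit$params)
  }

  # dominance: if the profile found a better point than the free fit, the free
  # fit was in a local minimum -- refit from that point
  imin <- which.min(chi2)
  if (length(imin) && chi2[imin] < free_fit$chi2) {
    init2 <- as.list(c(co[imin, ], stats::setNames(grid[imin], param)))
    p2 <- problem; p2$init <- utils::modifyList(problem$init, init2)
    refit <- fit_viscoelastic(p2, n_starts = 1)
    if (refit$chi2 < free_fit$chi2) free_fit <- refit
  }

  structure(list(param = param, grid = grid, chi2 = chi2,
                 co_fitted = co, converged = conv,
                 chi2_min = free_fit$chi2,
                 argmin = grid[which.min(chi2)],
                 fit = free_fit),
            class = "chi2_profile")
}

#' @export
print.chi2_profile <- function(x, ...) {
  cat(sprintf("<chi2_profile> over %s: %d grid points, free-fit chi2 = %.6g, argmin = %g\n",
              x$param, length(x$grid), x$chi2_min, x$argmin))
  print(data.frame(grid = x$grid, chi2 = x$chi2, converged = x$converged),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.chi2_profile <- function(x, ...) {
  graphics::plot(x$grid, x$chi2, type = "b", log = "y",
                 xlab = x$param, ylab = expression(chi^2), ...)
  graphics::abline(h = x$chi2_min, lty = 2)
  invisible(x)
}

#' Robust-observable count and determinacy verdict
#'
#' Fits offset, slope and curvature to both `df/n` and `dGamma/n` versus `n`
#' and classifies each observable as robust when its magnitude exceeds
#' `k` standard errors. The five-parameter viscoelastic model needs at least
#' five robust observables; with only offsets and slopes (four observables,
#' the typical very-thin-film situation) it is underdetermined, while reliable
#' curvatures in both channels make it overdetermined.
#'
#' @param shifts An [overtone_shifts()]; noise scales are taken from it, or
#'   estimated from the quadratic-fit residual scatter (flagged) when absent.
#' @param k Robustness threshold in standard errors (default 2).
#' @return An object of class `identifiability_report` with the observable
#'   table, `n_robust` and `verdict` (one of `"underdetermined"`,
#'   `"determined"`, `"overdetermined"`).
#' @export
identifiability_report <- function(shifts, k = 2) {
  stopifnot(inherits(shifts, "overtone_shifts"))
  n <- shifts$n
  if (length(n) < 3) stop("at least 3 overtones required")
  sigma_estimated <- is.null(shifts$sigma_f) || is.null(shifts$sigma_G)
  abs_tol <- 1e-8  # Hz; floats below this count as numerically zero
  one_channel <- function(y, sigma, channel) {
    fit <- quad_ols(n, y, sigma)
    se <- sqrt(abs(diag(fit$cov)))
    data.frame(channel = channel,
               observable = c("offset", "slope", "curvature"),
               value = fit$coef, se = se,
               robust = abs(fit$coef) > pmax(k * se, abs_tol, na.rm = TRUE))
  }
  tab <- rbind(one_channel(shifts$df_over_n, shifts$sigma_f, "df_over_n"),
               one_channel(shifts$dG_over_n, shifts$sigma_G, "dG_over_n"))
  n_robust <- sum(tab$robust, na.rm = TRUE)
  verdict <- if (n_robust >= 6) "overdetermined"
             else if (n_robust == 5) "determined"
             else "underdetermined"
  structure(list(observables = tab, n_robust = n_robust, verdict = verdict,
                 k = k, sigma_estimated = sigma_estimated),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("<identifiability_report> %d robust observables (|value| > %g se) -> %s\n",
              x$n_robust, x$k, x$verdict))
  print(x$observables, row.names = FALSE)
  if (x$sigma_estimated)
    cat("  note: noise scales estimated from residual scatter\n")
  invisible(x)
}
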