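make_problem <- function(d, sigma = 0.1, shifts = NULL, ...) {
  if (is.null(shifts))
    shifts <- shifts_from_complex(odd_n,
      predict_film(res5, layer(soft_material(), d), water, odd_n,
                   reference = "bulk"), reference = "bulk")
  fit_problem(shifts, res5, water, sigma_f = sigma, sigma_G = sigma, ...)
}

test_that("noiseless five-parameter fit recovers the generator exactly", {
  fit <- fit_viscoelastic(make_problem(10e-9))
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-12)
  truth <- c(d_f = 10e-9, value1 = 0.29e-6, value2 = 1.68e-6,
             beta1 = -1.61, beta2 = -0.91)
  for (nm in names(truth))
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-3)
  # the fitted layer regenerates the data through the forward model
  fl <- fitted_layer(fit)
  expect_s3_class(fl, "qcm_layer")
  regen <- predict_film(res5, fl, water, odd_n, reference = "bulk") / odd_n
  expect_equal(Re(regen), fit$problem$shifts$df_over_n, tolerance = 1e-6)
})

test_that("rigid-film data with only d_f free reproduces the Sauerbrey thickness", {
  fl <- layer(rigid_material(), 7e-9)
  sh <- shifts_from_complex(odd_n,
    predict_film(res5, fl, water, odd_n, reference = "bulk"), reference = "bulk")
  pr <- fit_problem(sh, res5, water, free = "d_f",
                    fixed = list(value1 = 1e-10, value2 = 1e-10,
                                 beta1 = 0, beta2 = 0))
  fit <- fit_viscoelastic(pr)
  d_sb <- sauerbrey_mass(res5, mean(sh$df_over_n)) / 1000
  expect_equal(fit$params[["d_f"]], d_sb, tolerance = 1e-3)
})

test_that("chi-square weights scale as sigma^-2 and leave the optimum unchanged", {
  sh <- step_shifts(10e-9, seed = 3)
  f1 <- fit_viscoelastic(make_problem(NA, sigma = 0.1, shifts = sh))
  f2 <- fit_viscoelastic(make_problem(NA, sigma = 0.3, shifts = sh))
  expect_equal(f2$chi2, f1$chi2 / 9, tolerance = 1e-6)
  expect_equal(f2$params[["d_f"]], f1$params[["d_f"]], tolerance = 1e-4)
})

test_that("chi-square minimum is invariant under exact reparameterization of the material", {
  # modulus {G', G''} and viscosity {eta', eta''} power laws describe the
  # identical model family (eta' = G''/omega shifts each exponent by one), so
  # the chi-square minima must agree exactly; only chi2 is asserted, since in
  # a degenerate landscape the parameter sets need not map onto each other
  sh <- step_shifts(10e-9, seed = 5)
  om_cen <- 2 * pi * 30e6
  pr_G <- fit_problem(sh, res5, water, representation = "modulus")
  fit_G <- fit_viscoelastic(pr_G)
  pr_v <- fit_problem(sh, res5, water, representation = "viscosity")
  fit_v <- fit_viscoelastic(pr_v)
  to_visc <- function(p) list(d_f = p[["d_f"]],
                              value1 = p[["value2"]] / om_cen,
                              value2 = p[["value1"]] / om_cen,
                              beta1 = p[["beta2"]] - 1, beta2 = p[["beta1"]] - 1)
  to_mod <- function(p) list(d_f = p[["d_f"]],
                             value1 = om_cen * p[["value2"]],
                             value2 = om_cen * p[["value1"]],
                             beta1 = p[["beta2"]] + 1, beta2 = p[["beta1"]] + 1)
  polish <- function(pr, init) {
    pr$init <- init
    fit_viscoelastic(pr, n_starts = 1)
  }
  chi_G <- min(fit_G$chi2, polish(pr_G, to_mod(fit_v$params))$chi2)
  chi_v <- min(fit_v$chi2, polish(pr_v, to_visc(fit_G$params))$chi2)
  expect_equal(chi_v, chi_G, tolerance = 1e-6)

  # equivalent physical start points give the same residuals in both systems
  mats <- list(power_law_material("modulus", 1e5, 9e5, -0.2, 0.3),
               power_law_material("viscosity", 9e5 / om_cen, 1e5 / om_cen,
                                  -0.7, -1.2))
  shift2 <- lapply(mats, function(m)
    predict_film(res5, layer(m, 7e-9), water, odd_n, reference = "bulk"))
  expect_equal(shift2[[1]], shift2[[2]], tolerance = 1e-12)
})

test_that("underdetermined thin-film regime shows up in the standard errors", {
  # 2 nm film with per-crystal offsets: some viscoelastic parameter has a
  # standard error comparable to (or larger than) its value
  frac <- withr::with_seed(21, {
    vapply(1:20, function(i) {
      sh <- step_shifts(2e-9, seed = sample.int(1e6, 1))
      fit <- fit_viscoelastic(fit_problem(sh, res5, water))
      rel <- fit$stderr[c("value1", "value2", "beta1", "beta2")] /
        abs(unlist(fit$params[c("value1", "value2", "beta1", "beta2")]))
      any(rel >= 1, na.rm = TRUE)
    }, logical(1))
  })
  expect_gt(mean(frac), 0.5)
})

test_that("profile likelihood dominates the free fit and finds the optimum on its grid", {
  sh <- step_shifts(10e-9, seed = 9, noise = noise_model(0.05, 0.02),
                    sigma_f = 0.05, sigma_G = 0.05)
  pr <- fit_problem(sh, res5, water, sigma_f = 0.05, sigma_G = 0.05)
  d_hat <- fit_viscoelastic(pr)$params[["d_f"]]
  grid <- sort(c(d_hat, seq(6e-9, 14e-9, length.out = 8)))
  prof <- chi2_landscape(pr, "d_f", grid)
  expect_true(all(prof$chi2 >= prof$chi2_min - 1e-9 * prof$chi2_min))
  expect_equal(prof$argmin, 10e-9, tolerance = 0.15)
  # the grid contains the free optimum, so the profile minimum reaches it
  expect_equal(min(prof$chi2), prof$chi2_min, tolerance = 1e-6)
  expect_equal(dim(prof$co_fitted), c(9L, 4L))
})

test_that("thin film gives a flat thickness valley above truth, thick film a sharp one", {
  thin <- step_shifts(2e-9, seed = 7)
  thick <- step_shifts(10e-9, seed = 7)
  prof_thin <- chi2_landscape(fit_problem(thin, res5, water), "d_f",
                              c(1e-9, 2e-9, 2.6e-9, 4e-9, 6e-9))
  prof_thick <- chi2_landscape(fit_problem(thick, res5, water), "d_f",
                               c(7e-9, 10e-9, 13e-9))
  # steep rise below truth for the thin film
  expect_gt(prof_thin$chi2[1] / prof_thin$chi2_min, 50)
  # flat (thin-and-stiff vs thick-and-soft degeneracy) up to ~3x truth
  expect_lt(max(prof_thin$chi2[2:5]) / prof_thin$chi2_min, 3)
  # sharp thick-film valley: +-30% costs far more, relatively, than the
  # thin film's +30%
  rel_thin <- prof_thin$chi2[3] / prof_thin$chi2_min - 1
  rel_thick <- min(prof_thick$chi2[c(1, 3)]) / prof_thick$chi2_min - 1
  expect_gt(rel_thick, 10 * rel_thin)
})

test_that("identifiability report separates curved from straight overtone dependence", {
  # noiseless curved data: six robust observables, overdetermined
  sh <- shifts_from_complex(odd_n,
    predict_film(res5, layer(soft_material(), 10e-9), water, odd_n,
                 reference = "bulk"),
    sigma_f = 0, sigma_G = 0, reference = "bulk")
  rep0 <- identifiability_report(sh)
  expect_identical(rep0$verdict, "overdetermined")
  expect_identical(rep0$n_robust, 6L)

  # straight-line data with noise: only offsets and slopes are robust
  sh_lin <- withr::with_seed(4, suppressWarnings(
    overtone_shifts(odd_n, -10 - 0.3 * odd_n + stats::rnorm(5, 0, 0.1),
                    2 + 0.2 * odd_n + stats::rnorm(5, 0, 0.1),
                    sigma_f = 0.1, sigma_G = 0.1)))
  rep1 <- identifiability_report(sh_lin)
  expect_identical(rep1$verdict, "underdetermined")
  expect_lte(rep1$n_robust, 4L)

  # emulated adsorption contrast: an n-dependence spanning ~0.3 Hz at 0.1 Hz
  # offsets is noise-dominated, ~3 Hz is signal-dominated
  thin <- step_shifts(2e-9, seed = 2)
  thick <- step_shifts(10e-9, seed = 2)
  expect_lt(diff(range(thin$df_over_n)), 0.9)
  expect_gt(diff(range(thick$df_over_n)), 2)
  expect_identical(identifiability_report(thin)$verdict, "underdetermined")
  expect_identical(identifiability_report(thick)$verdict, "overdetermined")
})

test_that("fit problem validates its contract", {
  sh <- step_shifts(10e-9)
  expect_error(fit_problem(sh, res5, water, free = c("d_f", "nope")))
  expect_error(fit_problem(sh, res5, water, free = "d_f"), "fixed value")
  expect_error(fit_problem(sh, res5, water, init = list(d_f = 1)), "bounds")
  sh0 <- overtone_shifts(odd_n, numeric(5), numeric(5))
  expect_error(fit_viscoelastic(fit_problem(sh0, res5, water)), "degenerate")
})
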