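test_that("air recipe: Sauerbrey data gives the areal mass exactly and zero compliance", {
  fl <- layer(rigid_material(), 40e-9)
  sh <- shifts_from_complex(odd_n, taylor_air(res5, fl, odd_n, "eq5"))
  est <- estimate_film_in_air(sh, res5, rho_f = 1000, variant = "eq5")
  expect_equal(est$m_f, fl$m_f, tolerance = 1e-12)
  expect_lt(abs(est$J1), 1e-12)
  expect_equal(est$J2, 0)
})

test_that("air recipe round-trips its generating equations to near machine precision", {
  mat <- power_law_material("compliance", 0.8e-6, 0.5e-6, -0.9, -0.4, rho = 1100)
  fl <- layer(mat, 60e-9)
  for (variant in c("eq6", "eq5")) {
    sh <- shifts_from_complex(odd_n, taylor_air(res5, fl, odd_n, variant))
    est <- estimate_film_in_air(sh, res5, rho_f = 1100, variant = variant)
    expect_equal(est$m_f, fl$m_f, tolerance = 1e-10)
    expect_equal(est$J1, 0.8e-6, tolerance = 1e-8)
    expect_equal(est$beta1, -0.9, tolerance = 1e-8)
    expect_equal(est$J2, 0.5e-6, tolerance = 1e-8)
    expect_equal(est$beta2, -0.4, tolerance = 1e-8)
    # comfortably inside the recipe's stated accuracy (1%, beta' 10%)
    expect_lt(abs(est$J1 / 0.8e-6 - 1), 0.01)
    expect_lt(abs(est$beta1 / -0.9 - 1), 0.1)
  }
})

test_that("air recipe on a noisy thin film: beta' carries a standard error exceeding its size", {
  mat <- soft_material()
  fl <- layer(mat, 2e-9)
  clean <- taylor_air(res5, fl, odd_n, "eq6")
  draws <- withr::with_seed(11, {
    replicate(200, {
      noisy <- clean + complex(real = stats::rnorm(5, 0, 0.1) * odd_n,
                               imaginary = stats::rnorm(5, 0, 0.1) * odd_n)
      # keep the bandwidth channel physical for this thin lossy film
      sh <- suppressWarnings(
        overtone_shifts(odd_n, Re(noisy) / odd_n, Im(noisy) / odd_n,
                        sigma_f = 0.1, sigma_G = 0.1))
      est <- suppressWarnings(estimate_film_in_air(sh, res5, variant = "eq6"))
      c(beta1 = est$beta1, se = unname(est$diagnostics$se["beta1"]),
        m_f = est$m_f)
    })
  })
  se_beta <- draws["se", ]
  expect_gt(stats::median(se_beta, na.rm = TRUE), abs(-1.61))
  # the mass, by contrast, stays robust (errors are not cross-correlated)
  expect_lt(stats::median(abs(draws["m_f", ] / fl$m_f - 1)), 0.05)
})

test_that("stiff-film-in-liquid recipe: rigid film recovers the Sauerbrey thickness", {
  fl <- layer(rigid_material(1200), 6e-9)
  sh <- shifts_from_complex(odd_n, taylor_liquid(res5, fl, water, odd_n),
                            reference = "bulk")
  est <- estimate_stiff_film_in_liquid(sh, res5, water, rho_f = 1200)
  expect_equal(est$d_f, 6e-9, tolerance = 1e-12)
  expect_equal(est$m_f, sauerbrey_mass(res5, mean(sh$df_over_n)), tolerance = 1e-12)
  expect_lt(abs(est$J2), 1e-12)
  expect_equal(est$J1, 0)
})

test_that("stiff-film-in-liquid recipe round-trips its generating equations", {
  mat <- power_law_material("compliance", 0.05e-6, 0.08e-6, -0.5, -0.3, rho = 1200)
  fl <- layer(mat, 8e-9)
  sh <- shifts_from_complex(odd_n, taylor_liquid(res5, fl, water, odd_n),
                            reference = "bulk")
  est <- estimate_stiff_film_in_liquid(sh, res5, water, rho_f = 1200)
  expect_equal(est$d_f, 8e-9, tolerance = 1e-10)
  expect_equal(est$J2, 0.08e-6, tolerance = 1e-8)
  expect_equal(est$beta2, -0.3, tolerance = 1e-8)
  expect_equal(est$J1, 0.05e-6, tolerance = 1e-8)
  expect_equal(est$beta1, -0.5, tolerance = 1e-8)
  expect_false(est$validity$stiffness_violated)
  # within the recipe's stated 2%
  expect_lt(abs(est$d_f / 8e-9 - 1), 0.02)
})

test_that("recipes applied to the exact model converge as the film gets thin", {
  mat <- power_law_material("compliance", 0.05e-6, 0.08e-6, -0.5, -0.3, rho = 1200)
  err <- vapply(c(8e-9, 2e-9), function(d) {
    sh <- shifts_from_complex(odd_n,
      predict_film(res5, layer(mat, d), water, odd_n, reference = "bulk"),
      reference = "bulk")
    est <- estimate_stiff_film_in_liquid(sh, res5, water, rho_f = 1200)
    abs(est$d_f / d - 1)
  }, 0)
  expect_gt(err[1] / err[2], 2)   # recipe error shrinks with thickness
  expect_lt(err[2], 0.02)
})

test_that("soft film violating the stiffness assumption is flagged and J' biased", {
  sh <- shifts_from_complex(odd_n,
    predict_film(res5, layer(soft_material(), 5e-9), water, odd_n,
                 reference = "bulk"), reference = "bulk")
  est <- estimate_stiff_film_in_liquid(sh, res5, water)
  expect_true(est$validity$stiffness_violated)
  # documented bias: J' off by far more than the stiff-regime accuracy
  expect_gt(abs(est$J1 / 0.29e-6 - 1), 0.1)
})

test_that("stiffness validity check reports both ratios and is monotone", {
  expect_true(validate_stiffness(rigid_material(), water, 15e6)$valid)
  expect_equal(validate_stiffness(rigid_material(), water, 15e6)$ratio_J, 0)

  # a film that is Newtonian like the bulk sits at the boundary: invalid
  newt <- power_law_material("viscosity", 1e-3, 1e-12, rho = 1000)
  v <- validate_stiffness(newt, water, 15e6)
  expect_false(v$valid)
  expect_equal(v$ratio_eta, 1, tolerance = 1e-6)
  expect_equal(v$ratio_J, 1, tolerance = 1e-6)

  # sweep: ratio_J increases monotonically with J''
  ratios <- vapply(10^seq(-9, -5, length.out = 9), function(J2) {
    m <- power_law_material("compliance", 1e-8, J2)
    validate_stiffness(m, water, 15e6)$ratio_J
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("thin-film acoustic ratio closed forms agree across representations", {
  # Eq-15-type compliance form == loss-tangent form after conversion
  set.seed(5)
  for (i in 1:25) {
    eta_abs <- 10^stats::runif(1, -3.5, -1.5)
    tand <- 10^stats::runif(1, -1, 2)
    om <- 2 * pi * 15e6
    J <- convert_representation(c(om * eta_abs, tand), "magnitude_loss",
                                "compliance", omega = om)
    r1 <- acoustic_ratio_compliance(J[1], J[2], 1e-3, om)
    r2 <- acoustic_ratio_loss(eta_abs, tand, 1e-3)
    expect_equal(r1, r2, tolerance = 1e-10)
  }
})

test_that("nearly Newtonian limit of the acoustic ratio matches the exact model", {
  # at |eta_f| = eta_bulk the thin-film ratio tends to 2 tan(delta); the
  # frequency shift is then second order in the inverse loss tangent
  t50 <- 50
  r_closed <- acoustic_ratio_loss(1e-3, t50, 1e-3)
  expect_equal(r_closed, 2 * t50, tolerance = 0.01)

  # exact model, thin film, same material
  eta1 <- 1e-3 * t50 / sqrt(1 + t50^2)
  eta2 <- 1e-3 / sqrt(1 + t50^2)
  mat <- power_law_material("viscosity", eta1, eta2, rho = 1000)
  sh <- predict_film(res5, layer(mat, 1e-11), water, 3, reference = "bulk")
  expect_equal(Im(sh) / (-Re(sh)), 2 * t50, tolerance = 0.05)

  # for |eta_f| > eta_bulk the large-tan-delta limit is (1/t)/(|eta_f|/eta_b - 1)
  for (r in c(0.2, 0.5)) {
    lim <- acoustic_ratio_loss(1e-3 / r, 1e5, 1e-3)
    expect_equal(lim, (1 / 1e5) / (1 / r - 1), tolerance = 1e-3)
  }
})

test_that("double-layer analysis: real viscosity increment gives Sauerbrey-type behavior", {
  mat <- power_law_material("viscosity", 1.05e-3, 1e-9, rho = 1000)
  d <- 3e-9
  sh <- shifts_from_complex(odd_n,
    predict_film(res5, layer(mat, d), water, odd_n, reference = "bulk"),
    reference = "bulk")
  # frequency shifts dominate, and df/n is nearly constant across overtones
  expect_true(all(abs(acoustic_ratio(sh)) < 0.05))
  expect_lt(diff(range(sh$df_over_n)) / abs(mean(sh$df_over_n)), 0.05)
  dl <- double_layer_analysis(sh, res5, water, d_f = d)
  # d * delta_eta' recovered within the small-increment approximation
  expect_equal(mean(dl$visc_mass), d * 0.05e-3, tolerance = 0.1)
})

test_that("double-layer analysis recovers the inverse loss tangent at |eta_f| = eta_bulk", {
  t50 <- 50
  eta1 <- 1e-3 * t50 / sqrt(1 + t50^2)
  eta2 <- 1e-3 / sqrt(1 + t50^2)
  mat <- power_law_material("viscosity", eta1, eta2, rho = 1000)
  d <- 1e-11
  sh <- shifts_from_complex(odd_n,
    predict_film(res5, layer(mat, d), water, odd_n, reference = "bulk"),
    reference = "bulk")
  true_inv <- eta2 / eta1                     # = 1/tan(delta) = 0.02
  dl_free <- double_layer_analysis(sh, res5, water)
  expect_equal(mean(dl_free$tan_delta_inv), true_inv, tolerance = 0.03)
  dl_d <- double_layer_analysis(sh, res5, water, d_f = d)
  expect_equal(mean(dl_d$tan_delta_inv), true_inv, tolerance = 0.03)
})

test_that("recipe error handling: no film and too few overtones", {
  sh_pos <- suppressWarnings(overtone_shifts(odd_n, rep(1, 5), rep(0, 5)))
  expect_error(estimate_film_in_air(sh_pos, res5), "no film")
  sh2 <- overtone_shifts(c(3, 5), c(-10, -10.2), c(0.5, 0.6))
  est <- estimate_film_in_air(sh2, res5)
  expect_true(est$validity$curvature_unidentifiable)
  expect_gt(est$m_f, 0)
})
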