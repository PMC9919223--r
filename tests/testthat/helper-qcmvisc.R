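# Shared fixtures: a 5 MHz AT-cut resonator, water, and the soft-adsorbate
# film parameters (compliance representation, f_cen = 30 MHz) used throughout.

res5 <- resonator(f0 = 5e6, Zq = 8.8e6)
water <- bulk_medium("newtonian", rho = 1000, eta = 1e-3)
vacuum <- bulk_medium("vacuum")

soft_material <- function(rho = 1000) {
  power_law_material("compliance", 0.29e-6, 1.68e-6,
                     beta1 = -1.61, beta2 = -0.91, f_cen = 30e6, rho = rho)
}

odd_n <- c(3, 5, 7, 9, 11)

# Frozen oracle values: arbitrary-precision complex evaluation of the exact
# single-film load equation (mpmath, 50 digits) for the soft-adsorbate film,
# d = 9.8 nm, rho_f = 1000, in water, referenced to the bulk baseline;
# df/n + i dGamma/n in Hz at n = 3, 5, 7, 9, 11.
oracle_soft_film <- complex(
  real = c(-38.423404296185344, -37.379260037030764, -36.627132098014222,
           -36.026990014926738, -35.52159268631345),
  imaginary = c(5.5857601477574039, 4.5720094783269448, 4.1354098244904977,
                3.9131236762956426, 3.7941267130783041))

# Frozen oracle: Kanazawa-Gordon closed form df = -f0^(3/2) sqrt(rho eta / pi) / Zq
# for water at 5 MHz, n = 1 (same source).
oracle_kanazawa_n1 <- -716.79901193754547

rigid_material <- function(rho = 1000) power_law_material("compliance", 0, 0, rho = rho)

# quick synthetic single-point dataset at a given thickness
step_shifts <- function(d, material = soft_material(), bulk = water,
                        noise = noise_model(0.1, 0.02), seed = 1,
                        sigma_f = 0.1, sigma_G = 0.1) {
  des <- experiment_design(res5, bulk, material,
                           growth = list(type = "step", d_max = d, t0 = 0),
                           times = 0:1, noise = noise, seed = seed)
  shifts_at(generate_timeseries(des), 1, sigma_f = sigma_f, sigma_G = sigma_G)
}
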