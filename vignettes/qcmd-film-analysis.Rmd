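---
title: "Viscoelastic film analysis for QCM-D data: models, recipes, and identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic film analysis for QCM-D data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcmvisc)
```

## The measurement and the model

A quartz crystal microbalance with dissipation monitoring (QCM-D) reports,
for a set of odd overtones $n$ (typically 3, 5, 7, 9, 11 on a 5 MHz crystal),
the overtone-normalized shifts in resonance frequency, $\Delta f/n$, and in
half-bandwidth, $\Delta\Gamma/n$ (instruments that report the dissipation
factor $D$ instead are handled through $\Gamma = D f_\mathrm{res}/2$, i.e.
2.5 Hz per ppm of $\Delta D$ on a 5 MHz crystal). A planar viscoelastic film
of thickness $d_f$ and complex shear modulus $\tilde G_f$, covered by a
semi-infinite ambient of shear-wave impedance $\tilde Z_\mathrm{bulk}$, loads
the resonator according to the standard acoustic-load result (within the
small-load approximation):

$$
\frac{\Delta f + i\,\Delta\Gamma}{f_0}
 = \frac{-\tilde Z_f}{\pi Z_q}\,
   \frac{\tilde Z_f \tan(\tilde k_f d_f) - i \tilde Z_\mathrm{bulk}}
        {\tilde Z_f + i \tilde Z_\mathrm{bulk}\tan(\tilde k_f d_f)},
$$

with $\tilde Z = (\rho \tilde G)^{1/2}$, $\tilde k = \omega\rho/\tilde Z$,
and $Z_q$ the shear-wave impedance of AT-cut quartz. `predict_film()`
evaluates this exactly (no expansion in thickness), `predict_multilayer()`
extends it to layer stacks by recursive impedance transfer, and
`kanazawa()` and `sauerbrey()` are its $d_f = 0$ and rigid-film limits.

Material properties are evaluated at $f = n f_0$ on each overtone. Because
the QCM covers only about one decade of frequency, dispersion is modelled by
power laws in the material's own representation,
$v_i(f) = v_{i,\mathrm{cen}} (f/f_\mathrm{cen})^{\beta_i}$, giving the
five-parameter set $\{d_f, v_1, v_2, \beta_1, \beta_2\}$. Four
representations are supported (compliance $J', J''$; modulus $G', G''$;
viscosity $\eta', \eta''$; magnitude--loss $|G|, \tan\delta$); the loss
tangent is representation-independent, and conversions are exact at any one
frequency.

One subtlety deserves emphasis: power laws in $(G', G'')$ and in
$(\eta', \eta'')$ describe the *same* model family (the exponents shift by
one, since $\eta' = G''/\omega$), and the fitted $\chi^2$ minima agree
exactly — this is asserted in the test suite. Power laws in $(J', J'')$
versus $(|G|, \tan\delta)$, however, span *different* five-parameter
families: $J'(f)$ is not an exact power law when $\tan\delta$ is one. Fits of
the same data in the two representations therefore legitimately return
different parameter sets — including different thicknesses — at slightly
different $\chi^2$, which is worth keeping in mind when comparing analyses.

## Parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| `f0` | 5e6 | Hz | most common QCM-D crystal |
| `Zq` | 8.8e6 | kg m$^{-2}$ s$^{-1}$ | standard AT-cut value; gives the familiar 5.7 Hz/nm sensitivity at unit density |
| `f_cen` | 30e6 | Hz | center of the overtone range of a 5 MHz crystal |
| `rho_f` | 1000 | kg m$^{-3}$ | customary assumption for hydrated organic films |
| `sigma_f`, `sigma_G` | 0.1 | Hz | magnitude of per-crystal irregularities; used as $\chi^2$ weights |
| `offset_scale` | 0.1 | Hz | half-width of the constant per-crystal offsets in synthetic data |
| `white_scale` | 0.02 | Hz | statistical noise floor per sample after typical pre-averaging |
| $\beta$ bounds | $[-3, 3]$ | — | generous envelope for soft-matter dispersion |

The fundamental ($n = 1$) is excluded by default everywhere (recipes and
fits): in practice it behaves erratically because of energy trapping and
mounting effects.

## The thin-film recipes

Two graphical recipes give closed-form estimates that are useful for
intuition and for starting values; `fit_viscoelastic()` is the accurate
route.

**Film in air** (`estimate_film_in_air()`): the third-order expansion puts
$\Delta f/n$ versus $n^2$ on a nearly straight line whose intercept gives the
areal mass $m_f = -\Delta f_\mathrm{intercept}/(n f_0)\, m_q$, slope gives
$J'$, and curvature gives $\beta'$; the bandwidth channel gives $J''$ and
$\beta''$. Two variants of the expansion are available (`eq5`, the plain
Taylor form, and `eq6`, which subtracts 1 from the compliance bracket — a
small correction beyond the small-load approximation; `eq6` is the default).

**Stiff film in liquid** (`estimate_stiff_film_in_liquid()`): valid when
$J''_f \ll J''_\mathrm{bulk}$ (equivalently $\eta'_f \gg \eta_\mathrm{bulk}$;
checked by `validate_stiffness()` at a configurable 10$\times$ threshold and
flagged, never silently enforced). Here $\Delta f/n$ versus $n$ yields
thickness, $J''$ and $\beta''$, while the acoustic ratio
$\Delta\Gamma/(-\Delta f) \approx \omega\eta_\mathrm{bulk} J'_f$ —
thickness-independent in this regime — yields $J'$ and $\beta'$.

Numerically, both recipes fit the prescribed ordinary-least-squares quadratic
(the offset/slope/curvature *observables*, with analytic standard errors),
and then invert the recipe's own generating equation exactly: because the
constant and linear basis functions are inside the quadratic basis, the OLS
coefficients of noiseless recipe data are exact linear images of the model,
and a one-dimensional root solve in the power-law exponent recovers the
generating parameters to machine precision. The compliance of the bandwidth
channel is inverted from $\Delta\Gamma/n$ directly rather than from the
acoustic-ratio form, which contains an extra "real bracket $\approx$ 1"
approximation; the acoustic-ratio values are still reported in diagnostics.
The curvature is typically the noisiest observable, and the recipe reports a
correspondingly large standard error on the exponent derived from it — on a
thin film with 0.1 Hz noise the error bar on $\beta'$ routinely exceeds
$|\beta'|$, while the mass stays robust.

## The near-Newtonian layer (viscosity increment)

For a thin layer that is almost the same Newtonian liquid as the bulk
($\tilde\eta_f = \eta_\mathrm{bulk} + \Delta\tilde\eta$), the bulk-referenced
shifts reduce to
$(\Delta f + i\Delta\Gamma)/n \approx -(2 f_0^2/Z_q)\,\rho\, d_f\,
\Delta\tilde\eta/\eta_\mathrm{bulk}$. Only the products
$d_f\,\Delta\eta'$ and $d_f\,\Delta\eta''$ are observable — the thickness
itself cannot be separated, which is the double-layer ambiguity:
Sauerbrey-type traces (frequency shift dominant, flat in $n$) arise whenever
$\Delta\tilde\eta$ is mostly real, whether caused by adsorption or by
increased near-surface viscosity.

`double_layer_analysis()` reports these products per overtone and an
inverse-loss-tangent estimate. In the thin-film limit at
$|\tilde\eta_f| = \eta_\mathrm{bulk}$, exact substitution into the
closed-form acoustic ratio gives
$\Delta\Gamma/(-\Delta f) \to 2\tan\delta$ (the frequency shift is second
order in the inverse loss tangent there, which makes the ratio large, not
small), so without a supplied thickness the inverse loss tangent is estimated
as $2/\mathrm{ratio}$; with a thickness it is computed exactly from the
recovered increment as $\Delta\eta''/(\eta_\mathrm{bulk} + \Delta\eta')$.
Both routes recover the truth to well within 3% at $\tan\delta = 50$ in the
test suite, and the general large-$\tan\delta$ limit implemented in
`acoustic_ratio_loss()` is
$(1/\tan\delta)\cdot 1/(|\tilde\eta_f|/\eta_\mathrm{bulk} - 1)$. The
closed forms in the compliance and magnitude–loss variables are exact
rewrites of one another, asserted over randomized parameters.

## Fitting and identifiability

`fit_viscoelastic()` minimizes
$\chi^2 = \sum_n \left[(\Delta f/n|_\mathrm{mod} - \Delta f/n|_\mathrm{dat})^2/\sigma_f^2
 + (\Delta\Gamma/n|_\mathrm{mod} - \Delta\Gamma/n|_\mathrm{dat})^2/\sigma_\Gamma^2\right]$
with the exact forward model, using bounded Levenberg–Marquardt on
transformed parameters: logarithms for the thickness and the two (positive)
stiffness values — positivity without penalty terms — and identity for the
exponents on $[-3, 3]$. Because the landscape can have shallow valleys, a
deterministic eight-point Latin-hypercube of starts over the bounds
supplements the user start; the best converged solution wins. $\chi^2$ is
reported unnormalized (and per degree of freedom as `chi2_reduced`), and
equal $\Delta f$/$\Delta\Gamma$ weighting of 0.1 Hz is the default. Local
standard errors come from an SVD pseudo-inverse of the weighted normal
matrix, so degenerate directions surface as very large error bars rather
than failures.

`chi2_landscape()` prescribes one parameter over a grid, refits the rest at
each point (warm-started from the neighboring solution, sweeping outward
from the free optimum — the valleys are continuous), and returns the profile
together with the co-fitted parameters. The profile dominates the free fit
by construction; if a grid point ever undercuts it, the free fit is refit
from that point so the dominance invariant holds exactly.

The practical identifiability story is the thickness profile's shape. A
2 nm soft film with 0.1 Hz per-crystal offsets produces a valley that rises
steeply below the true thickness but stays shallow above it — the fit trades
a larger thickness for a larger compliance ("thin and stiff or thick and
soft"), and in our synthetic emulation the profile stays within about
2$\times$ of its minimum up to roughly 3$\times$ the true thickness before
rising (by ~an order of magnitude at 5$\times$, where the exact model's
curvature in $n$ can no longer mimic the thin film's nearly straight
overtone dependence at these noise levels). A 10 nm film under the same
offsets gives a sharp single minimum: $\pm30\%$ in thickness costs an order
of magnitude more, relatively, than the thin film's $+30\%$.
`identifiability_report()` expresses the same contrast on the data side:
offsets, slopes and curvatures of both channels versus $n$ are classified as
robust at 2 standard errors, and five model parameters require at least five
robust observables — thin films typically offer four (offsets and slopes)
and are underdetermined, thick films offer all six and are overdetermined.

## What the synthetic generator does and does not emulate

`generate_timeseries()` produces adsorption transients (step, Langmuir or
linear thickness growth) through the exact model, referenced to the
bulk-loaded baseline, and adds the experimentally dominant noise structure:
per-crystal constant offsets, drawn once per overtone and channel from a
zero-mean uniform distribution of half-width 0.1 Hz and held fixed over the
series (block averaging with `pre_average()` leaves them bit-identical,
while white noise shrinks by $\sqrt{k}$), plus Gaussian per-sample noise
with a 0.02 Hz default. It does not emulate temperature drift, compressional
wave or mounting artifacts, the high-overtone anomalies seen on Newtonian
liquids, particulate or laterally heterogeneous adsorbates, or slip — so a
passing test here says the mathematics and the noise *structure* are
handled, not that every instrumental pathology is.

Problem sizes used by the tests and the acceptance script were chosen to
exercise the Monte-Carlo statistics at modest cost: 9 offset draws for the
landscape contrast, 100 datasets for the thickness-recovery statistic, 200
draws for the recipe error-bar check.

## Numerical choices

* Complex square roots are taken on the passivity branch $\Re(\tilde Z) > 0$,
  which makes $\Im(\tilde k) < 0$ (decaying wave) for passive materials.
* $\tan(\tilde k d)$ is computed as $-i(1 - w)/(1 + w)$ with
  $w = e^{-2i\tilde k d}$ (mirrored for the opposite half-plane), which is
  exact, overflow-free, and saturates smoothly at $-i$ so that very thick
  films return the semi-infinite value of the film material regardless of the
  terminating bulk.
* The rigid limit $\tilde J = 0$ is handled symbolically (a rigid layer adds
  pure inertia $i\omega\rho d$ to the load), so Sauerbrey behavior is exact
  rather than a numerical limit.
* Recipe exponent roots are bracketed on either side of the removable
  $q = 1$ singularity of the curvature/slope ratio, with the side chosen by
  the sign of the measured curvature; failure to bracket (noisy data with
  inverted curvature) degrades gracefully to the four-parameter output with
  the exponent's uncertainty reported as large or `NA`.
* Warm starts along a profile grid are clamped into the bounds before
  refitting; optimizer tolerances are `ftol = ptol = 1e-14` so noiseless
  round trips sit at machine precision.

## Known limitations

Planar, laterally homogeneous films only; piezoelectric stiffening, energy
trapping, roughness and slip are outside the model. The recipes are limits
of the exact equation and are labelled approximate in their output — their
estimates biased (and flagged) outside their validity regimes. Profile
likelihood curves and local standard errors are the only uncertainty
measures provided; there is no Bayesian posterior. Continuous viscoelastic
profiles are supported only as piecewise-constant stacks, which converge to
the smooth-profile integral in the thin limit.
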