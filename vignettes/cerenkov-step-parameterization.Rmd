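---
title: "Electron step parameterization and Cerenkov photon simulation in dense scintillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron step parameterization and Cerenkov photon simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerstep)
```

## The problem

Cerenkov photons are the earliest optical signal a 511 keV gamma produces
in a dense scintillator such as BGO: the photoelectric recoil electron is
relativistic for the first fraction of a millimetre of its path and radiates
a few tens of photons within picoseconds, with a cone geometry tied to the
electron direction. Detectors that trigger on these prompt photons are a
route to better coincidence timing in time-of-flight PET, so simulations
must get their number, direction, and detection time right.

Stepwise Monte Carlo codes track the electron in rectilinear steps and emit
Cerenkov light per step. The step length is therefore a physics
parameterization, not a numerical detail: a single range-length step keeps
all photons on a forward cone, while sub-micron steps let multiple
scattering randomize the electron — and hence the light — within tens of
microns. `cerstep` reimplements this chain at desk scale so the dependence
of every observable on the per-step velocity-change limit can be studied
without a full toolkit installation.

## Model

**Recoil electron.** A monoenergetic gamma travels along +z from a source
10 mm upstream of a 3×3×20 mm crystal. Interaction depths are exponential
(photoelectric mass attenuation 0.056 cm²/g for BGO at 511 keV), truncated
to the crystal because only interacting events are analyzed. The shell is
drawn with probability 0.80 for the bismuth K edge (0.091 MeV) and 0.20 for
a single L–M pseudo-shell at 0.008 MeV, the midpoint of the 0.001–0.016 MeV
band; the K share follows the standard rule that the innermost shell
carries about 80% of the photoelectric cross-section above its edge. The
electron energy is the gamma energy minus the binding energy (0.420 MeV at
511 keV), and its direction follows the Sauter distribution
$f(\theta) \propto \sin^2\theta / (1-\beta\cos\theta)^4$, which is strongly
forward at these energies.

**Energy loss.** Collision stopping powers are the Møller-corrected Bethe
(Berger–Seltzer) formula with the material mean excitation energy from
Bragg additivity under the usual condensed-phase adjustments (534 eV for
BGO); radiative losses use the classic $S_{rad}/S_{col} \approx
T\,Z_{\mathrm{eff}}/800$ estimate and stay below 10% of the total in the
energy range simulated. Both are tabulated on a 200-point log grid from
1 keV to 2 MeV together with the CSDA range (the integral of $1/(dE/dx)$),
and the pair plays the role of the energy-loss and range tables a
condensed-history code builds at initialization. The density-effect
correction is omitted; below 1 MeV in BGO it is a percent-level term,
smaller than the stated tolerance of every length-scale result.

**Stepping rule.** By default each step is range-based:
$\Delta x = R(KE) - R(KE_{cut})$ with $KE_{cut} = 10$ keV, which leaves a
terminal few-micron step and reproduces the observed two-steps-per-track
behaviour of default stepping. A user limit $\Delta\beta$ on the fractional
velocity change per step instead bounds
$\Delta\gamma = \gamma - (1-\beta^2(1-\Delta\beta)^2)^{-1/2}$, giving the
candidate step $\Delta l = m\,\Delta\gamma/(dE/dx)$; the step taken is
$\min(\Delta l, \Delta x)$. Two implementation choices matter and were made
deliberately:

* *The limit applies only above the Cerenkov threshold* ($\beta > 1/n_{max}$,
  ~53 keV in BGO). It is the Cerenkov process that imposes the velocity
  limit in stepwise toolkits, and the process is inactive below threshold.
  This detail is what reproduces the printed step-length scale: limiting
  all the way to the 1 keV cutoff would double the step count and halve the
  mean step length (0.10 µm instead of 0.205 µm at $\Delta\beta$ = 0.04%).
* *$\Delta l$ uses the collision (ionisation) stopping power*, while energy
  depletion along the step uses the total. With the total in the
  denominator the candidate step at $\Delta\beta$ = 30% falls 1% short of
  the range-based step and the plateau would onset just above 30%, against
  the observed behaviour; the ionisation table is also what the reference
  implementation queries for this purpose.

Energy is depleted through the range table (`ke_after_path`), so step
lengths always sum to the CSDA range and the mean track length is invariant
under $\Delta\beta$ by construction. The clock advances with the pre-step
velocity; electron transit times are picoseconds and negligible against
photon transport. Multiple scattering deflects the direction between steps
by a Gaussian polar angle of width
$\theta_0 = (13.6\,\mathrm{MeV}/\beta c p)\sqrt{x/X_0}$ (Highland, without
the logarithmic correction so that deflection variances add over
subdivided steps), with uniform azimuth. Tracking stops at 1 keV.

**Cerenkov emission.** The yield per mm is the Frank–Tamm integral
$\frac{2\pi\alpha}{hc}\int (1 - 1/(\beta^2 n^2(\varepsilon)))\,
d\varepsilon$ over the material's optical window, evaluated by trapezoid on
the dispersion grid with negative (sub-threshold) integrand clamped to
zero; for constant $n$ the trapezoid is exact, which the tests exploit. Per
step the photon count is Poisson. Two per-step modes exist:

* `interp` (default): the expectation is the step length times the
  pre/post-averaged yield and emission points are drawn with density
  proportional to the locally interpolated yield, making the expected count
  exactly additive under step subdivision;
* `pre`: the expectation uses the pre-step yield alone with uniform
  placement, and photons falling where the interpolated velocity is below
  threshold are discarded. This mirrors a toolkit that computes emission
  "from quantities known at the beginning of the step". For sub-micron
  steps the two modes agree to well under a percent; for a single
  range-length step the `pre` mode reproduces the characteristic downward
  bias of coarse stepping (about 17 → 14 photons per 511 keV interaction),
  which is why the coarse-stepping yield analyses use it.

Photon energies are sampled by rejection from
$1 - 1/(\beta^2 n^2(\varepsilon))$ with the envelope at $n_{max}$, and
directions lie exactly on the cone $\cos\theta = 1/(\beta n(\varepsilon))$
about the local electron direction. Scintillation (8200 photons/MeV,
480 nm Gaussian spectrum, 300 ns single exponential decay, isotropic, no
rise time or fast component) is available behind a decimation factor of 100
but is off in the headline analyses; its net effect on the Cerenkov
observables is negligible and it dominates runtime otherwise.

**Optical transport.** The crystal is a box with five polished faces backed
by a diffuse wrap and one grease-coupled face (n = 1.5) holding an ideal
photodetector (PDE = 1) at the crystal entrance — the front arrangement,
chosen because it amplifies the path-length differences under study.
Surfaces are resolved analytically: unpolarized Fresnel coefficients with
total internal reflection at every face; photons transmitted into the air
gap reach the wrap, survive it with probability 0.98 (per interaction), and
leave it Lambertian *in air*, re-entering the crystal through the
air→crystal interface with Fresnel acceptance and Snell refraction — so
re-entered directions are compressed into the ~27.7° refraction cone, a
consequence of treating the gap honestly rather than sampling a hemisphere
inside the crystal. Bulk absorption is exponential with a constant 3000 mm
length across the window (BGO transmits its own Cerenkov light well over
centimetre paths; the true wavelength dependence is not modeled — see
Limitations). Photons are detected when transmitted into the grease, and
declared trapped after 1000 boundary interactions (in a lossless rectangular
box, directions inside the total-internal-reflection cone of every face are
genuinely trapped). Detection time is the emission time plus path length
times $n_g/c$, with the group index $n_g = n + \varepsilon\,dn/d\varepsilon$
from the tabulated dispersion (a phase-index mode exists for sensitivity
checks).

**Analysis.** Step statistics use two-level averaging: the mean step length
is the mean over tracks of the within-track mean, the track length the mean
of the within-track sum — not pooled means, which differ whenever track
step counts differ. Per-event Cerenkov counts are histogrammed in unit bins
and fitted with a Gaussian by Levenberg–Marquardt least squares with
Poisson bin weights (`minpack.lm`); the fitted mean, not the sample mean,
is reported, with a sample-statistics fallback for degenerate inputs.
Directionality uses the x–z projection angle relative to the gamma axis in
36 bins of 10°, normalized to the maximum bin; the backward fraction is the
fraction of qualifying events within ±5° of 180°, and events lacking an
i-th photon are skipped, not zero-padded.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `delta_beta` | sweep, or `NA` | fraction | max velocity change per step; `NA` = range-based default |
| `ke_cut` | 0.01 | MeV | residual energy after a default range-based step |
| `cutoff` | 0.001 | MeV | tracking cutoff (far below the 53 keV Cerenkov threshold) |
| `k_shell_prob` | 0.8 | — | photoelectric K-shell share |
| optical window (BGO) | 320–800 | nm | bounds the Frank–Tamm integral; n from 2.36 to 2.07 |
| `absorption_mm` | 3000 | mm | constant bulk absorption length |
| `wrap_reflectivity` | 0.98 | — | diffuse wrap survival per interaction |
| `n_grease` | 1.5 | — | detector coupling index |
| `n_events` | 1000 | — | photoelectric events per run |

## What the generator emulates, and what it does not

The simulator *is* the data source: it emulates photoelectric recoil
generation, continuous slowing-down with $\Delta\beta$-limited stepping,
Frank–Tamm emission, and surface-resolved optical transport under a fixed
seed, at the study conditions (1000 events per run, the printed
$\Delta\beta$ sweep values, 511 and 1000 keV, BGO with the printed window).
It does not emulate: Compton interactions (photoelectric only, as in the
study design), delta-ray production (all inelastic loss is continuous; the
~53 keV threshold makes energetic secondaries rare), the exact
library-derived stopping powers of a full toolkit (analytic formulas carry
a stated ±15% on absolute lengths), measured-LUT surface reflectance
(replaced by the analytic polished+wrap model — the one deliberate physics
substitution), wavelength-dependent bulk absorption, or photodetector
electronics. Passing tests therefore validate the parameterization physics
and its internal consistency, not absolute agreement with any specific
toolkit build.

## Numerical choices

Log-spaced 200-point loss tables keep interpolation errors of ranges below
0.5% (asserted by a refinement test). Range inversion uses the same
monotone table, so `csda_range` and `ke_after_path` are consistent
round-trip to 0.1%. The Frank–Tamm trapezoid is exact for constant n and
agrees with closed forms to 1e-10; emission-point sampling inverts the
linear yield density in closed form. Rejection sampling of photon energies
caps at 10⁴ proposals (never reached in practice: the acceptance ratio is
bounded below by the band-mean over band-max of a positive density).
Gaussian fits start from sample moments. Degenerate inputs (zero-yield
steps, all-equal count histograms, vanishing x–z projections) are handled
explicitly and tested. Simulations are reproducible bit-for-bit given
`set.seed`; sweep run i uses master seed + i so runs are independently
reproducible.

Problem sizes were chosen so the full test suite and the acceptance script
each run in well under a minute of CPU: 1000-event runs for headline
statistics (matching the study design), 60–300 events for property and
sweep checks where only means at the few-percent level are needed.

## Known limitations

* Absolute length scales inherit the analytic stopping-power model; the
  0.42 MeV CSDA range is 0.334 mm against the reference 0.348 mm (−4%),
  comfortably inside the ±15% the substitution is documented to carry, and
  at 1 MeV the deviation grows (the unlimited-stepping mean step is ~24%
  above the reference 360 µm). Photon *counts* are insensitive to this
  because the yield integral and the range share the same $dE/dx$.
* The detected-photon timing of the fine-stepping run is the one headline
  number this model does not reproduce: with near-lossless constant
  absorption and a 0.98 diffuse wrap, forward-emitted photons survive the
  back-face round trip about as often (~91%) as backward photons reach the
  detector directly, so the mean transit settles near 0.28 ns instead of
  below 0.1 ns. Concentrating detection on the short direct paths would
  require the strong ultraviolet bulk absorption of real BGO (the
  Frank–Tamm spectrum is UV-heavy) and measured surface losses, both
  outside this model by design. The coarse-run transit (~0.36 ns vs ~0.3 ns)
  and every spatial observable are unaffected.
* TlBr optical constants are not tabulated here beyond a configurable
  ~2.5 flat dispersion over 440–800 nm, so TlBr photon counts are soft.
* The Highland model without its logarithmic term slightly overestimates
  very-small-step scattering; it was chosen for its additivity, which the
  track-length invariance relies on.
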