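---
title: "Models and methods behind putsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind putsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

putsim models photo-mediated ultrasound therapy (PUT): nanosecond laser
pulses synchronized onto the rarefaction phase of a 0.25 MHz ultrasound
burst so that the photoacoustic transient generated inside an absorbing
blood vessel tips a pre-existing sub-micron bubble over the cavitation
threshold. This vignette documents the models, the defaults and why they
were chosen, the numerical machinery, and what the synthetic-data
generators do and do not emulate.

## 1. The photoacoustic source

A blood vessel of diameter $d$ illuminated by a laser pulse much shorter
than the acoustic transit time $d/c$ is in *stress confinement*: the
absorbed energy density $\mu_a F$ converts to an initial pressure
$p_0 = \Gamma \mu_a F$ before the tissue can relax. `pa_waveform()`
represents the emitted transient as the classic bipolar (N-shaped) pulse
of width $d/c$ — the far-field signature of a cylindrical absorber —
smoothed by convolution with the Gaussian laser envelope (FWHM equal to
the pulse duration) and rescaled so its peak equals $p_0$. The exact
Bessel-integral solution of the cylinder problem differs from this
N-pulse in fine structure; for the purpose of superimposing a
short, bipolar tension spike onto the burst, the smoothed N-pulse
reproduces the morphology that matters (peak amplitude, width, zero
integral) at negligible cost.

Default absorber values are class values for whole blood at 1064 nm,
$\mu_a = 10\,\mathrm{cm^{-1}}$ and $\Gamma = 0.2$, giving
$p_0 = 0.2$ MPa per 100 mJ/cm². Both are plain arguments of
`vessel_absorber()` and should be overridden when measured values are
available. The observation point is the vessel axis, with no additional
geometric attenuation: the nucleus is taken to be co-located with the
source. Fluence at depth is an *input* (the package does no optical
transport); `fluence_from_energy()` only does the surface bookkeeping
$F = E/(\pi (d_\mathrm{beam}/2)^2)$.

## 2. Bubble dynamics

`simulate_bubble()` integrates the Keller–Miksis equation with
first-order liquid compressibility, a polytropic gas core in mechanical
equilibrium at $R_0$ ($p_{g0} = p_\infty + 2\sigma/R_0 - p_v$), surface
tension and Newtonian viscosity. The viscous contribution to the
radiation-damping term is moved to the left-hand side so the acceleration
stays explicit. The model family was chosen because it is the standard
single-bubble description for cavitation at these amplitudes; bubble
clouds, shells, thermal interior models and shock emission are out of
scope.

Default medium (`medium_properties()`): $\rho = 1000$ kg/m³,
$\sigma = 0.072$ N/m, $\kappa = 1.4$, $p_\infty = 101.325$ kPa,
$p_v = 2.33$ kPa, $c_0 = 1500$ m/s, $D = 2\times10^{-9}$ m²/s,
$C_0 = 0.75$ mol/m³ (air in water), saturation $C_i/C_0 = 1$. Viscosity
defaults to $2$ mPa·s: a 100-nm bubble in blood sits in the plasma phase
*between* red cells, so the effective microrheology at that scale is
plasma-like rather than bulk whole blood (3–4 mPa·s). All of these are
arguments, not constants.

### Numerics

The solver is an adaptive Dormand–Prince 5(4) scheme in compiled code
with a relative-error norm scaled to the current radius and wall speed
(`rtol = 1e-6` by default, with an absolute floor of $0.01 R_0$ on the
radius scale and 1 m/s on the velocity scale). Violent collapse is the
hard part: wall speeds approach the liquid sound speed, so $|\dot R|/c$
is clamped to 0.9 inside the bracketed Keller–Miksis factors, a hard
positivity floor at $10^{-3} R_0$ guards the radius, and if the error
target cannot be met at the minimum step ($10^{-16}$ s) the solver
accepts the best available estimate and counts the event (`nfloor` in
the trajectory diagnostics) instead of stalling. Output is sampled on a
uniform grid (64 samples per drive cycle by default) so spectra are
well-defined; integration lands on output instants exactly rather than
interpolating. The classic oracles pin the solver down in the test
suite: equilibrium drift $< 10^{-6}$, Minnaert-with-surface-tension
ringdown frequencies within 5% for 1–10 µm bubbles, Rayleigh collapse
time within 2%, and small-amplitude forced response within 5% of the
linear oscillator.

### Rectified-diffusion fate

Gas exchange is decoupled from the radial dynamics within a burst (the
bubble's gas content is fixed during integration) and evaluated
afterwards with the Eller–Flynn high-frequency cycle average
(`mass_flux()`):

$$\frac{dn}{dt} = 4\pi D R_0 C_0 \,\langle r\rangle
\left[\frac{C_i}{C_0} - \frac{p_{g0}}{p_\infty - p_v}
\frac{\langle r^{4-3\kappa}\rangle}{\langle r^4\rangle}\right],
\qquad r = R/R_0 .$$

The $r^4$ weighting (surface area × diffusion-shell thinning) is what
rectifies the exchange: episodes of large expansion contribute enormous
weight at low interior pressure. At $r \equiv 1$ the bracket reduces to
the quasi-static Epstein–Plesset rate, which is the static oracle in the
tests; with $\sigma = 0$, undriven and saturated, the flux is exactly
zero. Fate is the sign of this flux (`classify_fate()`): positive means
the exposure feeds gas into the bubble — treatment-relevant growth.

Decoupling is justified by scale: even a strongly driven 100-nm bubble
gains well under a percent of its gas content per burst, so the
trajectory computed at fixed mass is self-consistent; the growth the
flux predicts plays out over many bursts.

### The averaging window

Averages and spectra exclude transients. Without a photoacoustic pulse
the first 25% of the burst is discarded (configurable). With a PA pulse
the window opens half a drive cycle before the pulse arrival: the
pre-pulse cycles are the steady state to discard, and the pulse-triggered
response — the event the therapy is built on — is kept in full. A
mid-burst insertion (the default synchronization) therefore yields a
window of ~50 cycles at the default 100-cycle burst.

### Period doubling

A fixed-mass sub-micron nucleus at 0.25 MHz cannot period-double: it is
viscously overdamped at microsecond timescales (damping time
$\rho R_0^2/4\eta \sim 1$ ns), so every drive cycle starts from the same
state and the response is exactly period-1 — we verified this
numerically up to 2 MPa across the physically defensible parameter
range. Period doubling belongs to the *size regime the growing bubble is
driven into*: a bubble whose linear (Minnaert) resonance sits at half
the drive frequency (~26.5 µm at 0.25 MHz) oscillates subharmonically.
`classify_fate()` therefore labels a growing bubble
`PERIOD_DOUBLED_GROWTH` when its expansion maximum reaches that
subharmonically resonant radius, and confirms the label by simulating a
bubble of that destination size under the same drive and applying the
spectral criterion: amplitude at $f/2$ at least 10% (configurable) of
the amplitude at $f$, measured over the steady window with a Hann taper
on a whole-pairs-of-cycles segment so $f/2$ falls on a Fourier bin. An
alternation index of successive cycle maxima is computed alongside as a
cross-check. This "expanded sufficiently to period-double" reading is
the package's design choice for an inherently model-dependent label; the
expansion-maximum gate is what makes it discriminate plain explosive
growth (max $R \approx 16$–19 µm at 0.8 MPa) from period-doubled growth
(max $R \approx 34$ µm at 1.0 MPa).

### Thresholds and maps

`threshold_pressure()` bisects the drive PNP over simulate + classify
with a default tolerance of 0.01 MPa and a $[0, 2]$ MPa bracket,
reporting the bracket and fates rather than throwing when no flip exists
in range. `regime_map()` evaluates fates on a pressure × fluence grid
(default 21 × 21 over 0–1 MPa × 0–200 mJ/cm², ~35 s single-threaded at
the default 100-cycle bursts; the experimental burst is 500 cycles, and
the tests check fate labels are unchanged under tolerance refinement).
The destination-size subharmonic check depends only on the drive
pressure, so the map caches it per pressure column. Every stage is
deterministic: identical configurations give identical results
bit-for-bit.

The threshold at zero fluence is governed by the quasi-static
(adiabatic) Blake-type runaway of the nucleus plus the kinetics of
crossing the barrier within a rarefaction; the photoacoustic spike
lowers the measured threshold because its extra tension drives the
barrier crossing within its ~30 ns negative lobe. This is why the
threshold curve decreases with fluence and why the decrease steepens at
high fluence.

## 3. Active cavitation detection

`fit_baseline()` estimates per-pixel temporal mean and SD from the
zero-fluence stack; `detect_frame()` flags a frame when any unmasked
pixel exceeds $\mu + k\sigma$ ($k = 3$); `cavitation_probability()` is
the flagged fraction of frames, exactly. Design choices:

* **Per-pixel baseline** (default) rather than one pooled mean/SD,
  because B-mode speckle is spatially inhomogeneous; `global = TRUE`
  preserves the pooled reading.
* **Tube masking**: a supplied mask, or k-means clustering of the
  temporal-mean image into background/structure with a 2-px dilation.
* **Frame independence**: CP counts frames independently, which can
  overestimate when a bubble persists across consecutive frames; no
  run-length collapsing is applied, matching the statistic as defined.

## 4. Speckle-variance OCT-A

`speckle_variance()` computes the per-voxel population variance
($1/N_{rep}$ divisor, recorded in the output) across the repeated
B-scans; flow decorrelates between repeats and lights up, static tissue
cancels. `vessel_density()` is the mean OCT-A intensity within the
150–300 µm depth gate over the whole scan area — raw intensity, not a
binarized vessel mask, on linear-scale values. `percent_reduction()` and
`paired_compare()` (paired t-test, with degenerate zero-variance cases
reported rather than returning infinities) complete the treated/
untreated comparison. Axial gating converts µm to voxels through the
configurable pitch (default 3 µm/px).

## 5. What the generators emulate — and what they do not

`gen_bmode_stack()` produces background speckle, a bright static tube
wall (the structure the mask must remove), and Bernoulli-per-frame
bright events of configurable contrast (default 6σ) inside the lumen,
returning the ground-truth event indicator. Noise is **clipped** at 2σ
about the mean (Gaussian default, Rayleigh option): recorded B-mode
images are log-compressed into a finite dynamic range, so unbounded
tails never survive into the data, and the margin between the clip
boundary and the 3σ̂ threshold also absorbs the sampling error of
baseline statistics estimated from 100 frames. Without bounded noise the
any-pixel rule would fire on background alone in any usefully sized
region of interest — a property of the rule, not of the detector
implementation.

`gen_oct_series()` builds paired treated/untreated repeated-B-scan
volumes over an 8 mm × 8 mm extent: frozen tissue texture shared across
repeats (up to 0.015 SD noise), vessel segments within the 150–300 µm
band whose voxels are redrawn independently per repeat (maximal
decorrelation — flow speed is deliberately not parameterized), and a
treated series retaining an exact programmed fraction of vessel columns.
The programmed percent reduction is
$100(1 - \mathrm{retained})$; the pipeline recovers it with a small
(~1 pp) negative bias from the static-noise variance floor, well inside
the ±3 pp acceptance band used in the tests.

Neither generator is a physical image-formation model (no k-space
ultrasound speckle, no interferometry). Passing tests on them
demonstrates that the *estimators* implement their definitions and
recover programmed truth under realistic contrast and noise — not that
detection would meet the same sensitivity on clinical recordings, where
motion, persistence of bubbles across frames, and scanner processing
intervene. The in vivo headline numbers (45.20%/36.06% day-7 reductions,
43.5% histology) are used only as programmed ground truth for recovery
experiments; no deposited recordings exist to quantify from.

## 6. Problem sizes and reproducibility

Default problem sizes were chosen so a full desk-scale run stays
comfortable on one core: 100-cycle bursts for fate evaluation, 64 output
samples per cycle, 21 × 21 regime maps, 96 × 24 × 110-voxel OCT volumes
with 3 repeats, 100-frame B-mode stacks, and 20-seed recovery averages.
All stochastic entry points take explicit seeds and restore the caller's
RNG state; the ODE path has no randomness. `scripts/acceptance.R`
recomputes the threshold brackets, the period-doubling onset and the
OCT-A recovery from scratch against the installed package.

## 7. Known limitations

* Gas exchange is cycle-averaged, not coupled into the dynamics; the
  package classifies growth, it does not simulate the multi-burst growth
  trajectory to the destination size.
* The period-doubling label rests on the destination-size construction
  described above; a fully mass-coupled simulation over seconds of
  physical time would be needed to watch the subharmonic emerge in R(t)
  itself.
* Acoustic attenuation, focusing gains and standing waves are not
  modeled; pressures are taken as given at the target (the study's
  calibrated 0.91/1.36 MPa top/bottom values are inputs of this kind).
* The detection statistic inherits the frame-persistence overestimate of
  CP by construction.
* Synthetic OCT volumes are pre-registered; no motion correction exists
  in the pipeline.
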