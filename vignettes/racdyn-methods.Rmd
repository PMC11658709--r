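---
title: "Modeling Rac1 membrane-cytoplasm cycling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Rac1 membrane-cytoplasm cycling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racdyn)
```

## The model

`racdyn` implements a mass-conserving reaction-diffusion description of the
small GTPase Rac1 shuttling between the plasma membrane and the cytoplasm
of an amoeboid cell, coupled to two partners: a GAP that deactivates
membrane-bound Rac1-GTP and extracts it, and the effector DGAP1, which
binds the membrane independently and is released through complex formation
with Rac1-GTP. The cell edge is a ring of perimeter $L$; all species are
linear densities $\rho(x,t)$ with $x \in [0, L)$ periodic.

The condensed model tracks seven species. Cytoplasmic inactive Rac1
($\rho_r$), GAP ($\rho_g$) and DGAP1 ($\rho_d$) diffuse with coefficients
$D_r$, $D_g$, $D_d$; the membrane species — active Rac1 ($\rho_R$), free
DGAP1 ($\rho_D$) and the two complexes ($\rho_{RG}$, $\rho_{RD}$) — do
not. The reactions are mass-action:

* Rac1 binding + activation in one lumped step with autocatalytic
  recruitment, flux
  $\rho_r (1 - \rho_R/\rho_{R\max})(k_1 + k_{11}\rho_R + k_{12}\rho_{RG})$.
  The saturation factor caps the membrane density at $\rho_{R\max}$.
* GAP capture of Rac1-GTP ($k_2 \rho_R \rho_g$) and dissociation of the
  complex with release of both proteins ($k_{3a}\rho_{RG}$).
* DGAP1 membrane binding with its own saturation $\rho_{D\max}$ and
  cooperative recruitment
  $\rho_d (1 - \rho_D/\rho_{D\max})(k_4 + k_{41}\rho_R + k_{42}\rho_{RG})$,
  complex formation $k_5 \rho_R \rho_D$, and two dissociation routes:
  DGAP1-only release ($k_{6a}$) or release of both partners ($k_{6b}$).

Because every reaction moves molecules between pools of the same protein,
the totals $N_\mathrm{Rac1}$, $N_\mathrm{GAP}$ and $N_\mathrm{DGAP1}$ are
conserved exactly; copy numbers enter the dynamics only through the
linear totals $N/L$.

The extensive model (`extensive_rhs()`) adds membrane-bound *inactive*
Rac1 ($\rho_m$), splitting binding from GEF activation ($k_\mathrm{act}$),
with reverse release ($k_{-1}$, $k_{-4}$), an alternative Rac1-GAP route
that leaves inactive Rac1 on the membrane ($k_{3b}$), and two
complex-dissociation routes that retain DGAP1 on the membrane ($k_{6c}$,
$k_{6d}$). Setting the extra pathways to zero reproduces the condensed
reaction set for six of the seven shared species exactly; the binding flux
itself passes through $\rho_m$, so the condensed lumped step is recovered
in the fast-activation limit $k_\mathrm{act} \to \infty$, not by
$k_\mathrm{act} = 0$.

Defaults for every constant come from the published parameter table
(`baseline_params()`), with the published per-pattern presets exposed by name.

## Steady state and linear stability

Spatially uniform fixed points solve four independent reaction balances
plus the three conservation constraints. `solve_homogeneous_steady_state()`
reduces this system semi-analytically: given $\rho_R$, the GAP
partitioning is linear; the DGAP1 balance becomes a monotone scalar
equation in $\rho_D$ on $[0, \rho_{D\max})$, solved by bisection; the
remaining Rac1 conservation residual is a bracketed scalar function of
$\rho_R$ on $(0, \rho_{R\max})$. Monotonicity makes the root unique and
the solver free of starting-point tuning; a 50-start least-squares probe
in the test suite confirms uniqueness at the baseline. When the total
DGAP1 density exceeds $\rho_{D\max}$ and $\rho_R$ is small, the membrane
DGAP1 balance has no root below saturation; such trial values are treated
as lying below the Rac1 root so the bracket survives (this regime is
exercised by the published high-DGAP1 stationary patterns). Note that
saturation bounds only the membrane pools, so parameter sets with
$N/L$ above a saturation density are legitimate — the cytoplasm holds the
excess.

Perturbations $\delta\rho \propto e^{\sigma t + iqx}$ yield the
eigenvalue problem $\sigma_q \delta\rho = (J - q^2 \mathbb{D})\delta\rho$
with the analytic $7\times7$ Jacobian $J$ (`rac_jacobian()`, verified
against numerical differentiation) and the diagonal diffusion matrix.
On the ring, $q = 2\pi n/L$. Three eigenvalues vanish identically at
$q = 0$ (one per conservation law); they are excluded from
classification. A mode is unstable when its leading real part exceeds
`zero_tol` ($10^{-9}$); unstable modes are oscillatory (Hopf) when the
leading eigenvalue has nonzero imaginary part and stationary (Turing)
otherwise, with ties in the real part broken toward larger $|\mathrm{Im}|$.

The marginal wavenumber $q_m$ treats $q$ as continuous: the leading
growth rate is scanned over 400 points and the sign change bisected to
relative $10^{-8}$. The traveling-wave speed follows from matching the
growth ansatz to a co-moving wave: $v = \mathrm{Im}\,\sigma(q_m)/q_m$,
using the eigenvalue branch that crosses zero (a nearest-neighbour
continuity check against $0.999\,q_m$ guards against branch switching;
spectra at $\pm q$ are conjugate, so $|v|$ is reported). Mode thresholds
follow as $L_{n,\min} = 2n\pi/q_m$ with linear total densities held fixed
as $L$ varies (the natural convention in a mean-field model where only
$N/L$ matters; holding $N$ fixed instead rescales every total
simultaneously and mixes two effects).

Sensitivities of the wave speed use one-sided finite differences with a
default relative step of $+1\%$ (the source material does not state its
step); a step-halving test keeps $|S(1\%) - S(0.5\%)| < 0.05$ for all
reported parameters. Varying a saturation density rescales its binding
constants proportionally ($k = k' \rho_{\max}$ with the intrinsic $k'$
fixed), and "total" parameters vary $N$ at fixed $L$.

## Ring simulations

The spatial operator is the periodic three-point second difference on
100 uniform points (the discretization used for the published results;
a refinement test doubles it and finds period shifts below 2%). The
resulting 700 (condensed) or 800 (extensive) stiff ODEs are integrated
with the sparse-BDF solver (`deSolve::ode`, method `lsodes`) at relative
tolerance $10^{-8}$ and absolute $10^{-10}$, sampled every 1 s by
default (2 s in the long test runs). Species totals are monitored: drift
beyond $10^{-4}$ relative aborts, and all shipped runs stay below
$10^{-6}$ (in practice near machine precision, since the semi-discrete
reaction terms conserve each group identically and the stencil
telescopes). Densities are validated non-negative up to solver
undershoot ($-10^{-12}$ floored to zero; anything larger aborts).

Two initial-condition families are provided. `perturbed_steady` applies
white Gaussian noise at a prescribed SNR (30 dB default, the level the
published transition studies used), clips negatives and rescales each
conservation group so totals are exact. `seeded_pattern` superposes a
chosen Fourier mode on $\rho_R$ (mass drawn from $\rho_r$) plus a
phase-lagged copy at half amplitude on $\rho_{RG}$: a pure cosine seed is
mirror-symmetric and the dynamics preserve that symmetry, so rotating
solutions would be unreachable from it; the lag ($\pi/3$ by default)
breaks the symmetry. Seeded inits matter for marginally stable parameter
points whose patterns are reachable only at finite amplitude.

### Pattern classification

`classify_pattern()` operationalizes the visual taxonomy. After
discarding a transient (callers use run-specific values; the long-run
default recommendation is the larger of 2000 s and five estimated
periods), the dominant spatial mode $n$ is read from the time-averaged
spatial power spectrum and its complex amplitude $c_n(t)$ tracked:

* homogeneous: spatial contrast (mean over time of the angular sd/mean)
  below 0.02;
* traveling: the unwrapped phase of $c_n$ rotates by at least $\pi$ over
  the record while the amplitude never collapses
  ($\min|c_n|/\max|c_n| \ge 0.3$); the period is $2\pi$ over the phase
  rate;
* standing: the amplitude collapses periodically and the mean temporal
  autocorrelation of the angular fluctuations drops below $-0.3$ (the
  half-period anticorrelation $A(0, T/2) < 0$); the period is twice the
  first trough lag;
* stationary: persistent contrast without temporal decorrelation.

The thresholds (0.02 contrast, $\pi$ rotation, 0.3 collapse) are
implementation constants, not results; they are exercised against
constructed harmonics and against simulation output in the tests.
`transition_run()` applies the classifier over sliding windows and
flags class changes and direction reversals (sign flips of the phase
rate between traveling windows, tracked across intervening windows).

## Disk simulations

The two-dimensional solver carries only the Rac1-GAP cycle, the part of
the model the 2D verification exercised. A disk of radius $R$ is split
into $n$ rings $\times\ m$ angular segments (default $30 \times 100$;
the published-figure checks use $20 \times 60$, and doubling changes no
classification). Diffusion uses the conservative flux form of the polar
Laplacian — radial fluxes through ring boundaries weighted by boundary
lengths and segment areas, plus the angular second difference — so the
disk integral is conserved to round-off by construction; the inner
boundary has zero flux through $r = 0$.

Membrane exchange enters the outermost ring as the radial flux
$J_{n+1/2,j}$ built from the same mass-action terms with primed rate
constants $k' = k\,\rho^{1D}/\rho^{2D}$ (`convert_rates()`), reflecting
the change from per-length to per-area cytoplasmic densities. The
membrane ODEs split the same fluxes between $\rho_R$ and $\rho_{RG}$, so
cytoplasm + membrane totals are conserved exactly. The GAP flux is not
printed in the source material; it is constructed by exact analogy with
the Rac1 flux ($k_2'$ capture, $k_{3a}$ release), the only form that
conserves GAP.

### Copy-number accounting in the published disk runs

With the published primed constants, reading the quoted $N_\mathrm{Rac1}$
(7600 traveling / 6900 standing) as the all-pool total places both runs
in a regime whose unique uniform state is linearly stable with margin
($\mathrm{Re}\,\sigma \approx -0.03\,/\mathrm{s}$ for every angular
mode): every perturbation we tried — noise, localized bumps, empty
membrane loading, mapped 1D waves — decays, at both grid resolutions.
The oscillatory window of the model sits at all-pool totals of roughly
8600–9600, offset from the quoted values by almost exactly the Rac1 mass
sequestered in membrane Rac1-GAP complexes
($\rho_{RG}^* \times 2\pi R \approx 1950$). Reading the quoted numbers
as *free* Rac1 — cytoplasmic plus uncomplexed membrane Rac1-GTP — maps
7600 and 6900 into that window and reproduces the published sequence:
traveling waves at the higher value, standing waves at the lower one.
`rac_params2d()` therefore exposes `rac1_accounting = c("free", "total")`
with `"free"` as the default for this workflow; the choice is a
documented reading of the published copy numbers, not a fitted quantity.
Because growth rates in the window are $O(10^{-3})/\mathrm{s}$, the disk
runs start from the seeded mode-1 perturbation described above rather
than from noise.

## Kymograph analysis

The measurement-side tools mirror a confocal-microscopy pipeline
operating on intensity matrices $I(\Phi, t)$ over angular position and
time.

* `smooth_kymograph()`: cubic smoothing splines along each axis, the
  spatial axis wrapped by one period on each side. The smoothing
  parameter of the original pipeline is unpublished, so quantitative
  tests run on unsmoothed or synthetically constructed data; the default
  `spar = 0.5` attenuates a clean harmonic by under 2%.
* `autocorrelogram()`: $A(\Delta\Phi, \Delta t)$ with the fluctuation
  defined against the *angular* mean per time point (the printed
  definition), spatial lags wrapped, temporal lags truncated,
  normalized so $A(0,0) = 1$. Pure traveling and standing harmonics
  reproduce their closed forms $\cos(\Delta\Phi - \omega\Delta t)$ and
  $\cos\Delta\Phi\,\cos\omega\Delta t$ to high accuracy.
* `pearson_full()` / `sliding_pearson()`: element-wise Pearson
  correlation of two co-registered matrices over the first 120 s and
  over sliding 10 s windows — the `corr2` convention, no resampling.
* `pca_align()`: the two-channel matrices are stacked ($2n_t \times m$),
  each row standardized, and the $m$ columns treated as points in
  $2n_t$-dimensional space. Two conventions are deliberately fixed by
  an idempotence requirement: the projections dot the raw standardized
  columns with the principal axes (no re-centering of the column cloud),
  and the shift $\Delta t_j = -T\varphi_j/2\pi$ is applied as a
  displacement $S(t) = I(t - \Delta t_j)$. Under this reading, aligned
  columns re-projected on the axes concentrate at one phase (circular
  spread below 0.1 rad on clean waves); under the alternatives they
  scatter uniformly. The period comes from zero crossings of the first
  principal axis read as a time series (spectral-peak fallback below
  four crossings).
* `phase_portrait()`: orientation from the signed shoelace area of the
  closed $(x, y)$ trajectory; positive = counterclockwise.
* `psd_noise()`: square-root variance stabilization (matched to the
  variance-proportional-to-mean noise of photon-limited detection),
  4th-order high-pass Butterworth at 0.15 cycles per angular grid step
  applied with zero-phase forward-backward filtering on a triple-wrapped
  copy of each row (the ring is periodic; filtering the wrapped copy
  removes edge transients that would otherwise leak stop-band power),
  then the single-sided spatial PSD $\tfrac{2}{N}|\mathrm{FFT}|^2$
  averaged over time. "Cycles per unit length" is taken as cycles per
  grid step because the filter acts on the index-sampled axis; the
  result carries both that scale and cycles per micrometre.
* `interpolate_to_grid()`: periodic linear interpolation of irregular
  per-frame angular samples onto the uniform grid, the preprocessing the
  noise analysis assumes.

## Synthetic data

`synthetic_spec()`/`generate_pair()` produce two-channel kymograph pairs
with known ground truth: traveling/standing/stationary/homogeneous/random
patterns of chosen mode order and period, a channel-2 phase offset
($\pi$ = anti-correlated, the typical experimental relation), noise that
is Gaussian or variance-proportional-to-mean (the latter justifying the
square-root transform upstream), SNR calibration (realized SNR within
20% of spec), and optional jittered angular sampling followed by
interpolation, emulating contour-tracking output. The stationary profile
is a raised-cosine enriched domain repeated `mode_order` times, mimicking
the single-domain polarized state. Default period 190 s and channel
offset $\pi$ follow the typical measured traveling-wave cycle; frame
interval 1 s matches seconds-scale movies.

What the generator does *not* emulate: cell-shape deformation, probe
bleaching, detector gain statistics beyond the variance-mean
proportionality, or spatially correlated biological noise. Passing the
recovery tests therefore demonstrates the analysis pipeline's
correctness on data with the assumed statistical structure, not its
robustness to every property of live-cell recordings.

## Known limitations and open points

* The condensed/extensive equivalence at the published matched copy
  numbers ($N_\mathrm{Rac1} = 9200$, $N_\mathrm{GAP} = 880$,
  $N_\mathrm{DGAP1} = 1500$, $k_{11} = 5\times10^{-3}$) does not fully
  reproduce here: the extensive steady state is marginally *stable*
  (leading mode-1 growth rate $-1.5\times10^{-3}/\mathrm{s}$), noise
  inits decay, and the finite-amplitude attractors we find are
  standing-type (period $\approx 258$ s, within 10% of the condensed
  283 s) or stationary depending on the seed — never traveling. Both
  retention-pathway configurations ($k_{6c} = k_{6d} = 0.3$ and $0$) were
  examined; with zero the point has no pattern attractor at all, so the
  listed values are the default. The corresponding acceptance test is
  left failing rather than weakened.
* The simplified Rac1-GAP diffusion scan reproduces the published
  qualitative structure with $D_g$ varied at small fixed $D_r$
  (Turing at low GAP diffusion, a narrow mixed band, an oscillatory
  band for intermediate $D_g$, stability at high $D_g$); the printed
  axis annotation appears to swap the two coefficients.
* Problem sizes used by the shipped tests — 100-point rings (200 for the
  refinement check), $20\times60$ disks, records of a few thousand
  seconds — are the package's verification scale; they match the
  published discretization for the ring and are convergence-checked for
  the disk.
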