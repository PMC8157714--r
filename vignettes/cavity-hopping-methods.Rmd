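---
title: "Methods: water transport in viscous saccharide matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water transport in viscous saccharide matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitydiff)
```

## The scientific problem

When an aqueous droplet of a large organic solute (a saccharide, say) dries,
the solute concentrates until the matrix becomes ultra-viscous or glassy
(viscosities of 1e9 to 1e12 Pa s). The Stokes-Einstein (SE) relation

$$D = \frac{C\,k_BT}{\eta\,a}$$

predicts that the diffusion coefficient of any tracer falls inversely with
viscosity. For water — a tracer much smaller than the matrix molecules — this
prediction fails by many orders of magnitude: water keeps moving through a
matrix that is, rheologically, nearly solid. The failure is often summarized
by a fractional scaling $D \propto \eta^{-\alpha}$ with $\alpha < 1$.

`cavitydiff` implements the complete computational chain for quantifying this
behaviour and for explaining it mechanistically:

1. a spherical-shell Fickian model of droplet size response to steps in
   relative humidity (RH), and inverse fitting of the composition-dependent
   water diffusivity $\log_{10} D_w(a_w)$;
2. KWW (stretched-exponential) characterization of response functions;
3. SE predictions, divergence quantification, and fractional-exponent fits
   against an independently parameterized viscosity axis;
4. molecular-trajectory analysis of the *cavity hopping* mechanism: MSD
   diffusion coefficients, Gaussian hidden Markov state models (HMMs) with
   relaxation timescales, potentials of mean force (PMFs) by Boltzmann
   inversion, transition-state-theory (TST) barriers and hop statistics;
5. grid-based free-volume fractions of packed molecular configurations;
6. synthetic-data generators providing every input class with known ground
   truth, so each stage is testable by parameter recovery.

## Units and constants

Molecular-scale quantities use nm, ps/ns and $k_BT$; the droplet model uses
SI (m, s, kg). Diffusion coefficients are always reported in m$^2$ s$^{-1}$
(1 nm$^2$/ps = 1e-6 m$^2$/s). See `cavity_constants()`.

## The shell model

The droplet is discretized into concentric shells of **equal solute mass**,
so shells thin but never vanish as drying concentrates the solute. Each
explicit time step:

* water mass fraction, activity $a_w(w)$, density and shell geometry are
  recomputed;
* water moves between adjacent shells with a flux proportional to the
  diffusivity evaluated at the interface activity, the interface area, and
  the radial concentration gradient;
* the droplet surface is held at instantaneous equilibrium with the gas
  ($a_w = \mathrm{RH}/100$), imposed as a Dirichlet value at exactly $r = R$
  through a half-cell flux — liquid-phase diffusion is assumed rate-limiting,
  so there is no gas-side resistance;
* the time step obeys a diffusive stability bound (safety factor 0.4) and is
  halved automatically if a negative water mass would result.

The scheme is written in flux form, so water conservation holds to rounding:
the solver reports an audit of (interior change − boundary flux), typically
below 1e-13 relative. In the dilute, constant-$D$ limit the model reproduces
the classical sphere-sorption series $M(t)/M_\infty = 1 - (6/\pi^2)\sum
n^{-2} e^{-n^2\pi^2 Dt/r^2}$ to a few parts in a thousand. Outside that limit
(large RH steps) the series' fixed-boundary assumption breaks down — the
droplet radius changes by tens of percent — and the series is no longer the
right reference; the tests respect that validity domain.

**Activity model.** Measured water-activity data are not shipped; a
single-parameter monotone stand-in $a_w = w\,e^{A(1-w)^2}$ (water mass
fraction $w$, default $A = -1$, saccharide-like negative deviation) with
ideal volume additivity for density (water 997, amorphous saccharide
1580 kg m$^{-3}$) closes the model. Errors in this stand-in are absorbed
into the fitted $D_w(a_w)$ coefficients, exactly as measurement-driven
implementations absorb activity-data error.

**Inverse fitting.** `fit_diffusivity()` minimizes the summed squared
residual between forward solves and all response curves simultaneously over
the polynomial coefficients of $\log_{10} D_w(a_w)$ (default order 3, enough
for the smooth monotone curves seen in practice without over-fitting six
transitions). The start point comes from per-curve KWW time constants via
$D_\mathrm{eff} = r_0^2/(\pi^2\tau)$; Nelder-Mead refines. Identifiability
requires curves spanning distinct $a_w$ bands; a narrow band with order > 0
is refused, naming the unconstrained coefficients. The probed $a_w$ range is
stored as the validity window: $D_{w,\mathrm{org}} = 10^{c_0}$ (the $a_w \to
0$ intercept) is an extrapolation and is the hardest quantity — parameter
recovery tests hold it only to within a factor of 2 at realistic noise.

## KWW characterization

`fit_kww()` fits $c + (1-c)\exp[-(t/\tau)^\beta]$ by multi-start
least squares over a $\beta$ grid (stretched-exponential fits are rife with
local minima). $\beta = 1$ is a single exponential; activity-dependent
diffusivity during drying produces $\beta < 1$. Curves covering less than
80% of their fitted total change are flagged as incomplete relaxations (the
glassy regime), not errors.

## Stokes-Einstein divergence

The SE constant defaults to stick boundary conditions, $C = 1/(6\pi)$, with
slip $1/(4\pi)$ selectable; the water hydrodynamic radius defaults to 0.1 nm
(molecular diameter 0.2 nm). Divergence is reported in orders of magnitude,
$\log_{10}(D_\mathrm{meas}/D_\mathrm{SE})$. The fractional exponent is the
negative slope of a least-squares line in $(\log_{10}\eta, \log_{10}D)$ —
all regression is in log space because the data span ~12 decades of
viscosity — with residual-bootstrap uncertainty. `build_table()` joins the
$D(a_w)$ and $\eta(a_w)$ parameterizations on a common activity grid; rows
outside either validity range are flagged, never silently extrapolated.

## Cavity hopping analysis

**MSD.** Time-averaged MSD over strided sliding origins; $D$ = slope/6 in
the fit window (default 1–10% of the trajectory — long enough to clear the
caging regime, short enough that the estimator retains many independent
origins). Only unwrapped coordinates are accepted; wrapped input raises an
error rather than silently corrupting $D$. A log-log slope below 0.8 flags
sub-diffusive data (the value is still reported). Uncertainty by block
averaging over trajectory thirds.

**HMM.** Isotropic Gaussian emissions per state (cavities are compact
interstices; anisotropy deferred), trained by Baum-Welch EM with k-means
initialization and multiple restarts (a diffuse "background" state swallowing
several cavities is a real local optimum otherwise). Relaxation timescales
are implied timescales $t_i = -\tau_\mathrm{lag}/\ln\lambda_i$ of the
transition matrix — *joint* relaxation processes, deliberately not pairwise
hop times. The "Bayesian" 95% intervals are a parametric bootstrap over the
fitted model, a documented surrogate for a full posterior sampler. State
count selection trains on the first 70% of frames and scores held-out
log-likelihood on the last 30%; an extra state must earn at least 0.1 nats
per held-out frame (≈ 10% likelihood ratio per observation) — this is the
package's operational version of "a cavity is where the tracer has a
significant lifetime", and near-ties are flagged, with the smaller count
preferred.

**PMF.** $\mathrm{PMF} = -k_BT\ln P$ from a 2-D position histogram (yz
projection by default), gauge-fixed so the sampled minimum is zero; empty
bins are masked, never zero-filled.

**Frozen-matrix probe.** The fluctuating landscape is frozen at snapshot
times (default 1 ns apart), the tracer samples each rigid snapshot, and
consecutive PMFs are compared by mean |ΔPMF| over co-sampled, well-sampled
bins (≥ 100 counts, Jaccard overlap reported). A static landscape gives only
the shot-noise floor; a fluctuating one a significantly larger change.

**TST.** $k = \nu_0 e^{-\Delta G/k_BT}$ with $\nu_0$ defaulting to $k_BT/h$
(≈ 6.25e3 ns$^{-1}$ at 300 K). The prefactor is configurable because it is
rarely stated in applications; the default is validated only by consistency:
barriers of 6.4 ± 1.3 $k_BT$ map to hop frequencies of ~3–37 ns$^{-1}$,
inside the 1–50 ns$^{-1}$ band typical of water in a glassy saccharide.

**Hop statistics.** Hops are counted on a dwell-filtered Viterbi path:
excursions shorter than `min_dwell` (default 2 frames) are absorbed into the
surrounding state in a single linear pass, suppressing recrossing noise.
Return-trip fraction is the share of hops whose next hop goes straight back.

**Autocorrelation.** Normalized autocovariance of the displacement from the
mean position, summed over coordinates; the decorrelation time is the first
1/e crossing (interpolated). If no crossing occurs within the sampled lags
(default n/5) the value is censored and reported as a lower bound — this is
what happens for drifting, non-stationary input.

**1 ns slices.** `slice_and_model()` re-selects and refits an HMM per slice
(default 1 ns, an upper bound on matrix reorganization, so each slice sees a
quasi-static cavity landscape).

## Free volume

Occupied fraction by insertion on a regular grid of cell-center points: a
point is occupied iff within the van der Waals radius of any atom under the
minimum-image convention. Each atom visits only its own grid neighbourhood,
so cost is linear in atoms; the arithmetic is bit-identical to the
brute-force all-pairs oracle used in tests. Default spacing 0.05 nm with a
guard `spacing <= min(radius)/2`; halving the spacing moves the fraction by
< 0.3% absolute on the test packings. Raw geometric vdW occupancy is the
default (probe radius 0); a probe-radius option inflates radii for
water-accessible free volume, flagged as an extension rather than the
headline definition.

## What the synthetic generators emulate — and what they do not

* `gen_response_curve()` forward-simulates the shell model from a known
  $D_w(a_w)$ and adds multiplicative Gaussian noise (default 0.5%, typical of
  optical sizing). It emulates ideal single-droplet RH-step experiments: no
  wait-time path dependence, no crystallization, no gas-phase resistance.
* `gen_langevin_trajectory()` integrates overdamped Euler-Maruyama dynamics
  in a sum of inverted Gaussian wells (smooth, analytic gradients — any
  smooth multi-well form is admissible since real cavity PMFs are empirical)
  under periodic boundaries, with $D_0 = 1/\gamma$ and energies in $k_BT$.
  Inertia is neglected: water in a 1e9–1e12 Pa s matrix is strongly
  overdamped. Matrix reorganization is a sinusoidal depth modulation with a
  single decorrelation timescale (default 1 ns, the observed scale of
  saccharide position decorrelation; the sinusoid period is four times the
  timescale, since a sine first decorrelates after a quarter period). One
  timescale is a simplification: real matrix fluctuations are aperiodic and
  heterogeneous, so a green test here shows the analysis chain recovers a
  known stationary/modulated landscape, not that one timescale describes a
  real matrix.
* `gen_two_state_jump()` uses the exact two-state propagator $e^{Q\,dt}$, so
  HMM estimates can be checked against closed forms ($t = 1/(k_{12}+k_{21})$,
  occupancies $k_{21}/(k_{12}+k_{21})$, …) with no discretization error.
* `gen_sphere_packing()` provides Poisson placements (closed-form occupied
  fraction $1 - e^{-\rho\frac43\pi r^3}$) and random sequential addition
  (feasible below packing fraction 0.35). These are stand-ins for vdW
  snapshots of amorphous matrices: they reproduce the *measurement problem*
  (grid occupancy under PBC), not saccharide structure.

Single tracer only; no water-water interactions, no force fields, no
attempt at realistic conformers.

## Numerical choices

* Shell solver: explicit flux-form stepping, safety factor 0.4, automatic dt
  halving on negative mass, step budget with diagnostics. Chosen over
  implicit schemes for conservation auditability.
* Equal-solute-mass shells (not equal thickness): resolution follows the
  solute as drying concentrates it, and no shell ever empties.
* Response normalization: size(t)/size(0), decaying (or growing) to the
  equilibrium asymptote; the KWW form fits the asymptote freely so both
  drying and humidifying steps are handled.
* EM: convergence at 1e-7 relative log-likelihood, cap 200 iterations,
  empty states trigger a refit with one fewer state (warning).
* Timescales use eigenvalue moduli; eigenvalues within 1e-12 of 0 or 1 are
  dropped rather than reported as spurious infinities.
* The PMF gauge (min sampled bin = 0) makes PMF *differences* the only
  meaningful quantity, which is what all comparisons use.
* Tie-break in state-count selection: smallest count within 0.1 nats/frame
  of the best held-out score.

## Known limitations

* The activity and viscosity parameterizations are parametric stand-ins;
  with measured data the same interfaces apply unchanged.
* $D_{w,\mathrm{org}}$ is an extrapolation below the probed activity range
  and is only constrained to a factor-of-order-unity at realistic noise.
* The HMM assumes compact (Gaussian) cavities; landscapes where transit
  regions carry substantial Boltzmann mass are better described with an
  explicit background state, which the likelihood will select on its own.
* Hop counting depends on `min_dwell`; the jump-diffusion identity
  $D = k d^2/6$ holds within a factor of ~2 only when hops are uncorrelated
  and the dwell filter is matched to the within-cavity relaxation time.
* No cavity connectivity/percolation analysis is attempted — only volume
  fractions.
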