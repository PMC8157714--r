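# cavitydiff

Water transport in viscous aqueous–organic (saccharide) matrices: droplet-scale
Fickian modelling, Stokes–Einstein divergence analysis, and molecular-scale
cavity-hopping statistics — with synthetic-data generators that make every
stage testable by parameter recovery.

## The problem

As an aqueous droplet of a large organic solute dries, the matrix viscosity
climbs from ~1e-3 Pa s (dilute solution) to ~1e12 Pa s (amorphous glass). The
Stokes–Einstein relation

    D = C · k_B T / (η · a)

predicts that a tracer's diffusion coefficient falls in proportion to 1/η.
For water — a molecule far smaller than the matrix molecules — this fails
spectacularly: near the semi-solid threshold (1e4 Pa s) water can diffuse
several orders of magnitude faster than the continuum prediction, a
decoupling often summarized by a fractional scaling D ∝ η^(−α), α < 1.
Mechanistically, water does not move through a solvent continuum at all: it
sits in transient cavities of the molecular packing and makes discrete,
thermally activated hops as the matrix reorganizes.

`cavitydiff` is for researchers who quantify this behaviour from droplet
RH-step experiments and/or single-molecule trajectories:

* **Droplet scale** — a conservative spherical-shell Fickian solver
  (`solve_shell_diffusion`), KWW stretched-exponential characterization
  (`fit_kww`), and simultaneous inverse fitting of the activity-dependent
  water diffusivity log10 D_w(a_w) from many RH transitions
  (`fit_diffusivity`), including the dry-matrix intercept D_w,org.
* **Divergence** — SE predictions (`se_predict`), divergence in orders of
  magnitude (`divergence_orders`), matched D–η tables on an independent
  viscosity axis (`build_table`), fractional-exponent fits
  (`fit_fractional_exponent`).
* **Molecular scale** — MSD diffusion coefficients (`msd_diffusion`),
  Gaussian hidden Markov state models with relaxation timescales and
  bootstrap credibility intervals (`fit_hmm`, `select_n_states`,
  `slice_and_model`), Boltzmann-inversion PMFs (`compute_pmf`,
  `frozen_matrix_probe`), transition-state-theory barriers (`tst_barrier`,
  `tst_rate`), hop statistics (`hop_statistics`), matrix decorrelation times
  (`position_autocorrelation`), and grid-based free-volume fractions
  (`occupied_fraction`, `free_volume_series`).
* **Synthetic data** — `gen_response_curve`, `gen_langevin_trajectory`,
  `gen_two_state_jump`, `gen_sphere_packing`: every input class with known
  ground truth (exact two-state kinetics, closed-form Poisson void fractions,
  Boltzmann-checkable well landscapes).

See `vignettes/cavity-hopping-methods.Rmd` for the models, assumptions,
numerical choices and limitations.

## Worked example

Recover a diffusivity parameterization from three synthetic RH-step curves,
quantify the SE divergence, and analyse a hopping trajectory:

```r
library(cavitydiff)

truth <- d_parameterization(c(-15, 5, -1, 1))   # log10 D_w(a_w), ground truth
curves <- lapply(list(c(70, 50), c(50, 30), c(30, 10)), function(s)
  gen_response_curve(truth, s, r0 = 4e-6, noise_sd = 0.005, seed = 7,
                     n_shells = 30, n_times = 120))

fit_kww(curves[[3]])
#> <kww_fit> tau = 168.1 s, beta = 0.576, asymptote = 0.8620, rms = 0.0045

fit <- fit_diffusivity(curves, order = 1, n_shells = 30)
fit
#> <d_parameterization> order 1, D_w,org = 1.03e-15 m^2/s, valid a_w [0.1, 0.7]
#>   log10 D coefficients: -14.986 4.7247

tab <- build_table(fit, eta_parameterization(c(9, -12)), seq(0.1, 0.7, 0.1))
fit_fractional_exponent(tab)
#> <fse_fit> alpha = 0.394 (se 0.000, 95% CI 0.394-0.394), n = 7, ...
divergence_orders(tab$D_m2s[1], se_predict(tab$eta_Pas[1]))
#> 4.9   # orders of magnitude faster than Stokes-Einstein at a_w = 0.1

tr <- gen_two_state_jump(k12 = 1, k21 = 4, dt = 1, n_steps = 2e5, seed = 7)
m <- fit_hmm(tr, n_states = 2, lag = 10, n_bootstrap = 30, seed = 8)
m
#> <markov_model> 2 state(s) at lag 10 ps, loglik 51354.5
#>   relaxation timescales (ns): 0.1856       # truth: 1/(k12+k21) = 0.2 ns
#>   occupancy: 0.809 0.191                   # truth: 0.8 / 0.2
tst_barrier(hop_statistics(m)$hops_per_ns)
#> <barrier_estimate> delta_G = 8.296 k_BT, rate = 1.56 ns^-1, prefactor = 6251 ns^-1

occupied_fraction(gen_sphere_packing(800, 0.22, box = 4, mode = "poisson",
                                     seed = 7), spacing = 0.05)
#> <free_volume_result> occupied 42.56%, free 57.44% (grid 0.05 nm, 512000 points)
```

Reading the output: the drying curve's stretch factor beta = 0.58 < 1 is the
signature of the activity-dependent diffusivity; the fitted intercept
D_w,org = 1.03e-15 m²/s recovers the true 1e-15; the fractional exponent
alpha = 0.39 quantifies diffusion–viscosity decoupling on this landscape;
the HMM recovers the exact two-state relaxation timescale (0.19 vs 0.2 ns)
and stationary occupancies; and the Poisson packing's occupied fraction
matches its closed form 1 − exp(−ρ·4/3·π·r³) = 42.6%.

An end-to-end pipeline with a shipped demo configuration:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "cavitydiff"))
```

or from the shell:

```sh
Rscript inst/scripts/cavitydiff.R run --config inst/extdata/demo_config.json \
    --seed 1 --out /tmp/demo_run
```

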