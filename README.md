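# gridbind

Absolute protein–ligand binding free energies from restrained umbrella
sampling, via a three-dimensional "grid" potential of mean force.

## What problem this solves, and for whom

Computing an absolute binding free energy ΔG° (and thus a dissociation
constant K_d) from molecular dynamics requires more than a distance PMF:
the ligand's slow orientational and conformational degrees of freedom
stall convergence, and the finite simulation volume must be tied to the
1 M standard state. A practical route is to *restrain* those slow degrees
of freedom during distance-based umbrella sampling, then remove each
restraint analytically afterwards. `gridbind` is an R implementation of
that analysis chain for computational biophysicists who already have
biased collective-variable (CV) trajectories — it performs no MD itself.

The pipeline:

1. **Reweighting** — pooled frames from all umbrella windows get unbiased
   weights from the self-consistent estimator
   `w_k = c / Σ_i n_i exp(−(U_i(r_k) − F_i)/RT)` with
   `exp(−F_i/RT) = Σ_k w_k exp(−U_i(r_k)/RT)`, solved by a safeguarded
   Newton iteration in log space (`solve_weights()`).
2. **Grid PMF** — ligand positions are binned into voxels;
   `ΔG(x) = −RT ln p(x)`, anchored at the lowest-PMF voxel
   (`grid_pmf()`, `radial_profile()`).
3. **Volume terms** — pocket volume `V_P = ∫ exp(−ΔG/RT) dV` and the
   standard-state term `ΔG_V = −RT ln(V_P/V_B)`, with
   `V_B = 10²⁷/N_A ≈ 1661 Å³` (`pocket_volume()`, `volume_terms()`).
4. **Restraint corrections** — each always-on harmonic restraint `k ζ²/2`
   is removed with
   `ΔU = −RT ln(⟨e^{−kζ²/2RT}⟩_bulk / ⟨e^{−kζ²/2RT}⟩_pocket)`, the averages
   computed by quadrature from 1-D PMFs of ζ; nested restraints via
   `restraint_chain()` (`restraint_correction()`). The bulk orientation
   reference is the exact rotation-angle density `(1 − cos Ω)/π`
   (`bulk_orientation_pmf()`).
5. **Assembly** — `ΔG° = ΔG_grid + Σ ΔU + ΔG_V` (pocket-minus-bulk
   convention), `K_d = exp(ΔG°/RT)` M, with root-sum-square error
   propagation (`assemble_dg0()`).
6. **Uncertainty** — a 100-resample block Bayesian bootstrap re-runs the
   whole estimator under Dirichlet block weights
   (`block_bayesian_bootstrap()`).

A synthetic-data module (`toy_binding_system()`, `sample_windows()`)
provides a Gaussian-pocket toy ligand — optionally with a pocket-coupled
orientation angle — whose ΔG° is known exactly by quadrature, so the whole
chain can be validated without MD data.

## Worked example

Two umbrella windows on a 1-D harmonic CV, reweighted and histogrammed,
followed by a free-energy budget assembled from tabulated terms:

```r
library(gridbind)
set.seed(7)
cfg <- umbrella_config("x", from = 0, to = 2, n = 2, k = 2, temperature = 300)
draw <- function(center) rnorm(5000, 2 * center / 3, sqrt(rt(300) / 3))
trajs <- list(w01 = cv_trajectory("w01", 1:5000, data.frame(x = draw(0))),
              w02 = cv_trajectory("w02", 1:5000, data.frame(x = draw(2))))
samples <- pool_samples(trajs, cfg)
fit <- solve_weights(samples, cfg)
summary(fit)
#> Non-parametric reweighting fit at 300 K
#>   10000 frames in 2 windows; effective sample size 3264
#>   perturbed free energies F_i (kcal/mol, F_1 = 0): [0.000, 1.348]
#>   converged: TRUE after 4 sweeps, residual 1.6e-13 kcal/mol

budget <- assemble_dg0(
  grid_pmf_difference = -13.2, grid_err = 0.3,
  corrections = list(manual_correction("omega", 4.4, 0.3)),
  dg_volume = 2.5, dg_volume_err = 0.2, temperature = 300)
summary(budget)
#> Binding free-energy budget (kcal/mol) at 300 K
#>   grid PMF difference (pocket - bulk): -13.20 +/- 0.30
#>   dU_omega: 4.40 +/- 0.30
#>   dG_V: 2.50 +/- 0.20
#>   dG0 : -6.30 +/- 0.47
#>   K_d : 2.57e-05 M
#>   K_d range (+/- 1 s.d.): 1.17e-05 - 5.65e-05 M
```

The fitted `F_2 − F_1 = 1.348` kcal/mol is the free-energy offset between
the two biased ensembles (the exact value for these Gaussians is 4/3); the
budget output reads: the ligand sits 13.2 kcal/mol below the bulk on the
position grid, removing the orientation restraint costs 4.4 kcal/mol of
orientational entropy, confinement to the pocket volume costs another
2.5 kcal/mol against the 1 M standard state, leaving ΔG° = −6.3 ± 0.5
kcal/mol, i.e. K_d ≈ 26 μM.

A command-line front end with subcommands
(`reweight | pmf1d | gridpmf | radial | orient-ref | correct | volume |
assemble | bootstrap | synth`) is installed at
`system.file("cli", "gridbind.R", package = "gridbind")`; every run writes
a JSON manifest with parameters, input digests and the constants in force.

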