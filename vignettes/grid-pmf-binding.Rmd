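---
title: "Grid-PMF binding free energies from restrained umbrella sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-PMF binding free energies from restrained umbrella sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridbind)
```

## The model

`gridbind` estimates the standard (absolute) binding free energy
$\Delta G^\circ$ of a protein–ligand pair from distance-based umbrella
sampling, and converts it to a dissociation constant through
$\Delta G^\circ = RT \ln (K_d / 1\,\mathrm{M})$.

The central object is the *grid PMF*: the potential of mean force
$G(\mathbf{x}) = -RT \ln p(\mathbf{x})$ of the ligand's mass-center position
$\mathbf{x}$ relative to the binding-pocket center, binned on a regular
cubic lattice. With $\Delta G(\mathbf{x}) = G(\mathbf{x}) - G(\mathbf{0})$
anchored at the lowest-PMF voxel, the binding free energy splits into a
pocket-to-bulk PMF difference and a volume term,

$$\Delta G^\circ = -\Delta G(\mathbf{x}_B) - RT\ln\frac{V_P}{V_B},
\qquad
V_P = \int_{\mathrm{pocket}} e^{-\Delta G(\mathbf{x})/RT}\, dV,$$

where $\mathbf{x}_B$ is any bulk grid point and
$V_B = 10^{27}/N_A \approx 1661\ \mathring{A}^3$ is the volume per molecule
at the 1 M standard state, for which
$\Delta G_B = -RT\ln(V_B/\mathring{A}^3) \approx -7.42\,RT$. Because
$\Delta G$ is measured from the pocket minimum, distant voxels contribute
$e^{-\Delta G/RT} \approx 0$ and no sharp pocket boundary is needed for a
deep pocket; for shallow synthetic systems an explicit pocket radius pins
the definition down (`pocket_radius` in `estimate_dg0()`).

## Non-parametric reweighting

Frames pooled from $N$ umbrella windows with biases $U_i$ are reweighted to
the unbiased ensemble by the self-consistent estimator

$$w_k = \frac{c}{\sum_i n_i\, e^{-(U_i(\mathbf{r}_k) - F_i)/RT}},
\qquad
e^{-F_i/RT} = \sum_k w_k\, e^{-U_i(\mathbf{r}_k)/RT},$$

with $\sum_k w_k = 1$ and $F_1 = 0$ as the gauge anchor. With equal window
sample counts $n_i$ this reduces to the familiar equal-sample form; the
implementation keeps the general $n_i$ because production windows rarely
stay equal after discarding equilibration. The converged weights support
any downstream observable: 1-D PMFs by nearest-bin weighted histograms
(ties go to the lower-index bin), the 3-D grid PMF, and arbitrary ensemble
averages.

Numerical choices:

* all Boltzmann factors are evaluated in log space (log-sum-exp), so
  deeply biased frames cannot underflow;
* the default solver is a safeguarded Newton iteration on the equivalent
  convex objective — the gradient *is* the fixed-point residual and the
  Hessian comes from the normalised weight matrix — falling back to plain
  fixed-point sweeps whenever a Newton step fails to reduce the residual.
  `method = "sc"` runs the plain iteration; both reach the same fixed
  point, which the test suite checks against an independently written
  brute-force iteration;
* convergence is declared at $\max_i |\Delta F_i| < 10^{-8}$ kcal/mol
  (default), with `max_iter = 10000`; non-convergence is flagged on the
  returned object rather than thrown;
* initial values are $F_i = 0$ or a caller-supplied warm start (used by the
  bootstrap, which re-solves the same system under slightly perturbed
  multiplicities; the warm start changes the path, not the fixed point).

## Window biases versus always-on restraints

A `window_config` distinguishes two kinds of harmonic terms, and the
distinction is load-bearing. Per-window *biases* (the umbrella centers)
differ between windows; the estimator removes exactly these. *Always-on
restraints* — e.g. an orientation restraint $\tfrac12 k\Omega^2$ held in
every window — are part of the sampled ensemble. Had they been listed among
the window biases, the estimator would mathematically reweight to the
*unrestrained* ensemble, which sharply confined samples cannot support: the
effective sample size collapses and the grid PMF is garbage. The package
therefore keeps restraints in `config$restraints`, reconstructs the
*restrained* grid PMF, and removes the restraints afterwards with analytic
correction terms.

## Restraint corrections

For a restraint $\tfrac12 k\zeta^2$ on a CV $\zeta$ (orientation angle in
radians, RMSD in angstrom), the correction uses the restrained-factor
averages under the *unrestrained* 1-D PMF of $\zeta$ in the pocket and in
the bulk:

$$\Delta U = -RT \ln \frac{\langle e^{-k\zeta^2/2RT}\rangle_{\mathrm{bulk}}}
{\langle e^{-k\zeta^2/2RT}\rangle_{\mathrm{pocket}}},
\qquad
\langle e^{-k\zeta^2/2RT}\rangle =
\frac{\int e^{-(F(\zeta)+k\zeta^2/2)/RT}\,d\zeta}
     {\int e^{-F(\zeta)/RT}\,d\zeta},$$

evaluated by trapezoidal quadrature in log space on the PMF's own grid.
Grid points more than $25\,RT$ above the PMF minimum are dropped — they
contribute below $e^{-25}$ and tend to be the noisiest bins. Nested
restraints (removed one at a time, e.g. protein RMSD, then ligand RMSD,
then orientation) are handled by `restraint_chain()`; each term's PMFs must
have been measured with exactly the restraints listed in its
`conditioned_on` metadata still applied, and `chain_corrections()` refuses
chains whose metadata disagrees with the removal order — a silent mix-up
between conditioned and unconditioned PMFs being the main practical failure
mode of stratified corrections.

The budget is assembled in the pocket-minus-bulk sign convention (a binder
has a negative grid term), per-term 1-s.d. errors combine as a root sum of
squares, and $K_d = e^{\Delta G^\circ / RT}$ M.

## The orientation reference

The orientation CV $\Omega \in [0, \pi]$ is the single rotation angle
between the ligand's orientation and a reference. For a freely tumbling
ligand in the bulk, $\Omega$ follows the rotation-angle density of a
uniform distribution over SO(3), with closed form
$p(\Omega) = (1 - \cos\Omega)/\pi$.

`bulk_orientation_pmf()` reproduces this density numerically by
discretising three Euler angles. The package uses the intrinsic z–y–x
(yaw–pitch–roll) convention: yaw $\phi$ and roll $\psi$ over $[0, 2\pi)$,
pitch $\theta$ over $[-\pi/2, \pi/2]$, Haar weight
$\cos\theta / 8\pi^2$, and the quaternion half-angle identity

$$\cos\tfrac{\Omega}{2} =
\cos\tfrac{\phi}{2}\cos\tfrac{\theta}{2}\cos\tfrac{\psi}{2} +
\sin\tfrac{\phi}{2}\sin\tfrac{\theta}{2}\sin\tfrac{\psi}{2}.$$

This pairing matters: the half-angle identity above is exact for z–y–x
composition (the tests verify it against the rotation-matrix trace to
$10^{-10}$), and only the matched pair of identity and Haar weight
reproduces $(1-\cos\Omega)/\pi$. Pairing the same identity with the
$\sin\theta$ weight of a proper-Euler (z–x–z) convention, as is sometimes
done, misses the density by $O(0.1)$.

Two further numerical points. First, lattice mass is deposited *linearly*
between the two nearest $\Omega$ bins (cloud-in-cell): nearest-bin
deposition leaves aliasing noise of about $4\times10^{-3}$ at a 1° lattice,
several times the discretisation error, while linear deposition reaches
$6\times10^{-4}$. Second, the 1° density lattice is far too coarse for the
sharply restrained integrand of a correction term
($k = 0.5$ kcal mol$^{-1}$ deg$^{-2}$ confines $\Omega$ to about 1°), so
correction-term quadrature uses the closed-form density on a 0.01° grid
(`bulk_orientation_pmf_analytic()`).

## Estimating the bulk plateau

The grid term $-\Delta G(\mathbf{x}_B)$ requires the PMF plateau in the
bulk. Averaging per-voxel $-RT\ln(\hat m_v)$ values over a bulk shell is
biased upward when individual voxels hold few effective samples (Jensen's
inequality on the log), and the bias grows with autocorrelation — in early
experiments it reached 0.3–0.9 kcal/mol. `grid_pmf_difference()` instead
Boltzmann-sums the shell's voxel masses and divides by the *geometric*
voxel count of the shell (unvisited bulk voxels count as zero mass):

$$\Delta G_{\mathrm{bulk}} =
-RT \ln\!\left(\frac{\sum_{v \in \mathrm{shell}} \hat m_v}{N_{\mathrm{shell}}}\right),$$

which is linear in the unbiased masses and essentially unbiased. The
radial profile of shell means and population standard deviations
(`radial_profile()`) is still provided as the standard visual diagnostic.

## Uncertainties

Errors come from a block Bayesian bootstrap: within each window the frames
are cut into contiguous blocks (20 per window by default, or a fixed block
length), each resample draws flat Dirichlet weights over a window's blocks,
frame multiplicities are the block weight times the block count, and the
entire estimator — including the reweighting solve — is re-run. One
hundred resamples are used by default. Blocks, not frames, carry the
Dirichlet weights so that autocorrelation within a block does not deflate
the error; the test suite checks both the iid calibration (bootstrap s.d.
within a factor 1.3 of the analytic standard error) and the directional
property that longer blocks report larger errors on an AR(1) series.
Resamples are deterministic given the plan's seed; failed resamples are
excluded (more than 10% failing is an error) rather than retried, keeping
seed reproducibility.

## The synthetic benchmark

`toy_binding_system()` builds a fully solvable stand-in for a
protein–ligand system: a point ligand in a Gaussian pocket
$U_0(\mathbf{x}) = -\varepsilon\, e^{-|\mathbf{x}|^2/2\sigma^2}$ inside a
cubic box, optionally with an orientation angle carrying the rigid-body
Haar measure $(1-\cos\Omega)/\pi$ and a pocket-coupled stiffness
$h(\mathbf{x})\,\tfrac12\kappa_\Omega\Omega^2$ sharing the Gaussian
envelope $h$ — confined orientation in the pocket, free tumbling in the
bulk, which is precisely the physics that makes orientation restraints
necessary in real calculations. Exact reference values
($\Delta G(\mathbf{x}_B)$, $V_P$, $\Delta G^\circ$) come from 1-D radial
quadrature; refining the quadrature twofold must move $\Delta G^\circ$ by
less than $10^{-4}$ kcal/mol or the constructor errors out.

`sample_windows()` generates the per-window data: one Metropolis chain per
window, all windows stepped together, with Gaussian position proposals, a
reflective-by-rejection orientation proposal, and — one step in four —
a uniform random rotation of the position vector about the origin.
Rotation moves pass through the usual Metropolis criterion, so they remain
correct for any potential; for radially symmetric ones they are accepted
essentially always and cure the slow diffusive mixing over spherical
shells that otherwise dominates the bulk-plateau error. No replica
exchange is simulated: the reweighting estimator is exchange-agnostic, so
plain umbrella windows test the same estimator.

The benchmark study conditions, chosen once: pocket depth
$\varepsilon = 10$ kcal/mol and width $\sigma = 2$ Å in a 40 Å box with
orientation stiffness $\kappa_\Omega = 20$ kcal/mol/rad² — a strong,
sharply oriented binder whose pocket-to-bulk PMF difference (about
5.9 kcal/mol with the orientational entropy included) is large against the
estimator's noise yet cheap to sample; 31 distance windows with centers
0–15 Å and $k = 2$ kcal mol$^{-1}$ Å$^{-2}$, the standard distance-window
layout for this class of calculation; an orientation restraint of
$k = 0.5$ kcal mol$^{-1}$ deg$^{-2}$ for the restrained protocol; 2500
retained frames per window (thinning 10) — a realistic analysis size that
keeps the full two-protocol benchmark within minutes on one CPU; an
orientation umbrella run of the bound state (40 windows over 0–50°, 1200
frames each, with the ligand position restrained to the pocket center at
$k_d = 10$ kcal mol$^{-1}$ Å$^{-2}$) for the pocket-side orientation PMF;
bulk shells at 8–14 Å, where the pocket envelope is below $10^{-3}$; and a
pocket radius of $5\sigma = 10$ Å matching the oracle's pocket definition —
needed here because this pocket is shallow enough for sampled bulk voxels
to contribute visibly to $V_P$, which is not the case for a deep
protein–ligand pocket.

What passing these tests shows — and what it does not. The benchmark
validates the estimator chain end to end: reweighting, grid binning,
plateau and volume estimation, restraint corrections (the restrained and
unrestrained protocols must land on the same answer), and error
calibration. It does not exercise force-field error, imperfect CV
definitions, slow conformational degrees of freedom absent from the toy,
or the convergence of real MD sampling; agreement here is a necessary, not
sufficient, condition for trusting a production result.

## Degenerate inputs and edge rules

Frames missing any declared CV are rejected at parse time, not imputed —
every bias energy must be evaluable for every pooled frame. Exact
nearest-bin ties go to the lower-index bin. Unoccupied bins and voxels are
flagged or absent, never given pseudo-values. A restraint average that
underflows raises an error advising a finer PMF grid rather than returning
0. Temperatures are explicit arguments everywhere (300 K for simulation
quantities, 298.15 K for calorimetric comparisons); nothing infers them.

## Known limitations

* The pocket-side orientation PMF enters the correction as an input; its
  window layout must overlap well (spacing comparable to the restrained
  width), or the correction inherits a seed-level wobble larger than its
  bootstrap error.
* The bulk plateau estimator assumes the bulk shells lie inside the
  sampled region; shells beyond the outermost window are silently empty
  and raise an error only when *no* occupied voxel falls in the range.
* The Metropolis sampler is a data generator for validation, not a
  production MD engine; its rotation moves exploit symmetry that real
  systems lack.
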