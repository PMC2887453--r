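---
title: "Nonlinear conformational relaxation in elastic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear conformational relaxation in elastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmrelax)
```

## The model

`enmrelax` studies how a coarse-grained protein relaxes to its equilibrium
conformation when that relaxation is *not* assumed to be linear. The protein
is an elastic network: one bead per residue at the C-alpha position of a
reference crystal structure, and a Hookean spring between every pair of beads
closer than a cutoff $r_c$ in that structure. With $A_{ij}$ the adjacency
matrix, $d_{ij}$ the instantaneous and $d^0_{ij}$ the reference inter-bead
distances, the elastic energy is

$$E = \frac{\kappa}{2} \sum_{i<j} A_{ij}\,(d_{ij} - d^0_{ij})^2 ,$$

and the force on bead $i$ is
$F_i = -\kappa \sum_j A_{ij} (d_{ij}-d^0_{ij})(R_i-R_j)/d_{ij}$. All springs
share one stiffness $\kappa$; we work in rescaled units with $\kappa = 1$ and
the (uniform) bead mobility absorbed into the time unit. Although $E$ is
quadratic in the distances, each $d_{ij}$ is a nonlinear function of the
coordinates, so the forces — and hence the dynamics — are nonlinear. That
nonlinearity, not any anharmonic spring law, is the subject of the analysis.

Slow conformational motions of proteins in solvent are overdamped, so the
dynamics is the gradient flow

$$\frac{dR_i}{dt} = F_i(R_1,\dots,R_N),$$

optionally with constant external forces added. Without external forcing the
energy strictly dissipates, $dE/dt = -\sum_i |dR_i/dt|^2 \le 0$, and every
trajectory terminates in an energy minimum: the reference state (the global
minimum, at $E=0$ by construction) or a metastable local minimum. Inertia,
hydrodynamic coupling, explicit thermal noise and torsional elasticity are
all outside the model; thermal agitation enters only through the choice of
randomized starting conformations.

## Parameters that matter

* **Cutoff $r_c$** (Å): controls network connectivity. The package default
  is 10 Å, the value consistent with the link densities of the motor-protein
  networks this analysis targets (mean degree $\approx 17$); 8–10 Å are
  ordinary alternatives for sensitivity checks, set per call or per config.
* **Force protocol $f_0$, $t_0$**: random static forces of fixed modulus
  $f_0$ (uniformly random directions) applied for time $t_0$ prepare
  strongly deformed but unfolded starting states. For protein-scale runs
  these are required config fields with no defaults — they are physical
  choices per system. The fixture-scale defaults ($f_0 = 0.6$, $t_0 = 10$)
  produce typical deformations of 0.7–1.2 Å RMSD on the 40-bead hinge, of
  the same order as its functional conformational change, with maximum link
  stretches below 1.1 — "large but not unfolding".
* **RMS perturbation $a$** (Å): isotropic Gaussian displacement, rescaled so
  the realized RMS over beads equals $a$ exactly, used to probe the
  robustness of a specific relaxation path. Fixture default 0.3 Å, a
  substantial fraction of the hinge's functional deformation.
* **Unfolding guard**: preparation fails if any link stretches beyond
  2.0 × its natural length (config-exposed).
* **Convergence**: a trajectory has converged when the largest per-bead
  force norm falls below $10^{-8}$ (rescaled units).
* **Endpoint identity**: the final frame is compared with the reference by
  RMSD after optimal proper-rotation (Kabsch) superposition; below 0.5 Å it
  counts as the reference state, otherwise as metastable. Mirror images are
  *not* superposable, which matters for the bistable fixture below.

## Numerical choices

The gradient flow is integrated with `deSolve`'s `lsodar`: adaptive,
stiffness-switching, with a root function that terminates integration the
moment the convergence criterion is met. An explicit adaptive Runge–Kutta
would also work, but the spring networks produce decay rates spread over
several orders of magnitude ($\lambda_{\max}/\lambda_1 \sim 10^2$–$10^3$ on
these networks), which is exactly the regime where a
stiffness-aware multistep method is preferable. Relative tolerance defaults
to $10^{-8}$; tightening it to $10^{-10}$ moves fixture endpoints by less
than $10^{-6}$ Å.

Frames are recorded on a log-spaced schedule spanning six decades below
`t_max`, because the early transient (stiff modes) is fast and the tail
exponential. The six-decade floor is deliberate: with a shallower floor the
first recorded interval truncates the stiff transient and the two estimators
of the mechanical coordinate (next section) disagree at the $10^{-3}$ level
instead of the $10^{-5}$ level.

## The mechanical coordinate and energy profile

Once a trajectory has entered a relaxation valley its motion is effectively
one-dimensional. The collective mechanical coordinate $s(t)$ is the
configuration-space arc length still to be traveled to the endpoint:

$$s(T) = \int_T^\infty \Big|\frac{dR}{dt}\Big| \, dt
       = \int_T^\infty \sqrt{-\,dE/dt}\; dt ,$$

the two integrands being identical along the gradient flow. The package
computes $s$ two independent ways — chord-summed arc length over frames
(default), and quadrature of the speed recovered from the forces — and the
test suite requires them to agree within 0.1%. The speed quadrature uses the
logarithmic-mean rule per interval, which is exact when the speed decays
exponentially, as it does in the relaxation tail. $s$ is deliberately
computed in full $3N$-dimensional configuration space; the two label
distances $(l_{AB}, l_{BC})$ used for visualization are a projection and
carry no dynamical weight.

Near the reference state the profile must become the soft-mode parabola
$E(s) = \tfrac{1}{2}\lambda_1 s^2$, where $\lambda_1$ is the smallest
nonzero eigenvalue of the Hessian. `fit_quadratic_well()` fits $E = k s^2$
through the origin over a window of small $s$ (pipeline default: the last
30% of the path, comfortably inside the single-mode regime for fixtures with
a spectral gap) and reports the harmonic-domain radius — the largest $s$ at
which the profile stays within 10% of the fitted parabola, scanned
contiguously from the origin over points whose energy is numerically
meaningful (above $10^{-9}$ of the profile maximum, since a relative
criterion is vacuous at the $E \to 0$ endpoint).

## Normal modes

Linearizing the flow at the reference gives $d\,\delta R/dt = -H\,\delta R$
with $H$ the Hessian; each eigenvector decays exponentially at its
eigenvalue. Six eigenvalues are zero for a connected, non-collinear network
(rigid translations and infinitesimal rotations); the tests verify that the
zero subspace coincides with analytically constructed rigid-motion vectors.
Eigenvalues below $10^{-8}$ of the spectral maximum count as zero — a purely
numerical threshold, as the rigid modes sit at round-off while the softest
elastic fixtures modes are at $10^{-3}$ of the maximum or above.
Eigenvector signs are fixed (first significant component positive) so
exported spectra are reproducible. The dense symmetric eigensolver is
appropriate at these sizes (3N ≤ ~2600 for the target proteins).

The linear solution is valid only while the deviation is small; the suite
checks that nonlinear and linear trajectories started 0.005 Å RMSD from the
reference agree to second order in amplitude (doubling the amplitude
quadruples the gap). The soft mode's footprint in the label plane — the
undirected line along which purely exponential relaxation would move the two
monitored distances — is computed from the first-order change of $l_{AB}$
and $l_{BC}$ along $e_1$ and compared with the late-time tangent of
nonlinear trajectories; on the hinge fixture they agree to well under a
degree.

## What the synthetic fixtures emulate

No structure downloads are needed to exercise any stage; the generators
build conformation pairs with the geometric features the analysis assumes.

* **Chains and helices** (`make_toy_chain`): beads at 3.8 Å spacing —
  C-alpha-like, so protein-scale cutoffs behave sensibly — with known link
  counts (a straight chain under a 10 Å cutoff links each bead to its ±1 and
  ±2 neighbours: $2n-3$ springs) and known degeneracies (a collinear chain
  has more than six zero modes, because transverse bending costs no energy
  at harmonic order).
* **Two-domain hinge** (`make_two_domain_hinge`): two compact FCC-like bead
  clusters across a narrow waist, the "deformed" state twisting one domain
  about the inter-domain axis. Both states share one contact topology —
  verified at generation, with automatic angle reduction otherwise — which
  encodes the elastic assumption that ligand-induced motion preserves the
  residue contact pattern. The twist axis was chosen over an in-plane
  rotation because it preserves topology at much larger angles (21° vs 2.6°
  at the default geometry), giving a meaningful functional deformation. Its
  relaxation is soft-mode dominated (spectral gap ≈ 6.8), the analog of a
  motor with one well-defined attractive path.
* **Bistable flap** (`make_bistable_network`): a rigid tetrahedral base plus
  a flap held by exactly three springs. Three sphere constraints admit two
  isolated solutions — the reference and its mirror through the anchor
  plane — so the network has two zero-energy minima that are enantiomers,
  hence Kabsch-distinguishable. Multi-start descent (the oracle in the test
  suite) confirms exactly two attractors.
* **Two-valley network** (`make_two_valley_network`): the same base with a
  slow flap (soft angular coordinate, single minimum, one high barrier) and
  a fast flap. Bundles whose fast flap starts on either side of its rest
  azimuth descend through two distinct, same-side valleys that merge only
  near the equilibrium — the branched-path phenomenology. A shallow
  metastable shoulder on the slow flap's circle traps starts placed
  directly inside it.

What passing on fixtures does **not** show: real proteins have heterogeneous
contact densities, quasi-degenerate soft modes, and far larger metastable
repertoires, so endpoint statistics and branch structure measured here do
not transfer quantitatively — the fixtures validate the machinery, not any
biological claim.

## Bundle dispersion and branch detection

Trajectory bundles are compared in the label plane at matched *progress* —
each trace's own remaining arc-length fraction, since traces have different
total lengths. Dispersion is the RMS distance to the bundle medoid. An
attractive path shows dispersion falling monotonically to zero with
progress.

Branching is reported when a 2-means split of the bundle at some progress
value finds two clusters whose mutual gap (closest cross-cluster pair)
exceeds 3 × the median within-cluster nearest-neighbour spacing — an
empty-corridor criterion that stays quiet on elongated unimodal clouds —
*and* the clusters subtend less than 120° at the common endpoint. The angle
condition formalizes something the visual analysis treats implicitly: a
valley is an undirected line through the minimum, so trajectories entering
along its two opposite arms (which any isotropic random-start bundle
produces) are one path, not a branch. Genuine branching means two same-side
valleys. The factor 3 and the 120° threshold are this package's own
formalization of a judgement otherwise made by eye, and both are
config-exposed; the merge progress reported is the largest grid value below
all flagged bimodality.

## Problem sizes and reproducibility

The shipped experiments use a 40-bead hinge with bundles of 100 trajectories
(matching the bundle size of the motor-protein study design) and the
6-particle valley fixtures; at these sizes the full pipeline runs in a few
minutes on one core, and every random draw is governed by a single integer
seed (R's Mersenne-Twister, with per-replicate seeds derived by fixed
offsets). Protein-scale inputs (855 beads for the myosin V pair, 320 for
KIF1A) run through the identical code path via `network_from_pdb_pair()`
once the PDB entries are on disk; only the dense eigendecomposition grows
noticeably with size.

## Known limitations

* Identifier-based residue pairing only; no sequence alignment. Structures
  whose chains are named differently need an explicit `chain_map`.
* The branch detector assumes a bundle dense enough for nearest-neighbour
  spacing to estimate within-valley spread; below ~10 traces it is
  conservative by construction (minimum cluster size).
* Metastable endpoints are classified, not characterized: no basin volumes,
  committors or rate estimates.
* The harmonic-fit window is a fraction of the path; for systems without a
  spectral gap the single-mode parabola is not expected to match any window.
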