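---
title: "Coarse-grained Monte Carlo models of antibody solutions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Monte Carlo models of antibody solutions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Concentrated monoclonal antibody (mAb) solutions are hard to characterise:
small-angle X-ray scattering (SAXS) measures an effective structure factor
$S_\mathrm{eff}(q)$ that mixes single-molecule form and inter-protein
correlations, while atomistic simulation of hundreds of 148 kDa proteins is
out of reach. `cgmab` implements a multi-scale coarse-grained route:

1. **Amino-acid resolution.** A rigid structure is reduced to one bead per
   residue, with bead diameter $\sigma = (6 M_W/\pi\rho)^{1/3}$ from the
   residue molecular weight and an average residue density
   $\rho = 1\,\mathrm{g\,mol^{-1}\,\text{Å}^{-3}}$.
2. **Constant-pH titration MC.** Protonation states of titratable sites
   fluctuate under the Metropolis rule with
   $\Delta\beta U = \Delta\beta U_\mathrm{elec} \pm \ln(10)(\mathrm{p}K_a -
   \mathrm{pH})$ (plus sign for deprotonation) and screened-Coulomb
   couplings $\lambda_B q_i q_j e^{-r/\lambda_D}/r$, yielding the net charge
   $Q_\mathrm{net}$ and per-site mean charges.
3. **Many-protein rigid-body MC.** $N_p$ rigid copies move in a cubic
   periodic box of volume $V = N_p M_w /(c_p N_A 10^{-27})$ ų under either
   the amino-acid pair potential (screened Coulomb + Lennard-Jones) or the
   Y-shaped bead-model potential (hard core + size-corrected Yukawa $-$
   attractive $r^{-6}$), optionally with Hamiltonian replica exchange over
   the attraction strength $\varepsilon_{ij}$.
4. **Scattering.** $S_\mathrm{eff}(q)$ is estimated on the crystallographic
   grid $q = (2\pi p/L)(h,k,l)$, $p = 1..25$, families [100], [110], [111],
   as the per-bead-normalised ensemble intensity divided by the
   orientation-averaged single-molecule form factor; $(Q_\mathrm{eff},
   \varepsilon_{ij})$ are then fitted to a measured curve by a
   $\chi^2$ grid scan on the 51-point window $q = 0.01..0.12$ Å⁻¹.

## Electrostatics

The Bjerrum length $\lambda_B = e^2/(4\pi\varepsilon_0\varepsilon_r k_BT)$
is 7.1 Å in water at 25 °C ($\varepsilon_r = 78.7$).  At infinite protein
dilution the Debye length is $\lambda_D = 3.04/\sqrt{I(\mathrm{M})}$ Å.  In
a crowded box the package uses

$$\frac{1}{\lambda_D^2} = 4\pi\lambda_B\left[\frac{Z\rho_\mathrm{mAb}}{1-\phi}
 + 2\rho_\mathrm{salt} + 2\rho_\mathrm{buffer}\right],
 \qquad \phi = \rho_\mathrm{mAb}\,\frac{\pi(2R_g)^3}{6},$$

where the $1/(1-\phi)$ factor confines the released counterions to the
protein-free volume and $Z$ is the model's current net charge (its
magnitude; recomputed whenever a box is built, so a bead model at effective
charge $Q_\mathrm{eff}$ screens itself consistently).  The buffer term uses
the stated dissociated monovalent buffer concentration (default 0; set
`solution_conditions(buffer = ...)` if the formulation buffer is to be
counted — the package treats it as fully dissociated).

## Tunable parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| pH | 6 | — | reference formulation condition |
| temperature | 298.15 | K | room temperature |
| $\varepsilon_r$ | 78.7 | — | water at 25 °C |
| ionic strength | 0.007 | mol/L | low-salt study condition (also 0.057) |
| $c_p$ | 20 | mg/mL | the concentration at which $Q_\mathrm{eff}$ is fitted |
| $M_w$ | 148000 | g/mol | IgG1-class mAb |
| $R_g$ | 48.2 | Å | relaxed-conformation value at 7 mM (45 Å at 57 mM) |
| $\varepsilon_{ij}$ grid | 0.05–0.085 step 0.005 | $k_BT$ | 8 replicas |
| best-fit $\varepsilon_{ij}$ | 0.8 | $k_BT$ | value used for bead-model production runs |
| titration | $10^4$ sweeps × 10 moves | — | with 200 sweeps burn-in |
| $p_{max}$ | 25 | — | q-grid harmonics |

The titratable set uses standard intrinsic pKa values (Asp 4.0, Glu 4.4,
His 6.3, Cys 10.8, Tyr 9.6, Lys 10.4, Arg 12.0; chain termini `NTR` 7.5 /
`CTR` 3.67 available for users who model them), fully replaceable through
`read_pka_table()`.  Glutamine is treated as non-titratable.

## Geometry of the bead models

The Y-shaped models place $m = N_\mathrm{beads}/3$ identical tangent spheres
per arm along three straight directions: the two Fab arms at 60° to each
other and the Fc arm along the negative bisector (C2v symmetry; the 60° is a
fixed modelling assumption, configurable via `fab_angle`).  Bead $i$ of an
arm sits at distance $(i - \tfrac12)\sigma_\mathrm{bead}$ from the junction,
so all coordinates scale linearly with $\sigma_\mathrm{bead}$; the diameter
that matches a target $R_g$ therefore has the closed form
$\sigma_\mathrm{bead} = R_g^\mathrm{target}/R_g^{(\sigma=1)}$ — no iterative
solver, exact to machine precision.  $R_g$ uses the uniform-weight
point-bead convention $\sqrt{\frac1N\sum_i |r_i - r_{cm}|^2}$ with no
bead-volume term.  The 1-bead model has $R_g = 0$ under this convention; its
size enters only through its hard-core diameter, which defaults to $2R_g$
and can be overridden.  The effective charge is distributed uniformly,
$q_\mathrm{bead} = Q_\mathrm{eff}/N_\mathrm{beads}$.

## Monte Carlo design

* **Moves.** One sweep attempts one combined translation + rotation per
  molecule in a fresh random permutation.  Rotations use a uniform axis and
  an angle uniform in $(0, \delta_\mathrm{rot}]$ about the molecule centre —
  a symmetric proposal, so plain Metropolis acceptance preserves detailed
  balance.  Move sizes are tuned toward 35% acceptance during burn-in only
  and frozen for production.
* **Truncation.** Pair interactions are truncated (unshifted) at
  $r_c^\mathrm{elec} = \min(L/2,\,8\lambda_D + \sigma)$ and
  $r_c^\mathrm{vdW} = \min(L/2,\,4\sigma)$.  Screened interactions decay as
  $e^{-r/\lambda_D}$, so the neglected tail is below $10^{-3}\,k_BT$ per
  pair; $L/2$ respects the minimum-image convention.  Both radii are
  configurable in `pair_params()`.
* **Replica exchange.** Both pair potentials are affine in
  $\varepsilon_{ij}$: $\beta U = U_\mathrm{elec} + \varepsilon_{ij} W$.  The
  sampler tracks $(U_\mathrm{elec}, W)$ separately, so the swap criterion
  $\min\{1, \exp[-(\varepsilon_i-\varepsilon_j)(W_j - W_i)]\}$ is evaluated
  exactly without re-summing pairs.  Swaps alternate even/odd neighbour
  pairs every `swap_stride` sweeps.
* **Determinism.** All samplers use an internal xoshiro256** stream seeded
  explicitly; identical seeds give bit-identical trajectories independently
  of R's global RNG state.
* **Titration bookkeeping.** The per-sweep net-charge trace is the time
  average over the sweep's moves.  An isolated site at pH = pKa flips
  deterministically (zero energy change), so end-of-sweep snapshots would
  alias with even move counts; the time average removes the artifact and is
  the standard estimator.
* **Implicit proton bath.** The combinatorial/volume term of the reactive MC
  scheme applies to explicit-particle insertions; with implicit protons and
  no explicit ions it contributes no configuration-dependent difference and
  is folded into the pH/pKa term.  A hook (`dmu_deprot` in the titration
  system) is the natural place to reinstate it for explicit-ion variants.

## Scattering estimator

The intensity on a reciprocal-lattice vector is
$[(\sum_i \sin q\cdot r_i)^2 + (\sum_i \cos q \cdot r_i)^2]/N_\mathrm{tot}$.
Only positive-octant index permutations are used ([100]: 3, [110]: 3,
[111]: 1 per harmonic): the intensity is even under $q \to -q$, so sign
choices duplicate information.  The form factor is computed by uniform
random-orientation averaging of a single molecule — equivalent to a one-
molecule MC run, whose Boltzmann weight is orientation-independent — and both
numerator and denominator are normalised per bead, which pins
$S_\mathrm{eff} \equiv 1$ for non-interacting molecules without any free
normalisation constant.  During long runs the per-shell intensity can be
streamed inside the sampler (`intensity_grid =`), avoiding coordinate
storage and giving denser statistics for the same memory.

For $\chi^2$ fitting the simulated shells are first bin-averaged when closer
than half the experimental grid spacing, then linearly interpolated onto the
experimental q points (extrapolation is refused).  The $\chi^2$ denominator
is the experimental value, following the defining formula; the simulated
curve is the one interpolated, and every fit logs that convention.
$\chi^2$ scans reuse one simulation per $Q_\mathrm{eff}$ across all
$\varepsilon_{ij}$ values via replica exchange.

## What the synthetic fixtures emulate — and what they do not

`toy_mab()` builds a Y-shaped chain of real residue codes (so the pKa and
charge machinery runs unmodified) with deterministic coordinates; it has the
topology and titration behaviour of an antibody but not a real sequence,
secondary structure, or realistic charge anisotropy.  `synthetic_target()`
generates SAXS curves from the package's own bead-model pipeline with known
$(Q_\mathrm{eff}, \varepsilon_{ij})$ and multiplicative Gaussian noise;
recovery tests against it validate the inference machinery
(self-consistency), not the physical adequacy of the bead model for any real
protein.  Passing tests therefore demonstrate correct implementation of the
energy functions, samplers and estimators; conclusions about real mAbs
additionally require the deposited experimental structure and curves.

## Problem sizes used by the test-suite checks

The package's own validation runs are scaled-down study conditions chosen
for desk-scale reproducibility; each was sized from convergence diagnostics
(trace plateaus, blocked standard errors), not fitted to outcomes:

* Henderson–Hasselbalch: $10^4$ sweeps × 10 moves ($10^5$ moves), pH sweep
  over pKa ± 3.
* Ideal-gas $S_\mathrm{eff}$: 100 non-interacting point molecules, $2\times
  10^3$ sweeps, full $p_{max} = 25$ grid.
* Boltzmann two-particle check: $1.5\times10^5$ sweeps, samples every 25.
* Parameter recovery: 9-bead model at the 20 mg/mL, 7 mM condition,
  $N_p = 100$ (down from 500), truth $Q^\ast = 26\,e$,
  $\varepsilon^\ast = 0.8\,k_BT$, 2% noise; one high-precision reference
  scan ($1.6\times10^4$ sweeps per $Q_\mathrm{eff}$ cell) evaluated against
  five independently seeded targets ($10^4$ sweeps each).  Sharing the
  reference scan across targets is a variance-allocation choice: the scan
  curves are the method's deterministic (per seed) prediction set, while the
  five targets provide the independent noise realisations the recovery rate
  is measured over.

## Numerical choices, degenerate inputs, limitations

* The sampling kernels evaluate the screened-Coulomb radial factor
  $e^{-r/\lambda_D}/r$ from a piecewise-linear lookup table (0.005 Å step,
  interpolation error about $10^{-8}$ of the local value), the standard
  tabulated-potential technique of MC/MD engines; the user-facing pair-energy
  functions always evaluate the closed form, and the incremental/total energy
  bookkeeping is internally consistent because both sampler paths share the
  table.
* Because all interactions are truncated at or below $L/2$, the periodic
  image of a molecule pair is resolved once from the centre-of-mass
  separation and applied to every bead pair whenever
  $r_c + 2r_{max} \le L/2$ (identical result, far fewer rounding
  operations); otherwise the kernel falls back to per-bead-pair minimum
  images.
* Streamed intensities exploit the harmonic structure of the lattice grid:
  phases for $q = p\,q_1$ recur by complex multiplication, so each bead
  needs one sine/cosine pair per base direction rather than per q-vector.
  The streamed estimator agrees with the generic per-frame lattice sum to
  $10^{-13}$.
* Energies are in $k_BT$ throughout; lengths in Å; charges in $e$.  SAXS q
  is Å⁻¹ internally; files in nm⁻¹ are converted on read (header-detected
  or forced with `unit =`).
* Hard-core overlap is a legal return (`Inf`), short-circuited in the
  kernels; `make_box()` inserts with rejection and suggests a lattice start
  if a dense system cannot be placed.
* $N_p = 1$ boxes are allowed (form-factor runs); a 1-bead molecule has a
  degenerate point $R_g$ (see above).
* Daura clustering breaks neighbour-count ties by the lowest frame index;
  the RMSD cutoff is a free parameter (the 6 nm value quoted for full-size
  antibody trajectories is unusually large for generic use, so nothing is
  hard-coded).
* RMSD superposes frames (Kabsch) before measuring deviation; whether to
  pre-fit is a genuine convention choice, and superposition is the common
  one for conformational clustering.
* Charges are frozen after titration; many-body runs do not re-titrate
  (charge regulation during crowding is out of scope, as are anisotropic
  or hydrophobic-patch attractions, explicit ions, cluster moves and any
  dynamics).
* The low-$c_p$ flatness of $\chi^2$ in $\varepsilon_{ij}$ is physical:
  at 20 mg/mL and 7 mM the structure is dominated by long-range repulsion,
  so $Q_\mathrm{eff}$ is sharply determined while $\varepsilon_{ij}$ is
  nearly unidentifiable (the scan's row/column variance test makes this
  quantitative).  Above the fitted charge the self-consistent counterion
  screening partially compensates extra charge, which flattens the
  high-$Q_\mathrm{eff}$ side of the $\chi^2$ valley — visible in the
  recovery experiment's tolerance of ±1 grid step.
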