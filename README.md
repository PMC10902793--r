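# cgmab

Coarse-grained Monte Carlo models of monoclonal antibody (mAb) solutions.

Concentrated antibody formulations are governed by a balance of screened
electrostatic repulsion and weak short-range attraction.  Small-angle X-ray
scattering (SAXS) probes this balance through the effective structure factor
S<sub>eff</sub>(q), but interpreting it requires a molecular model that is
cheap enough to simulate at hundreds of proteins per box.  `cgmab` is aimed
at biophysicists and formulation scientists who want to go from a structure
and solution conditions to fitted interaction parameters.  It provides the
full multi-scale chain:

* **Coarse-graining** — one bead per residue with diameter
  σ = (6·M<sub>W</sub>/πρ)<sup>1/3</sup> (ρ = 1 g mol⁻¹ Å⁻³), or Y-shaped
  1/6/9/12-bead models whose bead diameter is solved so the point-bead
  radius of gyration matches a target R<sub>g</sub> (Fab–Fab angle 60°).
* **Constant-pH titration MC** — Metropolis flips of protonation states with
  ΔβU = ΔβU<sub>elec</sub> ± ln(10)(pK<sub>a</sub> − pH) and Yukawa
  couplings λ<sub>B</sub> q<sub>i</sub>q<sub>j</sub> e<sup>−r/λ_D</sup>/r;
  gives Q<sub>net</sub> and per-site charges.
* **Many-protein rigid-body MC** — N<sub>p</sub> rigid molecules in a cubic
  periodic box of volume V = N<sub>p</sub>M<sub>w</sub>/(c<sub>p</sub>N<sub>A</sub>10⁻²⁷) ų;
  amino-acid potential (screened Coulomb + Lennard-Jones) or bead potential
  (hard core + size-corrected Yukawa − ε(σ/r)⁶); Debye length from
  1/λ<sub>D</sub>² = 4πλ<sub>B</sub>[Zρ<sub>mAb</sub>/(1−φ) + 2ρ<sub>salt</sub> + 2ρ<sub>buffer</sub>]
  with φ = ρπ(2R<sub>g</sub>)³/6; Hamiltonian replica exchange over ε<sub>ij</sub>.
* **Scattering and fitting** — S<sub>eff</sub>(q) on the crystallographic
  grid q = (2πp/L)(h,k,l) (p ≤ 25; [100]/[110]/[111] families), an
  orientation-averaged single-molecule form factor, and χ² grid scans
  χ² = Σ(S<sup>sim</sup> − S<sup>exp</sup>)²/S<sup>exp</sup> over
  (Q<sub>eff</sub>, ε<sub>ij</sub>) on the 51-point window
  q = 0.01–0.12 Å⁻¹.
* **Synthetic fixtures** — a deterministic toy Y-shaped molecule (PDB text)
  and SAXS targets generated by the model itself with known ground truth,
  so the whole pipeline is testable offline.

MC and lattice-sum kernels are implemented in C++ (Rcpp); results come back
as tibbles and S3 objects with `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(cgmab)

# a deterministic toy Y-shaped molecule (stand-in for a homology model)
toy  <- toy_mab(n_res_per_arm = 10, seed = 1)
cond <- solution_conditions(ph = 6, ionic_strength = 0.007, c_p = 20)

# titrate the amino-acid model at pH 6, I = 7 mM
titr <- run_constant_ph(toy$molecule, cond, n_sweeps = 1e4, seed = 1)
glance(titr)
#> # A tibble: 1 x 7
#>   mean_net_charge se_net_charge acceptance_rate n_sweeps burn_in    ph lambda_d
#>             <dbl>         <dbl>           <dbl>    <dbl>   <dbl> <dbl>    <dbl>
#> 1          0.0781       0.00359          0.0125    10000     200     6     36.3
```

The toy's mixed acid/base composition nearly balances at pH 6 (mean net
charge +0.08 e); λ_D = 36.3 Å is the 7 mM infinite-dilution screening
length, and the low flip acceptance reflects sites sitting far from their
pK<sub>a</sub> at this pH.  A 9-bead model matched to R_g = 48.2 Å then feeds a many-protein
run and a charge fit against a synthetic target whose true effective charge
is 26 e:

```r
tpl    <- build_bead_model(9, target_rg = 48.2)
target <- synthetic_target(tpl, qeff = 26, eps = 0.8, c_p = 20,
                           conditions = cond, noise_frac = 0.02, seed = 1,
                           n_p = 100, n_sweeps = 1e4, burn_in = 1e3)
scan   <- scan_chi2(bead_model_builder(9, 48.2), target,
                    qeff_grid = seq(20, 32, 2), eps_grid = 0.8,
                    n_p = 100, c_p = 20, conditions = cond,
                    n_sweeps = 1.6e4, burn_in = 1.5e3, seed = 101)
scan
#> <chi2_scan> 7 x 1 (Q_eff x eps) grid; argmin Q_eff = 24 e, eps = 0.8 kBT (chi2 = 0.02228)
tidy(scan)
#> # A tibble: 7 x 3
#>    qeff   eps   chi2
#>   <dbl> <dbl>  <dbl>
#> 1    20   0.8 0.0741
#> 2    22   0.8 0.0506
#> 3    24   0.8 0.0223
#> 4    26   0.8 0.0320
#> 5    28   0.8 0.0387
#> 6    30   0.8 0.0587
#> 7    32   0.8 0.152
autoplot(scan)   # log-scaled chi2 heat map
```

The χ² valley sits at 24–26 e: this noise realisation tips the minimum one
grid step (2 e) below the 26 e ground truth, with the far cells (20, 32 e)
three to seven times higher — the effective charge is sharply determined at
low concentration even though the attraction strength is not.

A staged end-to-end run (structure → titration → bead model → simulation →
S_eff → fit) with artifact and provenance tracking:

```r
run_pipeline(list("run.outdir" = "out", "run.seed" = 1))
```

or from a shell via the thin wrapper `inst/scripts/cgmab.R`.

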