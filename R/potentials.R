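# Electrostatic screening quantities and pairwise energy functions.
# Units: lengths Angstrom, energies kBT, charges e, concentrations as noted.

#' Convert a molar concentration to a number density
#'
#' @param molar concentration in mol/L.
#' @return number density in particles per cubic Angstrom.
#' @export
molar_to_density <- function(molar) molar * .const$avogadro * 1e-27

#' Bjerrum length
#'
#' \eqn{\lambda_B = e^2 / (4\pi\varepsilon_0\varepsilon_r k_B T)}: the
#' distance at which two unit charges interact with thermal energy kBT.
#' Water at 25 C (\eqn{\varepsilon_r = 78.7}) gives 7.1 Angstrom.
#'
#' @param temperature absolute temperature, K.
#' @param eps_r relative dielectric constant of the solvent.
#' @return Bjerrum length, Angstrom.
#' @export
bjerrum_length <- function(temperature = 298.15, eps_r = 78.7) {
  if (any(!is.finite(temperature)) || any(temperature <= 0) ||
      any(!is.finite(eps_r)) || any(eps_r <= 0)) {
    abort("temperature and eps_r must be positive")
  }
  .const$e^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * temperature) * 1e10
}

#' Debye screening length at infinite protein dilution
#'
#' Aqueous 1:1 electrolyte at 25 C: \eqn{\lambda_D = 3.04/\sqrt{I}} Angstrom
#' with the ionic strength \eqn{I} in mol/L.
#'
#' @param ionic_strength ionic strength, mol/L.
#' @return Debye length, Angstrom.
#' @export
debye_length_dilute <- function(ionic_strength) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength <= 0)) {
    abort("ionic_strength must be > 0")
  }
  3.04 / sqrt(ionic_strength)
}

#' Effective hard-sphere volume fraction
#'
#' \eqn{\phi_{HS} = \rho \pi \sigma_{HS}^3 / 6} with
#' \eqn{\sigma_{HS} = 2 R_g} as the effective protein diameter.
#'
#' @param rho_mab protein number density, per cubic Angstrom.
#' @param sigma_hs effective hard-sphere diameter, Angstrom.
#' @return volume fraction (dimensionless).
#' @export
hs_volume_fraction <- function(rho_mab, sigma_hs) {
  if (any(rho_mab < 0) || any(sigma_hs < 0)) abort("inputs must be >= 0")
  rho_mab * pi * sigma_hs^3 / 6
}

#' Debye length in a crowded protein solution
#'
#' Screening from counterions, salt and buffer ions:
#' \deqn{1/\lambda_D^2 = 4\pi\lambda_B\left[\frac{Z_{mAb}\,\rho_{mAb}}{1-\phi}
#'   + 2\rho_{salt} + 2\rho_{buffer}\right],}
#' where the factor \eqn{1/(1-\phi)} confines the released counterions to the
#' free (protein-excluded) volume.
#'
#' @param z_mab net protein charge (its magnitude sets the counterion count), e.
#' @param rho_mab,rho_salt,rho_buffer number densities, per cubic Angstrom.
#' @param phi effective hard-sphere volume fraction, in `[0, 1)`.
#' @param lambda_b Bjerrum length, Angstrom.
#' @return Debye length, Angstrom.
#' @export
debye_length_solution <- function(z_mab, rho_mab, rho_salt = 0, rho_buffer = 0,
                                  phi = 0, lambda_b = bjerrum_length()) {
  if (any(phi < 0) || any(phi >= 1)) {
    abort("free-volume correction requires 0 <= phi < 1")
  }
  inv2 <- 4 * pi * lambda_b *
    (abs(z_mab) * rho_mab / (1 - phi) + 2 * rho_salt + 2 * rho_buffer)
  if (any(inv2 <= 0)) abort("no mobile ions: Debye length undefined")
  1 / sqrt(inv2)
}

#' Solution conditions
#'
#' Bundles the thermodynamic state used throughout: pH, temperature,
#' dielectric constant, ionic strength, buffer and protein concentration.
#' Derived quantities (Bjerrum length, ion number densities, protein number
#' density) are computed on construction.  Defaults follow the low-salt
#' antibody study state: pH 6, 25 C, water, I = 7 mM, 20 mg/mL of a 148 kDa
#' protein with Rg = 48.2 Angstrom.
#'
#' @param ph solution pH.
#' @param temperature absolute temperature, K.
#' @param eps_r relative dielectric constant.
#' @param ionic_strength 1:1 salt ionic strength, mol/L.
#' @param buffer dissociated monovalent buffer concentration, mol/L.
#' @param c_p protein concentration, mg/mL.
#' @param mw protein molecular weight, g/mol.
#' @param rg average protein radius of gyration, Angstrom (sets the
#'   effective hard-sphere diameter `2*rg` of the crowding correction).
#' @return a `solution_conditions` list.
#' @export
solution_conditions <- function(ph = 6, temperature = 298.15, eps_r = 78.7,
                                ionic_strength = 0.007, buffer = 0,
                                c_p = 20, mw = 148000, rg = 48.2) {
  if (temperature <= 0 || eps_r <= 0) abort("temperature and eps_r must be positive")
  if (ionic_strength < 0 || buffer < 0 || c_p < 0) abort("densities must be >= 0")
  structure(
    list(
      ph = ph, temperature = temperature, eps_r = eps_r,
      ionic_strength = ionic_strength, buffer = buffer,
      c_p = c_p, mw = mw, rg = rg,
      lambda_b = bjerrum_length(temperature, eps_r),
      rho_salt = molar_to_density(ionic_strength),
      rho_buffer = molar_to_density(buffer),
      rho_mab = c_p * .const$avogadro / (mw * 1e27)
    ),
    class = "solution_conditions"
  )
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf(
    "<solution_conditions> pH %.2f, T %.2f K, eps_r %.1f, I %.4g M, c_p %.4g mg/mL\n",
    x$ph, x$temperature, x$eps_r, x$ionic_strength, x$c_p
  ))
  cat(sprintf("  lambda_B %.3f A, rho_mab %.3e A^-3\n", x$lambda_b, x$rho_mab))
  invisible(x)
}

#' Pair-potential parameters
#'
#' @param eps_ij depth of the attractive well, kBT.
#' @param lambda_d Debye screening length, Angstrom.
#' @param lambda_b Bjerrum length, Angstrom.
#' @param model `"amino_acid"` (screened Coulomb + full Lennard-Jones) or
#'   `"bead"` (hard core + size-corrected Yukawa + attractive r^-6).
#' @param r_cut_elec,r_cut_vdw interaction truncation radii, Angstrom.
#'   `NULL` (default) resolves at simulation time to
#'   `min(L/2, 8*lambda_d + sigma)` and `min(L/2, 4*sigma)`; energies beyond
#'   the cutoff are dropped unshifted.
#' @return a `pair_params` list.
#' @export
pair_params <- function(eps_ij, lambda_d, lambda_b = bjerrum_length(),
                        model = c("amino_acid", "bead"),
                        r_cut_elec = NULL, r_cut_vdw = NULL) {
  model <- match.arg(model)
  if (eps_ij < 0) abort("eps_ij must be >= 0")
  if (lambda_d <= 0 || lambda_b <= 0) abort("screening lengths must be > 0")
  structure(
    list(eps_ij = eps_ij, lambda_d = lambda_d, lambda_b = lambda_b,
         model = model, r_cut_elec = r_cut_elec, r_cut_vdw = r_cut_vdw),
    class = "pair_params"
  )
}

resolve_cutoffs <- function(params, box_l, sigma_max) {
  rc_e <- params$r_cut_elec %||% min(box_l / 2, 8 * params$lambda_d + sigma_max)
  rc_v <- params$r_cut_vdw %||% min(box_l / 2, 4 * sigma_max)
  list(rc_e = rc_e, rc_v = rc_v)
}

# bead-model Debye-Hueckel finite-size factor exp(s/2lD) / (1 + s/2lD)
dh_size_factor <- function(sigma, lambda_d) {
  x <- sigma / (2 * lambda_d)
  exp(x) / (1 + x)
}

#' Amino-acid-level pair energy
#'
#' Screened Coulomb plus full Lennard-Jones:
#' \deqn{\beta V(r) = \lambda_B q_i q_j \frac{e^{-r/\lambda_D}}{r}
#'  + 4\epsilon_{ij}\left[\left(\frac{\sigma_{ij}}{r}\right)^{12}
#'  - \left(\frac{\sigma_{ij}}{r}\right)^{6}\right],}
#' with \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2}.
#'
#' @param q_i,q_j bead charges, e.
#' @param sigma_ij combined diameter, Angstrom.
#' @param r separation(s), Angstrom; must be > 0.
#' @param params a [pair_params()] object.
#' @return energy in kBT (vectorised over `r`).
#' @export
pair_energy_aa <- function(q_i, q_j, sigma_ij, r, params) {
  if (any(r <= 0)) abort("r = 0: Coulomb/LJ singularity")
  sr6 <- (sigma_ij / r)^6
  params$lambda_b * q_i * q_j * exp(-r / params$lambda_d) / r +
    4 * params$eps_ij * (sr6^2 - sr6)
}

#' Bead-model pair energy
#'
#' Hard core for \eqn{r < \sigma_{bead}} (returned as `Inf`); beyond contact a
#' size-corrected Yukawa repulsion minus an attractive \eqn{r^{-6}} term:
#' \deqn{\beta V(r) = \lambda_B q_{bead}^2
#'   \left(\frac{e^{\sigma/2\lambda_D}}{1+\sigma/2\lambda_D}\right)^2
#'   \frac{e^{-r/\lambda_D}}{r}
#'   - \epsilon_{ij}\left(\frac{\sigma}{r}\right)^6.}
#'
#' @param q_bead per-bead charge (`Q_eff / N_beads`), e.
#' @param sigma_bead bead diameter, Angstrom.
#' @param r separation(s), Angstrom; zero and overlap distances allowed
#'   (returned as `Inf`).
#' @param params a [pair_params()] object.
#' @return energy in kBT, possibly infinite (vectorised over `r`).
#' @export
pair_energy_bead <- function(q_bead, sigma_bead, r, params) {
  pref <- dh_size_factor(sigma_bead, params$lambda_d)
  out <- params$lambda_b * q_bead^2 * pref^2 * exp(-r / params$lambda_d) / r -
    params$eps_ij * (sigma_bead / r)^6
  out[r < sigma_bead] <- Inf
  out
}

#' Inter-molecular pair energy under periodic boundaries
#'
#' Sums the model's bead-bead pair energy over all inter-molecular bead pairs
#' with minimum-image distances in a cubic box of edge `box_l`, applying the
#' truncation radii resolved from `params`.  Any hard-core overlap (bead
#' model) short-circuits to `Inf`.
#'
#' @param mol_a,mol_b posed `cg_molecule`s (world pose from `com` and
#'   `orientation`).
#' @param box_l cubic box edge, Angstrom.
#' @param params a [pair_params()] object; `params$model` selects the
#'   potential.
#' @return total energy in kBT.
#' @export
molecule_pair_energy <- function(mol_a, mol_b, box_l, params) {
  ca <- world_coords(mol_a)
  cb <- world_coords(mol_b)
  sig_a <- mol_a$beads$diameter
  sig_b <- mol_b$beads$diameter
  qa <- mol_a$beads$charge
  qb <- mol_b$beads$charge
  if (params$model == "bead") {
    qa <- qa * dh_size_factor(sig_a, params$lambda_d)
    qb <- qb * dh_size_factor(sig_b, params$lambda_d)
  }
  rc <- resolve_cutoffs(params, box_l, max(sig_a, sig_b))
  res <- cpp_mol_pair_energy(
    ca, cb, qa, qb, sig_a, sig_b, box_l, params$lambda_b, params$lambda_d,
    if (params$model == "bead") 1L else 0L, rc$rc_e, rc$rc_v
  )
  if (res$overlap) return(Inf)
  res$elec + params$eps_ij * res$w
}
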