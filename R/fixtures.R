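# Synthetic inputs: toy Y-shaped titratable molecules as PDB text, and
# synthetic SAXS target curves with known ground truth for recovery tests.

#' Generate a toy Y-shaped antibody-like molecule
#'
#' Builds a deterministic (per seed) Y-shaped chain of standard residues:
#' three straight arms of `n_res_per_arm` residues with a backbone spacing of
#' 3.8 Angstrom and a small reproducible jitter, the two Fab arms separated
#' by `arm_angle`.  Residue identities are drawn from pools matching
#' `charge_pattern`, so the pKa/charge machinery is exercised unmodified.
#' Returns both the PDB text (one CA atom per residue) and the coarse-grained
#' molecule.  This is a synthetic stand-in with the antibody's Y topology,
#' not any real sequence.
#'
#' @param n_res_per_arm residues per arm (>= 1).
#' @param arm_angle angle between the Fab arms, degrees, in (0, 180).
#' @param charge_pattern `"mixed"`, `"acidic"`, `"basic"` or `"neutral"`.
#' @param seed integer seed.
#' @return list with `pdb` (character vector of PDB lines), `residues`
#'   (tibble) and `molecule` (`cg_molecule`).
#' @export
toy_mab <- function(n_res_per_arm = 10, arm_angle = 60,
                    charge_pattern = c("mixed", "acidic", "basic", "neutral"),
                    seed = 1) {
  charge_pattern <- match.arg(charge_pattern)
  if (n_res_per_arm < 1) abort("n_res_per_arm must be >= 1")
  if (arm_angle <= 0 || arm_angle >= 180) abort("arm_angle must be in (0, 180)")
  pool <- switch(charge_pattern,
    mixed = c("ASP", "LYS", "GLY", "GLU", "SER", "ARG", "ALA", "HIS", "VAL", "TYR"),
    acidic = c("ASP", "GLU", "GLY", "SER"),
    basic = c("LYS", "ARG", "GLY", "HIS"),
    neutral = c("GLY", "ALA", "SER", "VAL")
  )
  half <- arm_angle / 2 * pi / 180
  dirs <- rbind(
    c(sin(half), cos(half), 0),
    c(-sin(half), cos(half), 0),
    c(0, -1, 0)
  )
  spacing <- 3.8
  res <- with_seed(seed, {
    names_ <- sample(pool, 3 * n_res_per_arm, replace = TRUE)
    jitter <- matrix(rnorm(9 * n_res_per_arm, sd = 0.3), ncol = 3)
    coords <- do.call(rbind, lapply(1:3, function(a) {
      t(vapply(seq_len(n_res_per_arm),
               function(i) (i - 0.5) * spacing * dirs[a, ], numeric(3)))
    })) + jitter
    tibble(
      resno = seq_len(3 * n_res_per_arm), chain = "A", name = names_,
      x = round(coords[, 1], 3), y = round(coords[, 2], 3),
      z = round(coords[, 3], 3),
      mw = unname(residue_weights()[names_])
    )
  })
  pdb <- c(
    sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      res$resno, res$name, res$resno, res$x, res$y, res$z
    ),
    "END"
  )
  list(pdb = pdb, residues = res, molecule = aa_coarse_grain(res))
}

#' Generate a synthetic SAXS target with known ground truth
#'
#' Runs the bead-model pipeline at the given `(qeff, eps)`, interpolates the
#' resulting effective structure factor onto the 51-point experimental grid
#' and applies multiplicative Gaussian noise of relative scale `noise_frac`.
#' The ground truth is stored in the curve metadata (and written as header
#' comments by [write_saxs()]).
#'
#' @param template an uncharged `cg_molecule` bead model.
#' @param qeff ground-truth effective charge, e.
#' @param eps ground-truth attraction strength, kBT.
#' @param c_p protein concentration, mg/mL.
#' @param conditions [solution_conditions()].
#' @param noise_frac relative noise scale (>= 0).
#' @param seed integer seed (controls both the simulation and the noise).
#' @param n_p,n_sweeps,burn_in,sample_stride,n_orientations,p_max,intensity_stride
#'   sampler settings.
#' @param q_out output q-grid (default [default_saxs_grid()]).
#' @return a `saxs_curve` of kind `"experimental"` with truth metadata.
#' @export
synthetic_target <- function(template, qeff, eps, c_p = 20,
                             conditions = solution_conditions(),
                             noise_frac = 0.02, seed = 1, n_p = 100,
                             n_sweeps = 1500, burn_in = 500,
                             sample_stride = 10, n_orientations = 1024,
                             p_max = 25, q_out = default_saxs_grid(),
                             intensity_stride = 2) {
  if (noise_frac < 0) abort("noise_frac must be >= 0")
  mol <- set_bead_charges(template, qeff)
  box <- make_box(mol, n_p = n_p, c_p = c_p, conditions = conditions,
                  eps_ij = eps, seed = seed)
  grid <- build_qgrid(box$l, p_max)
  traj <- run_simulation(box, n_sweeps = n_sweeps, burn_in = burn_in,
                         sample_stride = sample_stride, seed = seed,
                         record_frames = FALSE, intensity_grid = grid,
                         intensity_stride = intensity_stride)
  ff <- form_factor(mol, box$l, n_orientations = n_orientations,
                    p_max = p_max, seed = seed)
  seff <- effective_structure_factor(traj, form = ff)
  v <- interp_curve(seff$q, seff$value, q_out)
  if (any(is.na(v))) abort("simulated grid does not cover the output q range")
  noise <- if (noise_frac > 0) {
    with_seed(seed + 77, rnorm(length(q_out), mean = 1, sd = noise_frac))
  } else {
    rep(1, length(q_out))
  }
  new_saxs_curve(
    q_out, v * noise,
    error = if (noise_frac > 0) noise_frac * abs(v) else NULL,
    kind = "experimental",
    meta = list(truth_qeff = qeff, truth_eps = eps, noise_frac = noise_frac,
                c_p = c_p, n_p = n_p, seed = seed)
  )
}
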