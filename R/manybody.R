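# Rigid-body Metropolis Monte Carlo of N_p molecules in a cubic periodic box,
# with optional Hamiltonian replica exchange over the attraction strength.

#' Move parameters for rigid-body MC
#'
#' @param max_translation maximum per-axis displacement, Angstrom.
#' @param max_rotation maximum rotation angle, radians (axis uniform on the
#'   sphere, angle uniform in `(0, max_rotation]`, about the molecule com).
#' @param target_acceptance acceptance fraction targeted by burn-in tuning.
#' @return a `move_params` list.
#' @export
move_params <- function(max_translation = 20, max_rotation = 0.5,
                        target_acceptance = 0.35) {
  stopifnot(max_translation > 0, max_rotation > 0,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(max_translation = max_translation, max_rotation = max_rotation,
                 target_acceptance = target_acceptance),
            class = "move_params")
}

#' The attraction-strength grid of the replica-exchange runs
#'
#' Eight values spanning 0.05 to 0.085 kBT in steps of 0.005 kBT.
#'
#' @return numeric vector of eps_ij values, kBT.
#' @export
default_eps_grid <- function() seq(0.05, 0.085, by = 0.005)

random_quats <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# effective per-bead charges passed to the kernels (bead model folds in the
# Debye-Hueckel size factor)
effective_charges <- function(template, params) {
  q <- template$beads$charge
  if (params$model == "bead") {
    q <- q * dh_size_factor(template$beads$diameter, params$lambda_d)
  }
  q
}

box_geometry <- function(box) {
  rc <- resolve_cutoffs(box$params, box$l, max(box$template$beads$diameter))
  list(
    tmpl = bead_coords(box$template),
    sigma = box$template$beads$diameter,
    qeff = effective_charges(box$template, box$params),
    model = if (box$params$model == "bead") 1L else 0L,
    rc_e = rc$rc_e, rc_v = rc$rc_v
  )
}

#' Create a periodic simulation box of rigid molecules
#'
#' The cubic volume follows the concentration:
#' \eqn{V = N_p M_w / (c_p N_A 10^{-27})} cubic Angstrom.  Molecules are
#' inserted at random positions and orientations with hard-overlap rejection
#' (bead model).  The Debye length is recomputed for the crowded solution
#' from the molecule's current net charge, the salt/buffer densities and the
#' free-volume correction \eqn{\phi = \rho \pi (2 R_g)^3 / 6}.
#'
#' @param template a posed `cg_molecule` shared by all molecules.
#' @param n_p number of molecules.
#' @param c_p protein concentration, mg/mL.
#' @param conditions [solution_conditions()].
#' @param eps_ij attraction strength, kBT.
#' @param mw molecular weight, g/mol (default from `conditions`).
#' @param params optional [pair_params()]; by default built from
#'   `conditions` with the crowded-solution Debye length.
#' @param seed integer seed for the insertion.
#' @param max_attempts insertion attempts per molecule before failing.
#' @return a `sim_box`.
#' @export
make_box <- function(template, n_p, c_p, conditions = solution_conditions(),
                     eps_ij = 0.8, mw = NULL, params = NULL, seed = 1,
                     max_attempts = 500) {
  if (c_p <= 0) abort("c_p must be > 0")
  mw <- mw %||% conditions$mw
  V <- n_p * mw / (c_p * .const$avogadro * 1e-27)
  L <- V^(1 / 3)
  rho <- n_p / V
  phi <- hs_volume_fraction(rho, 2 * conditions$rg)
  if (is.null(params)) {
    lambda_d <- debye_length_solution(
      z_mab = template$net_charge, rho_mab = rho,
      rho_salt = conditions$rho_salt, rho_buffer = conditions$rho_buffer,
      phi = phi, lambda_b = conditions$lambda_b
    )
    params <- pair_params(
      eps_ij = eps_ij, lambda_d = lambda_d, lambda_b = conditions$lambda_b,
      model = if (template$model == "bead") "bead" else "amino_acid"
    )
  }
  box <- structure(
    list(l = L, template = template, com = NULL, quat = NULL, params = params,
         conditions = conditions, n_p = n_p, c_p = c_p, mw = mw, phi = phi,
         replica_id = 1L, seed = seed),
    class = "sim_box"
  )
  geo <- box_geometry(box)
  hard <- geo$model == 1L
  com <- matrix(NA_real_, n_p, 3)
  quat <- matrix(NA_real_, n_p, 4)
  with_seed(seed, {
    for (i in seq_len(n_p)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        ci <- runif(3, 0, L)
        qi <- random_quats(1)[1, ]
        ok <- TRUE
        if (hard && i > 1) {
          wi <- sweep(geo$tmpl %*% t(quat_to_mat(qi)), 2, ci, "+")
          for (j in seq_len(i - 1)) {
            wj <- sweep(geo$tmpl %*% t(quat_to_mat(quat[j, ])), 2, com[j, ], "+")
            res <- cpp_mol_pair_energy(wi, wj, geo$qeff * 0, geo$qeff * 0,
                                       geo$sigma, geo$sigma, L, 1, 1, 1L,
                                       0, 0)
            if (res$overlap) { ok <- FALSE; break }
          }
        }
        if (ok) {
          com[i, ] <- ci
          quat[i, ] <- qi
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0(
          "could not insert molecule ", i, " without overlap after ",
          max_attempts, " attempts; the system is dense - consider a lattice start"
        ))
      }
    }
  })
  box$com <- com
  box$quat <- quat
  box
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf(
    "<sim_box> %d molecules (%s model, %d beads each), L = %.1f A, c_p = %.4g mg/mL\n",
    x$n_p, x$template$model, nrow(x$template$beads), x$l, x$c_p
  ))
  cat(sprintf("  eps_ij %.3g kBT, lambda_D %.2f A, phi %.3g\n",
              x$params$eps_ij, x$params$lambda_d, x$phi))
  invisible(x)
}

no_qvecs <- function() {
  list(qvecs = matrix(0, 0, 3), shell_map = matrix(0L, 0, 0), n_shells = 0L)
}

# express a q_grid as base (p = 1) directions plus a (p, direction) -> shell
# lookup (0-based), the form the streaming kernel consumes
grid_qvec_table <- function(grid) {
  if (is.null(grid)) return(no_qvecs())
  fam_dirs <- list(
    "100" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "110" = rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
    "111" = rbind(c(1, 1, 1))
  )
  base <- do.call(rbind, fam_dirs) * (2 * pi / grid$box_l)
  fam_of_dir <- rep(names(fam_dirs), vapply(fam_dirs, nrow, 1L))
  sh <- grid$shells
  shell_map <- matrix(0L, grid$p_max, nrow(base))
  for (d in seq_len(nrow(base))) {
    for (p in seq_len(grid$p_max)) {
      shell_map[p, d] <-
        as.integer(sh$shell[sh$p == p & sh$family == fam_of_dir[d]] - 1L)
    }
  }
  list(qvecs = base, shell_map = shell_map, n_shells = nrow(sh))
}

#' Run one Monte Carlo sweep
#'
#' One attempted translation + rotation per molecule (random permutation
#' order), Metropolis-accepted on the energy change computed from the pairs
#' involving the moved molecule.
#'
#' @param box a `sim_box`.
#' @param moves [move_params()].
#' @param seed integer seed for this sweep.
#' @return list with the updated `box` and the sweep `acceptance` fraction.
#' @export
mc_sweep <- function(box, moves = move_params(), seed = 1) {
  geo <- box_geometry(box)
  qt <- no_qvecs()
  res <- cpp_run_mc(
    geo$tmpl, geo$sigma, geo$qeff, box$com, box$quat, box$l,
    box$params$lambda_b, box$params$lambda_d, box$params$eps_ij, geo$model,
    geo$rc_e, geo$rc_v, 1L, 0L, 1L,
    moves$max_translation, moves$max_rotation, FALSE,
    moves$target_acceptance, as.double(seed), FALSE,
    qt$qvecs, qt$shell_map, qt$n_shells, 0L
  )
  box$com <- res$final_com
  box$quat <- res$final_quat
  list(box = box, acceptance = res$acceptance)
}

new_trajectory <- function(res, box, n_sweeps, burn_in, sample_stride, seed,
                           intensity_grid = NULL) {
  ns <- res$n_samples
  eps <- box$params$eps_ij
  structure(
    list(
      frames = res$frames,       # ns x (3 * n_p * n_beads), bead-major rows
      intensity = res$intensity, # streamed per-shell intensity (may be empty)
      intensity_grid = intensity_grid,
      com_trace = res$com_trace, quat_trace = res$quat_trace,
      energies = tibble(
        sample = seq_len(ns),
        elec = as.numeric(res$e_elec)[seq_len(ns)],
        w = as.numeric(res$e_w)[seq_len(ns)],
        total = as.numeric(res$e_elec + eps * res$e_w)[seq_len(ns)]
      ),
      box_l = box$l, n_p = box$n_p,
      n_beads = nrow(box$template$beads),
      template = box$template, params = box$params,
      conditions = box$conditions,
      sample_stride = sample_stride, n_sweeps = n_sweeps, burn_in = burn_in,
      acceptance = res$acceptance,
      tuned_moves = c(max_translation = res$max_trans, max_rotation = res$max_rot),
      final_box = {
        b <- box
        b$com <- res$final_com
        b$quat <- res$final_quat
        b
      },
      seed = seed
    ),
    class = "mc_trajectory"
  )
}

#' Run a rigid-body MC simulation
#'
#' Samples every `sample_stride` sweeps after `burn_in` sweeps.  Move sizes
#' are auto-tuned toward `moves$target_acceptance` during burn-in only and
#' frozen afterwards (preserving detailed balance in production).
#' Deterministic for a given `seed`.
#'
#' @param box a `sim_box` from [make_box()].
#' @param n_sweeps total sweeps (must exceed `burn_in`).
#' @param sample_stride sweeps between samples.
#' @param burn_in equilibration sweeps (discarded).
#' @param moves [move_params()].
#' @param seed integer seed.
#' @param record_frames keep world bead coordinates per sample (needed for
#'   scattering from stored frames).
#' @param intensity_grid optional [build_qgrid()]: stream per-shell scattering
#'   intensities every `intensity_stride` sweeps during the run instead of
#'   storing coordinates (memory-light, denser statistics).
#' @param intensity_stride sweeps between streamed intensity measurements.
#' @return an `mc_trajectory`.
#' @export
run_simulation <- function(box, n_sweeps, sample_stride = 10,
                           burn_in = max(1, n_sweeps %/% 5),
                           moves = move_params(), seed = 1,
                           record_frames = TRUE, intensity_grid = NULL,
                           intensity_stride = 1) {
  if (n_sweeps <= burn_in) abort("n_sweeps must exceed burn_in")
  geo <- box_geometry(box)
  qt <- grid_qvec_table(intensity_grid)
  res <- cpp_run_mc(
    geo$tmpl, geo$sigma, geo$qeff, box$com, box$quat, box$l,
    box$params$lambda_b, box$params$lambda_d, box$params$eps_ij, geo$model,
    geo$rc_e, geo$rc_v, as.integer(n_sweeps), as.integer(burn_in),
    as.integer(sample_stride), moves$max_translation, moves$max_rotation,
    TRUE, moves$target_acceptance, as.double(seed), record_frames,
    qt$qvecs, qt$shell_map, qt$n_shells, as.integer(intensity_stride)
  )
  new_trajectory(res, box, n_sweeps, burn_in, sample_stride, seed,
                 intensity_grid = intensity_grid)
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mc_trajectory> %d samples of %d x %d beads, L = %.1f A, eps = %.3g kBT\n",
    nrow(x$energies), x$n_p, x$n_beads, x$box_l, x$params$eps_ij
  ))
  cat(sprintf("  %d sweeps (burn-in %d, stride %d), acceptance %.3f\n",
              x$n_sweeps, x$burn_in, x$sample_stride, x$acceptance))
  invisible(x)
}

# extract sample i as an (n_p * n_beads) x 3 coordinate matrix
frame_coords <- function(traj, i) {
  matrix(traj$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Run Hamiltonian replica exchange over the attraction strength
#'
#' Replicas share geometry and charges but differ in `eps_ij`.  Every
#' `swap_stride` sweeps, alternating even/odd neighbour pairs attempt a
#' configuration swap, accepted with
#' `min(1, exp(-(eps_i - eps_j) * (W_j - W_i)))`, exact because both pair
#' potentials are affine in eps with coefficient `W` (the unit-eps
#' short-range sum tracked by the sampler).
#'
#' @param box a `sim_box` template (its `eps_ij` is overridden per replica).
#' @param eps_grid attraction strengths, kBT ([default_eps_grid()]).
#' @param n_sweeps production sweeps per replica (after burn-in).
#' @param swap_stride sweeps between swap attempts.
#' @param sample_stride sweeps between samples (a divisor of `swap_stride`
#'   keeps sampling regular; samples are collected within each chunk).
#' @param burn_in equilibration sweeps per replica (tuned, unswapped).
#' @param moves [move_params()].
#' @param seed integer seed.
#' @param record_frames keep per-sample coordinates.
#' @param intensity_grid,intensity_stride streamed-scattering options as in
#'   [run_simulation()].
#' @return a `replica_set`: list of `mc_trajectory` (one per eps, in grid
#'   order), swap acceptance statistics and the grid.
#' @export
run_replicas <- function(box, eps_grid = default_eps_grid(), n_sweeps = 1000,
                         swap_stride = 10, sample_stride = 10,
                         burn_in = max(1, n_sweeps %/% 5),
                         moves = move_params(), seed = 1,
                         record_frames = TRUE, intensity_grid = NULL,
                         intensity_stride = 1) {
  n_rep <- length(eps_grid)
  if (n_rep < 2) abort("need at least two replicas (use run_simulation for one)")
  geo <- box_geometry(box)
  qt <- grid_qvec_table(intensity_grid)
  qt0 <- no_qvecs()
  state <- lapply(seq_len(n_rep), function(r) {
    list(com = box$com, quat = box$quat,
         mt = moves$max_translation, mr = moves$max_rotation)
  })
  # burn-in with tuning, per replica
  for (r in seq_len(n_rep)) {
    res <- cpp_run_mc(
      geo$tmpl, geo$sigma, geo$qeff, state[[r]]$com, state[[r]]$quat, box$l,
      box$params$lambda_b, box$params$lambda_d, eps_grid[r], geo$model,
      geo$rc_e, geo$rc_v, as.integer(burn_in), as.integer(burn_in), 1L,
      state[[r]]$mt, state[[r]]$mr, TRUE, moves$target_acceptance,
      as.double(seed * 1000 + r), FALSE,
      qt0$qvecs, qt0$shell_map, qt0$n_shells, 0L
    )
    state[[r]]$com <- res$final_com
    state[[r]]$quat <- res$final_quat
    state[[r]]$mt <- res$max_trans
    state[[r]]$mr <- res$max_rot
    state[[r]]$E_elec <- res$E_elec
    state[[r]]$E_w <- res$E_w
  }
  n_chunks <- n_sweeps %/% swap_stride
  samples <- lapply(seq_len(n_rep), function(r) list())
  acc <- vapply(seq_len(n_rep), function(r) NA_real_, numeric(1))
  acc_sum <- rep(0, n_rep)
  swap_att <- 0L
  swap_acc <- 0L
  for (chunk in seq_len(n_chunks)) {
    for (r in seq_len(n_rep)) {
      res <- cpp_run_mc(
        geo$tmpl, geo$sigma, geo$qeff, state[[r]]$com, state[[r]]$quat, box$l,
        box$params$lambda_b, box$params$lambda_d, eps_grid[r], geo$model,
        geo$rc_e, geo$rc_v, as.integer(swap_stride), 0L,
        as.integer(sample_stride), state[[r]]$mt, state[[r]]$mr, FALSE,
        moves$target_acceptance,
        as.double(seed * 1e6 + chunk * 100 + r), record_frames,
        qt$qvecs, qt$shell_map, qt$n_shells, as.integer(intensity_stride)
      )
      state[[r]]$com <- res$final_com
      state[[r]]$quat <- res$final_quat
      state[[r]]$E_elec <- res$E_elec
      state[[r]]$E_w <- res$E_w
      acc_sum[r] <- acc_sum[r] + res$acceptance
      samples[[r]][[chunk]] <- res
    }
    # alternate even/odd neighbour pairs
    first <- if (chunk %% 2 == 1) 1L else 2L
    pairs <- if (first > n_rep - 1) integer(0) else seq.int(first, n_rep - 1, by = 2)
    u <- with_seed(seed * 7 + chunk, runif(length(pairs)))
    for (k in seq_along(pairs)) {
      i <- pairs[k]; j <- i + 1L
      delta <- (eps_grid[i] - eps_grid[j]) *
        (state[[j]]$E_w - state[[i]]$E_w)
      swap_att <- swap_att + 1L
      if (delta <= 0 || u[k] < exp(-delta)) {
        tmp <- state[[i]][c("com", "quat", "E_elec", "E_w")]
        state[[i]][c("com", "quat", "E_elec", "E_w")] <-
          state[[j]][c("com", "quat", "E_elec", "E_w")]
        state[[j]][c("com", "quat", "E_elec", "E_w")] <- tmp
        swap_acc <- swap_acc + 1L
      }
    }
  }
  trajs <- lapply(seq_len(n_rep), function(r) {
    chunks <- samples[[r]]
    res <- list(
      frames = do.call(rbind, lapply(chunks, function(x) x$frames)),
      intensity = do.call(rbind, lapply(chunks, function(x) x$intensity)),
      com_trace = do.call(rbind, lapply(chunks, function(x) x$com_trace)),
      quat_trace = do.call(rbind, lapply(chunks, function(x) x$quat_trace)),
      e_elec = unlist(lapply(chunks, function(x) x$e_elec)),
      e_w = unlist(lapply(chunks, function(x) x$e_w)),
      acceptance = acc_sum[r] / n_chunks,
      max_trans = state[[r]]$mt, max_rot = state[[r]]$mr,
      final_com = state[[r]]$com, final_quat = state[[r]]$quat,
      n_samples = sum(vapply(chunks, function(x) x$n_samples, numeric(1)))
    )
    b <- box
    b$params$eps_ij <- eps_grid[r]
    b$replica_id <- r
    new_trajectory(res, b, n_sweeps, burn_in, sample_stride, seed,
                   intensity_grid = intensity_grid)
  })
  structure(
    list(replicas = trajs, eps_grid = eps_grid,
         swap_acceptance = if (swap_att > 0) swap_acc / swap_att else NA_real_,
         swap_attempts = swap_att, seed = seed),
    class = "replica_set"
  )
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf(
    "<replica_set> %d replicas, eps %.3g..%.3g kBT, swap acceptance %.3f\n",
    length(x$replicas), min(x$eps_grid), max(x$eps_grid), x$swap_acceptance
  ))
  invisible(x)
}

#' Total configurational energy of a box
#'
#' Full pair-sum recomputation (used to validate the sampler's incremental
#' bookkeeping).
#'
#' @param box a `sim_box`.
#' @return list with `elec`, `w` and `total` (kBT); `total` is `Inf` on
#'   hard-core overlap.
#' @export
box_energy <- function(box) {
  geo <- box_geometry(box)
  res <- cpp_box_energy(geo$tmpl, geo$sigma, geo$qeff, box$com, box$quat,
                        box$l, box$params$lambda_b, box$params$lambda_d,
                        geo$model, geo$rc_e, geo$rc_v)
  total <- if (res$overlap) Inf else res$elec + box$params$eps_ij * res$w
  list(elec = res$elec, w = res$w, total = total)
}
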