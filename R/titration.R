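# Constant-pH Metropolis Monte Carlo on a single rigid molecule.
#
# Protonation states of titratable sites fluctuate; a flip move changes the
# reduced energy by Delta(beta*U_elec) +/- ln(10)*(pKa - pH), with the plus
# sign for deprotonation.  Site-site electrostatics use the Yukawa potential
# lambda_B q_i q_j exp(-r/lambda_D)/r over all charged bead pairs involving
# the flipped site; the implicit proton bath contributes no
# configuration-dependent term beyond the pH/pKa factor.

# Precompute geometry-dependent couplings for a rigid molecule.
titration_system <- function(mol, cond, lambda_d = NULL) {
  lambda_d <- lambda_d %||% debye_length_dilute(cond$ionic_strength)
  b <- mol$beads
  sites <- which(b$titratable)
  if (length(sites) == 0) abort("molecule has no titratable sites")
  # columns of the coupling matrix: all titratable sites plus any fixed charges
  fixed <- which(!b$titratable & b$charge != 0)
  cols <- c(sites, fixed)
  coords <- bead_coords(mol)
  ns <- length(sites)
  J <- matrix(0, ns, length(cols))
  lb <- cond$lambda_b
  for (i in seq_len(ns)) {
    d <- sqrt(rowSums(sweep(coords[cols, , drop = FALSE], 2, coords[sites[i], ])^2))
    Jrow <- ifelse(d > 0, lb * exp(-d / lambda_d) / d, 0)
    J[i, ] <- Jrow
    J[i, i] <- 0  # site's own column: self-energy excluded
  }
  list(
    sites = sites, cols = cols, J = J,
    site_col = seq_len(ns) - 1L,  # 0-based column of each site
    q_fixed_cols = ifelse(seq_along(cols) > ns, b$charge[cols], 0),
    q_prot = b$q_protonated[sites],
    q_deprot = b$q_deprotonated[sites],
    dmu_deprot = log(10) * (b$pka[sites] - cond$ph),
    fixed_net = sum(b$charge[-sites]),
    lambda_d = lambda_d, ph = cond$ph,
    labels = b$label[sites]
  )
}

#' Initialise a titration state
#'
#' All sites start in the given protonation state (`"deprotonated"` by
#' default: acids carry their full negative charge, bases are neutral).
#'
#' @param mol a titratable `cg_molecule` (from [aa_coarse_grain()]).
#' @param cond [solution_conditions()].
#' @param lambda_d Debye length, Angstrom; defaults to the infinite-dilution
#'   value [debye_length_dilute()] at `cond$ionic_strength`.
#' @param start `"deprotonated"` or `"protonated"`.
#' @return a `titration_state`.
#' @export
titration_state <- function(mol, cond = solution_conditions(),
                            lambda_d = NULL,
                            start = c("deprotonated", "protonated")) {
  start <- match.arg(start)
  sys <- titration_system(mol, cond, lambda_d)
  prot <- rep(start == "protonated", length(sys$sites))
  q <- ifelse(prot, sys$q_prot, sys$q_deprot)
  structure(
    list(
      protonated = prot,
      site_charges = q,
      net_charge = sys$fixed_net + sum(q),
      sweep_index = 0L,
      system = sys
    ),
    class = "titration_state"
  )
}

#' Attempt one titration flip move
#'
#' Proposes flipping the protonation state of `site` and accepts with the
#' Metropolis probability `min(1, exp(-dU))`, where
#' `dU = dq * sum_j q_j J_sj + ln(10)*(pKa - pH)` for deprotonation (sign
#' reversed for protonation).  Uses R's global RNG.
#'
#' @param state a [titration_state()].
#' @param site index into the molecule's titratable sites.
#' @return list with the updated `state` and an `accepted` flag.
#' @export
titration_move <- function(state, site) {
  sys <- state$system
  ns <- length(sys$sites)
  if (!is.numeric(site) || site < 1 || site > ns || site != round(site)) {
    abort(sprintf("site must index a titratable site (1..%d)", ns))
  }
  qcols <- c(state$site_charges, sys$q_fixed_cols[-seq_len(ns)])
  prot <- state$protonated[site]
  q_old <- state$site_charges[site]
  q_new <- if (prot) sys$q_deprot[site] else sys$q_prot[site]
  dq <- q_new - q_old
  coupling <- sum(sys$J[site, ] * qcols)  # own column is zero
  dU <- dq * coupling + if (prot) sys$dmu_deprot[site] else -sys$dmu_deprot[site]
  accepted <- dU <= 0 || runif(1) < exp(-dU)
  if (accepted) {
    state$protonated[site] <- !prot
    state$site_charges[site] <- q_new
    state$net_charge <- state$net_charge + dq
  }
  list(state = state, accepted = accepted)
}

#' Run constant-pH Monte Carlo titration
#'
#' `n_sweeps` sweeps of `moves_per_sweep` attempted flips each on a single
#' rigid molecule, starting fully deprotonated.  Deterministic for a given
#' `seed` (an internal RNG stream independent of R's global RNG).
#'
#' @param mol a titratable `cg_molecule`.
#' @param cond [solution_conditions()].
#' @param n_sweeps number of MC sweeps (default 1e4).
#' @param moves_per_sweep attempted flips per sweep (default 10).
#' @param seed integer seed.
#' @param burn_in sweeps discarded by the averaging helpers (default 200).
#' @param lambda_d Debye length override, Angstrom (default: infinite-dilution
#'   value at `cond$ionic_strength`).
#' @param start initial protonation, `"deprotonated"` (default) or
#'   `"protonated"`.
#' @return a `titration_result`: `net_charge_trace` (tibble `sweep`,
#'   `net_charge`), `mean_site_charges` (tibble, post burn-in),
#'   `acceptance_rate`, `burn_in`, plus run metadata.
#' @export
run_constant_ph <- function(mol, cond = solution_conditions(), n_sweeps = 1e4,
                            moves_per_sweep = 10, seed = 1, burn_in = 200,
                            lambda_d = NULL,
                            start = c("deprotonated", "protonated")) {
  start <- match.arg(start)
  if (burn_in >= n_sweeps) abort("burn_in must be smaller than n_sweeps")
  sys <- titration_system(mol, cond, lambda_d)
  ns <- length(sys$sites)
  prot0 <- rep(start == "protonated", ns)
  res <- cpp_titrate(
    sys$J, sys$site_col, sys$q_fixed_cols, sys$q_prot, sys$q_deprot,
    prot0, sys$dmu_deprot, sys$fixed_net, as.integer(n_sweeps),
    as.integer(moves_per_sweep), as.double(seed)
  )
  keep <- seq.int(burn_in + 1, n_sweeps)
  site_means <- colMeans(res$site_trace[keep, , drop = FALSE])
  structure(
    list(
      net_charge_trace = tibble(sweep = seq_len(n_sweeps),
                                net_charge = as.numeric(res$trace)),
      mean_site_charges = tibble(
        site = seq_len(ns), bead = sys$sites, label = sys$labels,
        pka = mol$beads$pka[sys$sites], mean_charge = site_means
      ),
      acceptance_rate = res$acceptance,
      burn_in = burn_in, n_sweeps = n_sweeps,
      moves_per_sweep = moves_per_sweep,
      seed = seed, lambda_d = sys$lambda_d, ph = sys$ph
    ),
    class = "titration_result"
  )
}

#' Mean net charge after equilibration
#'
#' Arithmetic mean of the net-charge trace, discarding the first `burn_in`
#' sweeps.
#'
#' @param result a `titration_result`.
#' @param burn_in sweeps to discard (defaults to the run's own setting).
#' @return mean net charge, e.
#' @export
mean_net_charge <- function(result, burn_in = result$burn_in) {
  n <- nrow(result$net_charge_trace)
  if (burn_in >= n) abort("burn_in must be smaller than the trace length")
  mean(result$net_charge_trace$net_charge[seq.int(burn_in + 1, n)])
}

#' Apply titration mean charges to a molecule
#'
#' Freezes the equilibrium per-site mean charges onto the molecule's beads
#' (the charge state handed to many-body simulations).
#'
#' @param mol the titrated `cg_molecule`.
#' @param result the matching `titration_result`.
#' @return molecule with updated charges.
#' @export
apply_titration_charges <- function(mol, result) {
  mol$beads$charge[result$mean_site_charges$bead] <-
    result$mean_site_charges$mean_charge
  mol$net_charge <- sum(mol$beads$charge)
  mol
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf(
    "<titration_result> %d sweeps x %d moves, pH %.2f, lambda_D %.2f A\n",
    x$n_sweeps, x$moves_per_sweep, x$ph, x$lambda_d
  ))
  cat(sprintf("  mean net charge (burn-in %d): %+.3f e; acceptance %.3f\n",
              x$burn_in, mean_net_charge(x), x$acceptance_rate))
  invisible(x)
}
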