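# broom-style tidiers for the package's result objects.

#' Tidy a titration result
#'
#' @param x a `titration_result`.
#' @param ... unused.
#' @return tibble of per-site mean charges (post burn-in).
#' @method tidy titration_result
#' @export
tidy.titration_result <- function(x, ...) x$mean_site_charges

#' One-row summary of a titration run
#'
#' @param x a `titration_result`.
#' @param ... unused.
#' @return one-row tibble: mean net charge, its blocked standard error,
#'   acceptance rate and run settings.
#' @method glance titration_result
#' @export
glance.titration_result <- function(x, ...) {
  trace <- x$net_charge_trace$net_charge
  keep <- trace[seq.int(x$burn_in + 1, length(trace))]
  tibble(
    mean_net_charge = mean(keep),
    se_net_charge = block_se(keep),
    acceptance_rate = x$acceptance_rate,
    n_sweeps = x$n_sweeps, burn_in = x$burn_in,
    ph = x$ph, lambda_d = x$lambda_d
  )
}

#' Tidy a chi-squared scan
#'
#' @param x a `chi2_scan`.
#' @param ... unused.
#' @return long tibble with columns `qeff`, `eps`, `chi2`.
#' @method tidy chi2_scan
#' @export
tidy.chi2_scan <- function(x, ...) x$table

#' One-row summary of a chi-squared scan
#'
#' @param x a `chi2_scan`.
#' @param ... unused.
#' @return one-row tibble with the best-fit parameters and grid sizes.
#' @method glance chi2_scan
#' @export
glance.chi2_scan <- function(x, ...) {
  tibble(
    qeff_best = x$argmin$qeff, eps_best = x$argmin$eps,
    chi2_min = x$argmin$chi2,
    n_qeff = length(x$qeff_grid), n_eps = length(x$eps_grid),
    n_missing = sum(is.na(x$chi2))
  )
}

#' Tidy an MC trajectory's energy trace
#'
#' @param x an `mc_trajectory`.
#' @param ... unused.
#' @return tibble with per-sample `elec`, `w` and `total` energies (kBT).
#' @method tidy mc_trajectory
#' @export
tidy.mc_trajectory <- function(x, ...) x$energies

#' One-row summary of an MC trajectory
#'
#' @param x an `mc_trajectory`.
#' @param ... unused.
#' @return one-row tibble of run settings and the mean total energy.
#' @method glance mc_trajectory
#' @export
glance.mc_trajectory <- function(x, ...) {
  tibble(
    n_samples = nrow(x$energies), n_p = x$n_p, n_beads = x$n_beads,
    box_l = x$box_l, eps_ij = x$params$eps_ij,
    lambda_d = x$params$lambda_d, acceptance = x$acceptance,
    mean_energy = mean(x$energies$total)
  )
}

#' Tidy a conformer clustering
#'
#' @param x a `conformer_set`.
#' @param ... unused.
#' @return tibble with `frame`, `cluster` and an `is_center` flag.
#' @method tidy conformer_set
#' @export
tidy.conformer_set <- function(x, ...) {
  tibble(
    frame = seq_len(x$n_frames),
    cluster = x$labels,
    is_center = seq_len(x$n_frames) %in% x$centers
  )
}
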