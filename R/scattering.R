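# q-grid construction, form factors, effective structure factors and
# chi-squared comparison against experimental SAXS curves.

new_saxs_curve <- function(q, value, error = NULL, kind = "intensity",
                           box_l = NA_real_, p_max = NA_integer_,
                           meta = list()) {
  ord <- order(q)
  tb <- tibble(q = q[ord], value = value[ord])
  if (!is.null(error)) tb$error <- error[ord]
  if (any(diff(tb$q) <= 0)) abort("q values must be strictly increasing")
  if (any(!is.finite(tb$value))) abort("curve values must be finite")
  structure(tb, class = c("saxs_curve", class(tibble())),
            kind = kind, box_l = box_l, p_max = p_max, meta = meta)
}

#' The default experimental q-grid for chi-squared fits
#'
#' 51 points from 0.01 to 0.12 inverse Angstrom (spacing 0.0022).
#'
#' @return numeric vector of q values, inverse Angstrom.
#' @export
default_saxs_grid <- function() seq(0.01, 0.12, length.out = 51)

#' Build the crystallographic q-grid of a cubic box
#'
#' Scattering vectors \eqn{q = (2\pi p / L)(h,k,l)} for \eqn{p = 1..p_{max}}
#' and the positive-octant axis permutations of the direction families
#' `[100]` (3 directions), `[110]` (3) and `[111]` (1).  Each (p, family)
#' combination forms one shell of magnitude \eqn{(2\pi p/L)\sqrt{h^2+k^2+l^2}}.
#' Negative index signs are omitted: the lattice-sum intensity is even under
#' `q -> -q`, so they duplicate information.
#'
#' @param box_l cubic box edge, Angstrom.
#' @param p_max largest harmonic index (default 25).
#' @return a `q_grid`: list with a `shells` tibble (`shell`, `p`, `family`,
#'   `magnitude`, `n_dirs`) and `vectors` (per-shell matrices of q-vectors).
#' @export
build_qgrid <- function(box_l, p_max = 25) {
  if (box_l <= 0 || p_max < 1) abort("box_l must be > 0 and p_max >= 1")
  fam <- list(
    "100" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "110" = rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
    "111" = rbind(c(1, 1, 1))
  )
  rows <- list()
  vecs <- list()
  k <- 0L
  for (p in seq_len(p_max)) {
    for (f in names(fam)) {
      k <- k + 1L
      dirs <- fam[[f]]
      rows[[k]] <- tibble(
        p = p, family = f,
        magnitude = 2 * pi * p / box_l * sqrt(sum(fam[[f]][1, ]^2)),
        n_dirs = nrow(dirs)
      )
      vecs[[k]] <- 2 * pi * p / box_l * dirs
    }
  }
  shells <- bind_rows(rows)
  ord <- order(shells$magnitude)
  shells <- shells[ord, ]
  shells$shell <- seq_len(nrow(shells))
  structure(list(shells = shells, vectors = vecs[ord], box_l = box_l,
                 p_max = p_max),
            class = "q_grid")
}

#' Scattering intensity of a bead configuration
#'
#' Per shell, the average over the shell's q-vectors of
#' \eqn{[(\sum_i \sin q\cdot r_i)^2 + (\sum_i \cos q\cdot r_i)^2] / N}.
#'
#' @param coords `n x 3` bead coordinate matrix, Angstrom.
#' @param grid a [build_qgrid()] object.
#' @return a `saxs_curve` of kind `"intensity"`.
#' @export
scattering_intensity <- function(coords, grid) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) abort("need at least one bead")
  vals <- vapply(grid$vectors, function(qv) {
    mean(cpp_intensity(coords, qv))
  }, numeric(1))
  new_saxs_curve(grid$shells$magnitude, vals, kind = "intensity",
                 box_l = grid$box_l, p_max = grid$p_max)
}

# per-frame, per-shell intensity matrix (frames x shells) of a trajectory
trajectory_intensity <- function(traj, grid) {
  ns <- nrow(traj$energies)
  if (ns < 1) abort("trajectory holds no samples")
  if (length(traj$frames) == 0) abort("trajectory was recorded without frames")
  out <- matrix(NA_real_, ns, nrow(grid$shells))
  for (i in seq_len(ns)) {
    coords <- frame_coords(traj, i)
    out[i, ] <- vapply(grid$vectors, function(qv) {
      mean(cpp_intensity(coords, qv))
    }, numeric(1))
  }
  out
}

#' Orientation-averaged single-molecule form factor
#'
#' Averages the per-bead-normalised intensity of one molecule over uniformly
#' random orientations on the box's crystallographic q-grid (equivalent to a
#' single-molecule MC run, whose Boltzmann weight is orientation-independent).
#' Normalised so the large-q limit is 1.
#'
#' @param template a `cg_molecule`.
#' @param box_l cubic box edge, Angstrom.
#' @param n_orientations number of random orientations.
#' @param p_max largest harmonic index.
#' @param seed integer seed (deterministic curve for a given seed).
#' @return a `saxs_curve` of kind `"form_factor"`.
#' @export
form_factor <- function(template, box_l, n_orientations = 2048, p_max = 25,
                        seed = 1) {
  if (n_orientations < 1) abort("n_orientations must be >= 1")
  grid <- build_qgrid(box_l, p_max)
  coords <- bead_coords(template)
  acc <- rep(0, nrow(grid$shells))
  with_seed(seed, {
    quats <- random_quats(n_orientations)
    for (i in seq_len(n_orientations)) {
      rot <- coords %*% t(quat_to_mat(quats[i, ]))
      acc <- acc + vapply(grid$vectors, function(qv) {
        mean(cpp_intensity(rot, qv))
      }, numeric(1))
    }
  })
  new_saxs_curve(grid$shells$magnitude, acc / n_orientations,
                 kind = "form_factor", box_l = box_l, p_max = p_max)
}

#' Effective structure factor of a trajectory
#'
#' \eqn{S_{eff}(q)}: the frame- and shell-averaged many-molecule intensity
#' divided by the single-molecule form factor on the same grid.  Both are
#' normalised per bead, so non-interacting molecules give
#' \eqn{S_{eff} \equiv 1} in expectation.  The `error` column is the blocked
#' standard error of the frame average propagated through the division.
#'
#' @param traj an `mc_trajectory` recorded with frames.
#' @param form the matching [form_factor()] curve.
#' @param p_max harmonic index if `form` is missing (grid rebuilt).
#' @return a `saxs_curve` of kind `"s_eff"`.
#' @export
effective_structure_factor <- function(traj, form = NULL, p_max = 25) {
  if (is.null(form)) {
    form <- form_factor(traj$template, traj$box_l, p_max = p_max)
  }
  grid <- build_qgrid(traj$box_l, attr(form, "p_max"))
  if (!isTRUE(all.equal(grid$shells$magnitude, form$q, tolerance = 1e-9))) {
    abort("form factor grid does not match the trajectory's box")
  }
  streamed <- !is.null(traj$intensity_grid) && NROW(traj$intensity) > 0
  if (streamed) {
    gq <- traj$intensity_grid$shells$magnitude
    if (!isTRUE(all.equal(gq, form$q, tolerance = 1e-9))) {
      abort("form factor grid does not match the trajectory's streamed q-grid")
    }
    inten <- traj$intensity
  } else {
    inten <- trajectory_intensity(traj, grid)
  }
  m <- colMeans(inten)
  se <- apply(inten, 2, block_se)
  new_saxs_curve(grid$shells$magnitude, m / form$value, error = se / form$value,
                 kind = "s_eff", box_l = traj$box_l,
                 p_max = attr(form, "p_max"))
}

# bin-average curve points closer than half the target spacing, then
# linearly interpolate onto q_out; NA outside the simulated range
interp_curve <- function(q, v, q_out) {
  half <- min(diff(q_out)) / 2
  bin <- floor(q / half)
  agg <- tibble(bin = bin, q = q, v = v) %>%
    group_by(bin) %>%
    summarise(q = mean(q), v = mean(v), .groups = "drop") %>%
    arrange(q)
  approx(agg$q, agg$v, xout = q_out, rule = 1)$y
}

#' Chi-squared deviation between two curves
#'
#' \eqn{\chi^2 = \sum_i (S_{sim}(q_i) - S_{exp}(q_i))^2 / S_{exp}(q_i)} over
#' the experimental q points.  The simulated curve is bin-averaged (shells
#' closer than half the experimental spacing) and linearly interpolated onto
#' the experimental grid; extrapolation is refused.
#'
#' @param sim simulated `saxs_curve` (or tibble with `q`, `value`).
#' @param exp experimental `saxs_curve`; values must be positive.
#' @return chi-squared (dimensionless).
#' @export
chi_square <- function(sim, exp) {
  if (any(exp$value <= 0)) abort("experimental curve must be positive")
  if (length(exp$q) > 1) {
    s <- interp_curve(sim$q, sim$value, exp$q)
  } else {
    if (exp$q < min(sim$q) || exp$q > max(sim$q)) s <- NA_real_
    else s <- approx(sim$q, sim$value, xout = exp$q, rule = 1)$y
  }
  if (any(is.na(s))) {
    abort("simulated curve does not cover the experimental q range (extrapolation refused)")
  }
  sum((s - exp$value)^2 / exp$value)
}

#' Scan chi-squared over an (Q_eff, eps_ij) grid
#'
#' For each effective charge, runs one bead-model simulation (a replica
#' exchange across `eps_grid` when it has more than one value, so all eps
#' cells reuse a single run) and compares the resulting effective structure
#' factors with the experimental curve.
#'
#' @param template_builder function of one argument `qeff` returning the
#'   charged `cg_molecule` to simulate (see [bead_model_builder()]).
#' @param exp_curve experimental `saxs_curve`.
#' @param qeff_grid effective charges to scan, e.
#' @param eps_grid attraction strengths to scan, kBT.
#' @param n_p,c_p,conditions system size and state for [make_box()].
#' @param n_sweeps,burn_in,sample_stride,swap_stride,moves sampler settings.
#' @param n_orientations form-factor orientations.
#' @param p_max harmonic index of the q-grid.
#' @param intensity_stride sweeps between streamed intensity measurements.
#' @param seed integer seed.
#' @return a `chi2_scan`: `table` (long tibble `qeff`, `eps`, `chi2`),
#'   `chi2` matrix (`qeff x eps`), the grids, `argmin`, and the per-cell
#'   S_eff curves.
#' @export
scan_chi2 <- function(template_builder, exp_curve, qeff_grid,
                      eps_grid = 0.8, n_p = 100, c_p = 20,
                      conditions = solution_conditions(),
                      n_sweeps = 1500, burn_in = 500, sample_stride = 10,
                      swap_stride = 10, moves = move_params(),
                      n_orientations = 1024, p_max = 25, seed = 1,
                      intensity_stride = 2) {
  if (length(qeff_grid) < 1 || length(eps_grid) < 1) abort("grids must be non-empty")
  chi2 <- matrix(NA_real_, length(qeff_grid), length(eps_grid),
                 dimnames = list(qeff = qeff_grid, eps = eps_grid))
  curves <- vector("list", length(qeff_grid))
  for (iq in seq_along(qeff_grid)) {
    cell <- tryCatch({
      template <- template_builder(qeff_grid[iq])
      box <- make_box(template, n_p = n_p, c_p = c_p, conditions = conditions,
                      eps_ij = eps_grid[1], seed = seed + iq)
      grid <- build_qgrid(box$l, p_max)
      ff <- form_factor(template, box$l, n_orientations = n_orientations,
                        p_max = p_max, seed = seed + iq)
      if (length(eps_grid) > 1) {
        reps <- run_replicas(box, eps_grid = eps_grid, n_sweeps = n_sweeps,
                             swap_stride = swap_stride,
                             sample_stride = sample_stride, burn_in = burn_in,
                             moves = moves, seed = seed + iq,
                             record_frames = FALSE, intensity_grid = grid,
                             intensity_stride = intensity_stride)
        lapply(reps$replicas, effective_structure_factor, form = ff)
      } else {
        traj <- run_simulation(box, n_sweeps = n_sweeps, burn_in = burn_in,
                               sample_stride = sample_stride, moves = moves,
                               seed = seed + iq, record_frames = FALSE,
                               intensity_grid = grid,
                               intensity_stride = intensity_stride)
        list(effective_structure_factor(traj, form = ff))
      }
    }, error = function(e) {
      warning(sprintf("scan cell qeff = %g failed: %s",
                      qeff_grid[iq], conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    curves[[iq]] <- cell
    for (ie in seq_along(eps_grid)) {
      chi2[iq, ie] <- tryCatch(chi_square(cell[[ie]], exp_curve),
                               error = function(e) NA_real_)
    }
  }
  tab <- tibble(
    qeff = rep(qeff_grid, times = length(eps_grid)),
    eps = rep(eps_grid, each = length(qeff_grid)),
    chi2 = as.vector(chi2)
  )
  amin <- arrayInd(which.min(chi2), dim(chi2))
  structure(
    list(table = tab, chi2 = chi2, qeff_grid = qeff_grid, eps_grid = eps_grid,
         argmin = list(qeff = qeff_grid[amin[1]], eps = eps_grid[amin[2]],
                       chi2 = min(chi2, na.rm = TRUE)),
         curves = curves, exp_curve = exp_curve),
    class = "chi2_scan"
  )
}

#' @export
print.chi2_scan <- function(x, ...) {
  cat(sprintf(
    "<chi2_scan> %d x %d (Q_eff x eps) grid; argmin Q_eff = %g e, eps = %g kBT (chi2 = %.4g)\n",
    length(x$qeff_grid), length(x$eps_grid),
    x$argmin$qeff, x$argmin$eps, x$argmin$chi2
  ))
  invisible(x)
}

#' Builder of charged Y-shaped bead templates for chi-squared scans
#'
#' @param n_beads bead count (1, 6, 9 or 12).
#' @param target_rg radius of gyration to match, Angstrom.
#' @param fab_angle Fab-Fab angle, degrees.
#' @param sigma_override explicit bead diameter, Angstrom.
#' @return function `qeff -> cg_molecule` with `q_bead = qeff / n_beads`.
#' @export
bead_model_builder <- function(n_beads, target_rg = 48.2, fab_angle = 60,
                               sigma_override = NULL) {
  force(n_beads); force(target_rg); force(fab_angle); force(sigma_override)
  function(qeff) {
    set_bead_charges(
      build_bead_model(n_beads, target_rg, fab_angle, sigma_override), qeff
    )
  }
}

#' Read a SAXS curve from a text file
#'
#' Whitespace- or comma-separated columns `q value [error]`; `#` lines are
#' comments.  Units: inverse Angstrom by default; `unit = "invnm"` (or an
#' `# unit: 1/nm` header comment) converts from inverse nanometres.
#'
#' @param file input path.
#' @param unit `"auto"`, `"invang"` or `"invnm"`.
#' @param kind curve kind tag (default `"experimental"`).
#' @return a `saxs_curve`.
#' @export
read_saxs <- function(file, unit = c("auto", "invang", "invnm"),
                      kind = "experimental") {
  unit <- match.arg(unit)
  lines <- readLines(file, warn = FALSE)
  comments <- lines[startsWith(trimws(lines), "#")]
  if (unit == "auto") {
    unit <- if (any(grepl("1/nm|nm-1|nm\\^-1", comments))) "invnm" else "invang"
  }
  meta <- list()
  kv <- regmatches(comments,
                   regexec("#\\s*(\\w+)\\s*[:=]\\s*([-0-9.eE+]+)\\s*$", comments))
  for (m in kv) {
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.finite(v)) meta[[m[2]]] <- v
    }
  }
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  body <- gsub(",", " ", body)
  df <- read.table(text = body, header = FALSE)
  q <- df[[1]]
  if (unit == "invnm") q <- q / 10
  err <- if (ncol(df) >= 3) df[[3]] else NULL
  new_saxs_curve(q, df[[2]], error = err, kind = kind, meta = meta)
}

#' Write a SAXS curve to a text file
#'
#' Two or three whitespace-separated columns with `#` metadata comments
#' (unit, kind and any ground-truth metadata carried by the curve).
#'
#' @param curve a `saxs_curve`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_saxs <- function(curve, file) {
  meta <- attr(curve, "meta") %||% list()
  hdr <- c(
    "# cgmab scattering curve",
    "# unit: 1/angstrom",
    sprintf("# kind: %s", attr(curve, "kind") %||% "curve"),
    vapply(names(meta), function(nm) sprintf("# %s = %.8g", nm, meta[[nm]]),
           character(1))
  )
  cols <- if ("error" %in% names(curve)) {
    sprintf("%.8g %.8g %.8g", curve$q, curve$value, curve$error)
  } else {
    sprintf("%.8g %.8g", curve$q, curve$value)
  }
  writeLines(c(hdr, cols), file)
  invisible(file)
}
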