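test_that("the crystallographic q-grid has the stated structure", {
  L <- 626.3786
  grid <- build_qgrid(L, p_max = 25)
  expect_equal(nrow(grid$shells), 75)
  first <- grid$shells[grid$shells$p == 1 & grid$shells$family == "100", ]
  expect_equal(first$magnitude, 2 * pi / L, tolerance = 1e-12)
  expect_equal(round(first$magnitude, 5), 0.01003)
  p1 <- grid$shells[grid$shells$p == 1, ]
  expect_equal(sort(p1$magnitude) / min(p1$magnitude), c(1, sqrt(2), sqrt(3)),
               tolerance = 1e-12)
  expect_equal(p1$n_dirs[order(p1$magnitude)], c(3L, 3L, 1L))
  expect_true(all(diff(grid$shells$magnitude) > 0))
  # every vector in a shell shares the magnitude
  for (k in c(1, 30, 75)) {
    mags <- sqrt(rowSums(grid$vectors[[k]]^2))
    expect_lt(max(abs(mags - grid$shells$magnitude[k])), 1e-12)
  }
  expect_error(build_qgrid(-1, 25), "box_l")
})

test_that("intensity limits and the brute-force double sum agree", {
  grid <- build_qgrid(200, p_max = 5)
  one <- matrix(c(13.3, -4.1, 99), 1)
  curve <- scattering_intensity(one, grid)
  expect_true(all(abs(curve$value - 1) < 1e-12))
  n <- 7
  coincident <- matrix(rep(c(5, 5, 5), each = n), n)
  expect_true(all(abs(scattering_intensity(coincident, grid)$value - n) < 1e-9))
  set.seed(12)
  cloud <- matrix(runif(150, 0, 200), 50)
  got <- scattering_intensity(cloud, grid)
  want <- sapply(seq_along(grid$vectors), function(k) {
    mean(apply(grid$vectors[[k]], 1, function(qv) oracle_intensity(cloud, qv)))
  })
  expect_equal(got$value, want, tolerance = 1e-10)
  expect_true(all(got$value >= 0))
})

test_that("shell averages are invariant to direction order", {
  grid <- build_qgrid(150, p_max = 4)
  set.seed(1)
  cloud <- matrix(runif(90, 0, 150), 30)
  a <- scattering_intensity(cloud, grid)
  grid2 <- grid
  grid2$vectors <- lapply(grid$vectors, function(m) m[rev(seq_len(nrow(m))), ,
                                                     drop = FALSE])
  b <- scattering_intensity(cloud, grid2)
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("form factors reproduce the point and dimer limits", {
  single <- point_molecule(0, 10)
  ffs <- form_factor(single, 300, n_orientations = 16, seed = 1)
  expect_true(all(abs(ffs$value - 1) < 1e-12))
  ff1 <- form_factor(build_bead_model(6, 45), 400, n_orientations = 64, seed = 5)
  ff2 <- form_factor(build_bead_model(6, 45), 400, n_orientations = 64, seed = 5)
  expect_identical(ff1$value, ff2$value)
})

test_that("a rigid dimer matches the Debye formula within two percent", {
  d <- 30
  beads <- tibble::tibble(
    label = "bead", x = c(0, 0), y = c(0, 0), z = c(-d / 2, d / 2),
    diameter = 5, charge = 0, titratable = FALSE, pka = NA_real_,
    q_protonated = 0, q_deprotonated = 0
  )
  dimer <- cgmab:::new_cg_molecule(beads, model = "bead")
  L <- 250
  ff <- form_factor(dimer, L, n_orientations = 6000, p_max = 12, seed = 3)
  keep <- ff$q * d < 10
  debye <- 1 + sin(ff$q * d) / (ff$q * d)
  expect_lt(max(abs(ff$value[keep] - debye[keep]) / debye[keep]), 0.02)
})

test_that("chi-squared follows its defining formula", {
  g <- default_saxs_grid()
  expect_equal(diff(g)[1], 0.0022, tolerance = 1e-12)
  exp_curve <- cgmab:::new_saxs_curve(g, rep(1, 51), kind = "experimental")
  sim_same <- cgmab:::new_saxs_curve(g, rep(1, 51))
  expect_equal(chi_square(sim_same, exp_curve), 0)
  sim_hi <- cgmab:::new_saxs_curve(g, rep(1.1, 51))
  expect_equal(chi_square(sim_hi, exp_curve), 0.51, tolerance = 1e-9)
  single <- cgmab:::new_saxs_curve(0.05, 2, kind = "experimental")
  sim <- cgmab:::new_saxs_curve(c(0.01, 0.1), c(1, 1))
  expect_equal(chi_square(sim, single), 0.5)
  # additive over disjoint q subsets
  set.seed(2)
  v <- runif(51, 0.5, 2)
  simv <- cgmab:::new_saxs_curve(g, v)
  lo <- cgmab:::new_saxs_curve(g[1:25], rep(1, 25), kind = "experimental")
  hi <- cgmab:::new_saxs_curve(g[26:51], rep(1, 26), kind = "experimental")
  expect_equal(chi_square(simv, lo) + chi_square(simv, hi),
               chi_square(simv, exp_curve <- cgmab:::new_saxs_curve(
                 g, rep(1, 51), kind = "experimental")), tolerance = 1e-10)
  bad <- cgmab:::new_saxs_curve(g, c(-1, rep(1, 50)), kind = "experimental")
  expect_error(chi_square(sim_same, bad), "positive")
  narrow <- cgmab:::new_saxs_curve(c(0.02, 0.03), c(1, 1))
  expect_error(chi_square(narrow, cgmab:::new_saxs_curve(g, rep(1, 51))),
               "extrapolation")
})

test_that("S_eff is one for an ideal gas and flat at large q", {
  mol <- soft_point_molecule()
  box <- make_box(mol, n_p = 50, c_p = 20, conditions = solution_conditions(),
                  eps_ij = 0, seed = 30)
  grid <- build_qgrid(box$l, p_max = 12)
  traj <- run_simulation(box, n_sweeps = 800, burn_in = 100,
                         sample_stride = 400,
                         moves = move_params(max_translation = box$l / 3),
                         seed = 31, record_frames = FALSE,
                         intensity_grid = grid, intensity_stride = 2)
  ff <- form_factor(mol, box$l, n_orientations = 8, p_max = 12, seed = 1)
  se <- effective_structure_factor(traj, ff)
  z <- (se$value - 1) / se$error
  expect_lt(max(abs(z)), 4)
  expect_lt(abs(mean(se$value) - 1), 0.01)
})

test_that("charged repulsive spheres suppress the low-q structure factor", {
  run_seff <- function(q) {
    mol <- point_molecule(q, 40)
    box <- make_box(mol, n_p = 40, c_p = 30,
                    conditions = solution_conditions(), eps_ij = 0, seed = 32)
    grid <- build_qgrid(box$l, p_max = 12)
    traj <- run_simulation(box, n_sweeps = 1500, burn_in = 300,
                           sample_stride = 500, seed = 33,
                           record_frames = FALSE, intensity_grid = grid,
                           intensity_stride = 2)
    ff <- form_factor(mol, box$l, n_orientations = 8, p_max = 12, seed = 1)
    effective_structure_factor(traj, ff)
  }
  charged <- run_seff(30)
  expect_lt(charged$value[1], 1)                    # suppressed compressibility
  # more charge suppresses further (monotone repulsion effect)
  weaker <- run_seff(10)
  expect_lt(charged$value[1], weaker$value[1])
  # and the large-q shells decay back to unity
  tail_z <- (tail(charged$value, 10) - 1) / tail(charged$error, 10)
  expect_lt(max(abs(tail_z)), 4)
})

test_that("chi2 scans have the right shape and a well-defined argmin", {
  mol0 <- build_bead_model(1, 40, sigma_override = 40)
  builder <- bead_model_builder(1, 40, sigma_override = 40)
  cond <- solution_conditions()
  target <- synthetic_target(mol0, qeff = 20, eps = 0.5, c_p = 20,
                             conditions = cond, noise_frac = 0, seed = 50,
                             n_p = 30, n_sweeps = 800, burn_in = 200,
                             n_orientations = 8)
  scan <- scan_chi2(builder, target, qeff_grid = c(5, 20, 45),
                    eps_grid = c(0.3, 0.7), n_p = 30, c_p = 20,
                    conditions = cond, n_sweeps = 600, burn_in = 200,
                    n_orientations = 8, seed = 51)
  expect_equal(dim(scan$chi2), c(3L, 2L))
  expect_true(all(scan$chi2 >= 0, na.rm = TRUE))
  expect_equal(scan$argmin$chi2, min(scan$chi2, na.rm = TRUE))
  idx <- which(scan$chi2 == scan$argmin$chi2, arr.ind = TRUE)
  expect_equal(scan$argmin$qeff, c(5, 20, 45)[idx[1]])
  expect_equal(scan$argmin$qeff, 20)   # gross separation is resolvable
  tt <- tidy(scan)
  expect_equal(nrow(tt), 6)
  gl <- glance(scan)
  expect_equal(gl$qeff_best, scan$argmin$qeff)
})

test_that("at low concentration Q_eff is sharp while eps is flat", {
  builder <- bead_model_builder(1, 40, sigma_override = 40)
  cond <- solution_conditions(c_p = 10)
  target <- synthetic_target(build_bead_model(1, 40, sigma_override = 40),
                             qeff = 20, eps = 0.5, c_p = 10,
                             conditions = cond, noise_frac = 0, seed = 60,
                             n_p = 40, n_sweeps = 1500, burn_in = 300,
                             n_orientations = 8)
  scan <- scan_chi2(builder, target, qeff_grid = c(8, 20, 32),
                    eps_grid = c(0.1, 0.5, 0.9), n_p = 40, c_p = 10,
                    conditions = cond, n_sweeps = 1500, burn_in = 300,
                    n_orientations = 8, seed = 61)
  # Q_eff is identifiable: chi2 varies strongly across charges ...
  across_q <- mean(apply(scan$chi2, 2, stats::var))
  # ... while eps is not: at the fitted charge the row is nearly flat
  best_row <- scan$chi2[which(scan$qeff_grid == scan$argmin$qeff), ]
  across_eps <- stats::var(best_row)
  expect_equal(scan$argmin$qeff, 20)
  expect_gt(across_q, 10 * across_eps)
})

test_that("SAXS curves round-trip through the text format with units", {
  g <- default_saxs_grid()
  curve <- cgmab:::new_saxs_curve(g, exp(-g * 10), error = rep(0.01, 51),
                                  kind = "experimental",
                                  meta = list(truth_qeff = 26))
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs(curve, f)
  back <- read_saxs(f)
  expect_equal(back$q, curve$q)
  expect_equal(back$value, curve$value, tolerance = 1e-6)
  expect_equal(attr(back, "meta")$truth_qeff, 26)
  # inverse-nanometre files are converted on read
  fnm <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q in 1/nm", "0.1 1.0", "0.2 0.9"), fnm)
  nm <- read_saxs(fnm)
  expect_equal(nm$q, c(0.01, 0.02))
})
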