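test_that("the box volume follows the concentration formula", {
  box <- make_box(point_molecule(0, 60), n_p = 20, c_p = 20, mw = 148000,
                  conditions = solution_conditions(), seed = 1)
  expect_equal(box$l^3, 2.4576e8, tolerance = 1e-3)
  expect_equal(box$l, 626.3786, tolerance = 0.1 / 626)
  box2 <- make_box(point_molecule(0, 60), n_p = 20, c_p = 40, mw = 148000,
                   conditions = solution_conditions(), seed = 1)
  expect_equal(box2$l^3, box$l^3 / 2, tolerance = 1e-9)
})

test_that("initial configurations carry no hard overlaps", {
  mol <- set_bead_charges(build_bead_model(9, 48.2), 26)
  box <- make_box(mol, n_p = 40, c_p = 60, conditions = solution_conditions(),
                  seed = 3)
  expect_true(is.finite(box_energy(box)$total))
})

test_that("a zero-energy system accepts every move", {
  mol <- soft_point_molecule()   # no charge, no hard core
  box <- make_box(mol, n_p = 20, c_p = 20, conditions = solution_conditions(),
                  eps_ij = 0, seed = 2)
  out <- mc_sweep(box, move_params(max_translation = 50, max_rotation = 1),
                  seed = 7)
  expect_equal(out$acceptance, 1.0)
})

test_that("incremental energy bookkeeping matches full recomputation", {
  mol <- set_bead_charges(build_bead_model(6, 48.2), 20)
  box <- make_box(mol, n_p = 25, c_p = 80, conditions = solution_conditions(),
                  seed = 4)
  traj <- run_simulation(box, n_sweeps = 100, burn_in = 0, sample_stride = 100,
                         seed = 5)
  full <- box_energy(traj$final_box)
  expect_equal(tail(traj$energies$total, 1), full$total, tolerance = 1e-8)
  expect_equal(tail(traj$energies$elec, 1), full$elec, tolerance = 1e-8)
})

test_that("trajectories are reproducible and seeds matter", {
  mol <- set_bead_charges(build_bead_model(6, 48.2), 20)
  box <- make_box(mol, n_p = 15, c_p = 50, conditions = solution_conditions(),
                  seed = 6)
  a <- run_simulation(box, n_sweeps = 200, burn_in = 50, sample_stride = 10,
                      seed = 11)
  b <- run_simulation(box, n_sweeps = 200, burn_in = 50, sample_stride = 10,
                      seed = 11)
  expect_identical(a$frames, b$frames)
  expect_identical(a$energies, b$energies)
  c_ <- run_simulation(box, n_sweeps = 200, burn_in = 50, sample_stride = 10,
                       seed = 12)
  expect_false(identical(a$frames, c_$frames))
})

test_that("non-interacting molecules fill the box uniformly", {
  mol <- soft_point_molecule()
  box <- make_box(mol, n_p = 40, c_p = 20, conditions = solution_conditions(),
                  eps_ij = 0, seed = 8)
  traj <- run_simulation(box, n_sweeps = 600, burn_in = 100,
                         sample_stride = 25,
                         moves = move_params(max_translation = 250),
                         seed = 13)
  coords <- do.call(rbind, lapply(seq_len(nrow(traj$energies)),
                                  function(i) cgmab:::frame_coords(traj, i)))
  wrapped <- coords - traj$box_l * floor(coords / traj$box_l)
  for (d in 1:3) {
    ks <- suppressWarnings(
      stats::ks.test(unique(wrapped[, d]) / traj$box_l, "punif")
    )
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("energies are invariant under a global half-box translation", {
  mol <- set_bead_charges(build_bead_model(9, 48.2), 26)
  box <- make_box(mol, n_p = 20, c_p = 60, conditions = solution_conditions(),
                  seed = 9)
  e0 <- box_energy(box)$total
  shifted <- box
  shifted$com <- (box$com + box$l / 2) %% box$l
  expect_equal(box_energy(shifted)$total, e0, tolerance = 1e-9)
})

test_that("acceptance decreases with the translation step on a dense system", {
  mol <- set_bead_charges(build_bead_model(6, 45), 26)
  box <- make_box(mol, n_p = 30, c_p = 150, conditions = solution_conditions(),
                  seed = 10, max_attempts = 5000)
  accs <- sapply(c(5, 30, 120), function(mt) {
    tr <- run_simulation(box, n_sweeps = 60, burn_in = 10, sample_stride = 60,
                         moves = move_params(max_translation = mt,
                                             max_rotation = 0.3),
                         seed = 14)
    # tuning is confined to burn-in; use production acceptance
    tr$acceptance
  })
  expect_true(all(diff(accs) < 0))
})

test_that("sampled bead-model frames never overlap hard cores", {
  mol <- set_bead_charges(build_bead_model(6, 40), 10)
  sigma <- mol$beads$diameter[1]
  box <- make_box(mol, n_p = 12, c_p = 120, conditions = solution_conditions(),
                  seed = 15, max_attempts = 5000)
  traj <- run_simulation(box, n_sweeps = 300, burn_in = 50, sample_stride = 25,
                         seed = 16)
  L <- traj$box_l
  for (i in seq_len(nrow(traj$energies))) {
    co <- cgmab:::frame_coords(traj, i)
    mol_id <- rep(seq_len(traj$n_p), each = traj$n_beads)
    d <- as.matrix(stats::dist(co))
    # minimum-image correction for the distance matrix, axis by axis
    dmin <- matrix(0, nrow(co), nrow(co))
    for (ax in 1:3) {
      dd <- outer(co[, ax], co[, ax], "-")
      dd <- dd - L * round(dd / L)
      dmin <- dmin + dd^2
    }
    dmin <- sqrt(dmin)
    inter <- outer(mol_id, mol_id, "!=")
    expect_gte(min(dmin[inter]), sigma * (1 - 1e-12))
  }
})

test_that("hard-sphere pressure agrees with Carnahan-Starling at phi 0.2", {
  phi <- 0.2
  sigma <- 30
  mol <- point_molecule(0, sigma)
  n_p <- 80
  # choose the concentration that yields the target packing fraction
  mw <- 148000
  rho <- 6 * phi / (pi * sigma^3)
  c_p <- rho * mw * 1e27 / 6.02214076e23
  cond <- solution_conditions(c_p = c_p, rg = sigma / 2)
  box <- make_box(mol, n_p = n_p, c_p = c_p, conditions = cond, eps_ij = 0,
                  params = pair_params(0, lambda_d = 10, model = "bead"),
                  seed = 17, max_attempts = 20000)
  traj <- run_simulation(box, n_sweeps = 3000, burn_in = 500,
                         sample_stride = 10,
                         moves = move_params(max_translation = 8,
                                             max_rotation = 0.5), seed = 18)
  L <- traj$box_l
  edges <- seq(sigma, 1.25 * sigma, length.out = 11)
  counts <- numeric(length(edges) - 1)
  nf <- nrow(traj$energies)
  for (i in seq_len(nf)) {
    co <- cgmab:::frame_coords(traj, i)
    dmin <- matrix(0, nrow(co), nrow(co))
    for (ax in 1:3) {
      dd <- outer(co[, ax], co[, ax], "-")
      dd <- dd - L * round(dd / L)
      dmin <- dmin + dd^2
    }
    r <- sqrt(dmin[upper.tri(dmin)])
    counts <- counts + graphics::hist(r[r >= sigma & r < 1.25 * sigma],
                                      breaks = edges, plot = FALSE)$counts
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  rho_box <- n_p / L^3
  g <- counts / (nf * n_p / 2 * shell * rho_box)
  fit <- stats::lm(g ~ mids)
  g_contact <- unname(stats::predict(fit, newdata = data.frame(mids = sigma)))
  z_mc <- 1 + 4 * phi * g_contact
  z_cs <- (1 + phi + phi^2 - phi^3) / (1 - phi)^3
  expect_equal(z_mc, z_cs, tolerance = 0.05)
})

test_that("replica exchange swaps freely at equal eps and spans the grid", {
  expect_equal(default_eps_grid(), seq(0.05, 0.085, by = 0.005))
  expect_length(default_eps_grid(), 8)
  mol <- set_bead_charges(build_bead_model(6, 45), 15)
  box <- make_box(mol, n_p = 10, c_p = 60, conditions = solution_conditions(),
                  seed = 19)
  same <- run_replicas(box, eps_grid = c(0.4, 0.4, 0.4), n_sweeps = 100,
                       burn_in = 20, swap_stride = 10, sample_stride = 10,
                       seed = 20, record_frames = FALSE)
  expect_equal(same$swap_acceptance, 1.0)
  full <- run_replicas(box, eps_grid = default_eps_grid(), n_sweeps = 40,
                       burn_in = 10, swap_stride = 10, sample_stride = 10,
                       seed = 21, record_frames = FALSE)
  expect_length(full$replicas, 8)
  expect_equal(sapply(full$replicas, function(t) t$params$eps_ij),
               default_eps_grid())
})

test_that("replica energy distributions match independent runs", {
  mol <- point_molecule(charge = 20, sigma = 40)
  box <- make_box(mol, n_p = 16, c_p = 120, conditions = solution_conditions(),
                  seed = 22, max_attempts = 5000)
  eps <- c(0.3, 1.2)
  reps <- run_replicas(box, eps_grid = eps, n_sweeps = 4000, burn_in = 500,
                       swap_stride = 10, sample_stride = 10, seed = 23,
                       record_frames = FALSE)
  expect_gt(reps$swap_acceptance, 0)
  for (k in seq_along(eps)) {
    b2 <- box
    b2$params <- pair_params(eps[k], lambda_d = box$params$lambda_d,
                             lambda_b = box$params$lambda_b, model = "bead")
    single <- run_simulation(b2, n_sweeps = 4000, burn_in = 500,
                             sample_stride = 10, seed = 24 + k,
                             record_frames = FALSE)
    ks <- suppressWarnings(stats::ks.test(reps$replicas[[k]]$energies$total,
                                          single$energies$total))
    expect_gt(ks$p.value, 0.01)
  }
})
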