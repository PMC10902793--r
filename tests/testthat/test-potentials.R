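test_that("Bjerrum length matches water at room temperature and scales", {
  expect_equal(bjerrum_length(298.15, 78.7), 7.1, tolerance = 0.05 / 7.1)
  lb <- bjerrum_length(298.15, 78.7)
  expect_equal(bjerrum_length(298.15, 2 * 78.7), lb / 2, tolerance = 1e-12)
  expect_equal(bjerrum_length(298.15, 1), 78.7 * lb, tolerance = 1e-12)
  expect_error(bjerrum_length(-1, 78.7), "positive")
})

test_that("dilute Debye length follows the aqueous 1:1 constant", {
  expect_equal(debye_length_dilute(1), 3.04)
  expect_equal(debye_length_dilute(0.01), 30.4)
  expect_equal(debye_length_dilute(0.007), 3.04 / sqrt(0.007), tolerance = 1e-12)
  expect_equal(round(debye_length_dilute(0.007), 2), 36.33)
  expect_error(debye_length_dilute(0), "ionic_strength")
})

test_that("hard-sphere volume fraction is rho*pi*sigma^3/6", {
  expect_equal(hs_volume_fraction(0, 96.4), 0)
  rho150 <- 150 * 6.02214076e23 / (148000 * 1e27)
  expect_equal(hs_volume_fraction(rho150, 2 * 48.2), 0.286, tolerance = 2e-3)
  expect_equal(hs_volume_fraction(2e-7, 50), 2 * hs_volume_fraction(1e-7, 50))
})

test_that("solution Debye length handles counterions and crowding", {
  lb <- bjerrum_length()
  # pure salt reduces to the dilute expression within 1%
  rho_salt <- molar_to_density(0.05)
  expect_equal(debye_length_solution(0, 0, rho_salt = rho_salt, lambda_b = lb),
               debye_length_dilute(0.05), tolerance = 0.01)
  # crowding shortens the screening length at fixed Z*rho
  l0 <- debye_length_solution(30, 8e-8, phi = 0, lambda_b = lb)
  l5 <- debye_length_solution(30, 8e-8, phi = 0.5, lambda_b = lb)
  expect_lt(l5, l0)
  # direct hand evaluation of the inverse-square expression
  z <- 30; rho <- 8.14e-8; phi <- 0.1
  hand <- 1 / sqrt(4 * pi * lb * (z * rho / (1 - phi)))
  expect_equal(debye_length_solution(z, rho, phi = phi, lambda_b = lb), hand,
               tolerance = 1e-10)
  # strictly decreasing in every density argument
  base <- debye_length_solution(10, 1e-8, 1e-6, 1e-7, 0.05, lb)
  expect_lt(debye_length_solution(10, 2e-8, 1e-6, 1e-7, 0.05, lb), base)
  expect_lt(debye_length_solution(10, 1e-8, 2e-6, 1e-7, 0.05, lb), base)
  expect_lt(debye_length_solution(10, 1e-8, 1e-6, 2e-7, 0.05, lb), base)
  expect_error(debye_length_solution(10, 1e-8, phi = 1), "phi")
})

test_that("amino-acid pair energy combines screened Coulomb and LJ", {
  p <- pair_params(eps_ij = 0.5, lambda_d = 30, lambda_b = 7.1)
  expect_equal(pair_energy_aa(0, 0, 6, 6, p), 0)            # LJ zero at sigma
  expect_lt(abs(pair_energy_aa(1, 1, 6, 1e4, p)), 1e-12)    # decays to zero
  # at r = lambda_B with negligible screening the Coulomb term is 1 kBT
  p2 <- pair_params(eps_ij = 0, lambda_d = 1e9, lambda_b = 7.1)
  expect_equal(pair_energy_aa(1, 1, 1, 7.1, p2), 1, tolerance = 1e-6)
  expect_error(pair_energy_aa(1, 1, 6, 0, p), "singularity")
  # continuity: no jumps on a fine radial mesh
  r <- seq(5, 60, by = 0.01)
  v <- pair_energy_aa(1, -1, 6, r, p)
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(diff(v))), 2)
  # for like charges with no attraction the energy decreases monotonically
  v2 <- pair_energy_aa(2, 2, 0.01, seq(1, 50, 0.1),
                       pair_params(0, lambda_d = 30, lambda_b = 7.1))
  expect_true(all(v2 > 0))
  expect_true(all(diff(v2) < 0))
})

test_that("bead pair energy has a hard core and the DH size correction", {
  p <- pair_params(eps_ij = 0.8, lambda_d = 20, lambda_b = 7.1, model = "bead")
  expect_equal(pair_energy_bead(3, 30, 0.9 * 30, p), Inf)
  # independent hand evaluation
  pref <- exp(30 / 40) / (1 + 30 / 40)
  hand <- 7.1 * 9 * pref^2 * exp(-40 / 20) / 40 - 0.8 * (30 / 40)^6
  expect_equal(pair_energy_bead(3, 30, 40, p), hand, tolerance = 1e-12)
  # vanishing bead size: size factor goes to 1, plain Yukawa remains
  p0 <- pair_params(eps_ij = 0, lambda_d = 20, lambda_b = 7.1, model = "bead")
  yuk <- 7.1 * 4 * exp(-25 / 20) / 25
  expect_equal(pair_energy_bead(2, 1e-8, 25, p0), yuk, tolerance = 1e-6)
  # finite and continuous beyond contact
  r <- seq(30.0001, 200, by = 0.01)
  v <- pair_energy_bead(3, 30, r, p)
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(diff(v))), 0.5)
})

test_that("molecule pair energy respects images and matches a double loop", {
  L <- 200
  p <- pair_params(eps_ij = 0.8, lambda_d = 20, lambda_b = 7.1, model = "bead")
  m1 <- point_molecule(charge = 3, sigma = 30)
  m2 <- point_molecule(charge = 3, sigma = 30)
  m1$com <- c(10, 0, 0)
  m2$com <- c(190, 0, 0)   # image distance 20 < sigma: overlap
  expect_equal(molecule_pair_energy(m1, m2, L, p), Inf)
  m2$com <- c(150, 0, 0)   # image distance 60
  expect_equal(molecule_pair_energy(m1, m2, L, p),
               pair_energy_bead(3, 30, 60, p), tolerance = 1e-12)
  # straddling the boundary equals the unwrapped arrangement
  m3 <- point_molecule(3); m4 <- point_molecule(3)
  m3$com <- c(195, 50, 50); m4$com <- c(5, 50, 50)
  m5 <- point_molecule(3); m6 <- point_molecule(3)
  m5$com <- c(95, 50, 50); m6$com <- c(105, 50, 50)
  expect_equal(molecule_pair_energy(m3, m4, L, p),
               molecule_pair_energy(m5, m6, L, p), tolerance = 1e-12)
})

test_that("six-bead molecule pair energy matches the 36-term oracle", {
  set.seed(21)
  L <- 400
  pa <- pair_params(eps_ij = 0.3, lambda_d = 25, lambda_b = 7.1,
                    model = "amino_acid")
  mk <- function(com) {
    m <- build_bead_model(6, 30)
    m$beads$charge <- rnorm(6)
    m$net_charge <- sum(m$beads$charge)
    m$com <- com
    th <- runif(1, 0, pi)
    m$orientation <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0,
                              0, 0, 1), 3, byrow = TRUE)
    m
  }
  a <- mk(c(50, 50, 50))
  b <- mk(c(120, 80, 60))
  rc <- L / 2
  pa_uncut <- pair_params(eps_ij = 0.3, lambda_d = 25, lambda_b = 7.1,
                          model = "amino_acid", r_cut_elec = rc, r_cut_vdw = rc)
  wa <- sweep(as.matrix(a$beads[, c("x", "y", "z")]) %*% t(a$orientation), 2,
              a$com, "+")
  wb <- sweep(as.matrix(b$beads[, c("x", "y", "z")]) %*% t(b$orientation), 2,
              b$com, "+")
  want <- oracle_molecule_pair(wa, wb, a$beads$charge, b$beads$charge,
                               a$beads$diameter, b$beads$diameter, L,
                               pa_uncut, rc, rc)
  expect_equal(molecule_pair_energy(a, b, L, pa_uncut), want, tolerance = 1e-10)
})

test_that("the default truncation changes pair energies negligibly", {
  p_def <- pair_params(eps_ij = 0.8, lambda_d = 20, lambda_b = 7.1,
                       model = "bead")
  p_inf <- pair_params(eps_ij = 0.8, lambda_d = 20, lambda_b = 7.1,
                       model = "bead", r_cut_elec = 1e9, r_cut_vdw = 1e9)
  L <- 1e4  # large box so L/2 never truncates the comparison
  m1 <- point_molecule(3); m2 <- point_molecule(3)
  m1$com <- c(0, 0, 0)
  set.seed(5)
  for (k in 1:20) {
    m2$com <- runif(3, 40, 400)
    e1 <- molecule_pair_energy(m1, m2, L, p_def)
    e2 <- molecule_pair_energy(m1, m2, L, p_inf)
    expect_lt(abs(e1 - e2), 1e-3)
  }
})
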