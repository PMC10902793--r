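# Independent oracles used to validate the implementation paths.

# Brute-force RMSD by dense SO(3) search (Euler grid + local refinement).
# Independent of the Kabsch superposition route.
oracle_rmsd_grid <- function(a, b, n_grid = 24) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rot_euler <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cc <- cos(ang[3]); sc <- sin(ang[3])
    rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  dev <- function(ang) {
    d <- b %*% t(rot_euler(ang)) - a
    sqrt(mean(rowSums(d^2)))
  }
  best <- Inf
  best_ang <- c(0, 0, 0)
  g1 <- seq(0, 2 * pi, length.out = n_grid)
  g2 <- seq(0, pi, length.out = n_grid %/% 2)
  for (x in g1) for (y in g2) for (z in g1) {
    v <- dev(c(x, y, z))
    if (v < best) {
      best <- v
      best_ang <- c(x, y, z)
    }
  }
  opt <- stats::optim(best_ang, dev)
  min(best, opt$value)
}

# Exhaustive re-implementation of neighbour-count clustering, written
# directly from the verbal description (no shared code with daura_cluster).
oracle_daura <- function(frames, cutoff) {
  n <- length(frames)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    if (i == j) 0 else cgmab::rmsd(frames[[i]], frames[[j]])
  }))
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  while (anyNA(labels)) {
    cl <- cl + 1L
    free <- which(is.na(labels))
    counts <- sapply(free, function(i) sum(d[i, free] <= cutoff))
    center <- free[which.max(counts)]
    members <- free[d[center, free] <= cutoff]
    labels[members] <- cl
    centers[cl] <- center
  }
  list(labels = labels, centers = centers)
}

# Direct complex-exponential double sum |sum_j exp(i q.r_j)|^2 / N
oracle_intensity <- function(coords, qvec) {
  ph <- coords %*% qvec
  (sum(sin(ph))^2 + sum(cos(ph))^2) / nrow(coords)
}

# Explicit double-loop inter-molecular energy under minimum image,
# built on the scalar pair-energy functions
oracle_molecule_pair <- function(ca, cb, qa, qb, sa, sb, L, params,
                                 rc_e, rc_v) {
  tot <- 0
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      d <- ca[i, ] - cb[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      sij <- (sa[i] + sb[j]) / 2
      if (params$model == "bead") {
        if (r < sij) return(Inf)
        el <- params$lambda_b * qa[i] * qb[j] *
          dh_size_pref(sij, params$lambda_d)^2 *
          exp(-r / params$lambda_d) / r
        vd <- -params$eps_ij * (sij / r)^6
      } else {
        el <- params$lambda_b * qa[i] * qb[j] * exp(-r / params$lambda_d) / r
        sr6 <- (sij / r)^6
        vd <- 4 * params$eps_ij * (sr6^2 - sr6)
      }
      tot <- tot + (if (r <= rc_e) el else 0) + (if (r <= rc_v) vd else 0)
    }
  }
  tot
}

dh_size_pref <- function(sigma, lambda_d) {
  x <- sigma / (2 * lambda_d)
  exp(x) / (1 + x)
}

# three-residue PDB fixture written by hand
pdb_three_residues <- function() {
  c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ASP A   2       4.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  LYS A   3       8.000   5.000   3.000  1.00  0.00           C",
    "END"
  )
}

# a small charged single-bead molecule for box tests
point_molecule <- function(charge = 0, sigma = 30) {
  m <- build_bead_model(1, target_rg = sigma / 2, sigma_override = sigma)
  set_bead_charges(m, charge)
}

# an uncharged soft single-bead molecule (no hard core): a true ideal-gas
# particle when charge and eps are zero
soft_point_molecule <- function() {
  res <- tibble::tibble(resno = 1, chain = "A", name = "GLY",
                        x = 0, y = 0, z = 0, mw = 75.07)
  aa_coarse_grain(res, pka_table = tibble::tibble(code = character(),
                                                  pka = numeric()))
}
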