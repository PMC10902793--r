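# Structure handling: PDB reading, coarse-graining, Y-shaped bead models,
# geometric descriptors and conformational clustering.

new_cg_molecule <- function(beads, model = c("amino_acid", "bead"),
                            com = c(0, 0, 0), orientation = diag(3)) {
  model <- match.arg(model)
  stopifnot(is.data.frame(beads), nrow(beads) >= 1)
  needed <- c("label", "x", "y", "z", "diameter", "charge", "titratable", "pka")
  missing <- setdiff(needed, names(beads))
  if (length(missing) > 0) {
    abort(paste0("bead table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(beads$diameter <= 0)) abort("bead diameters must be > 0")
  if (any(beads$titratable & !is.finite(beads$pka))) {
    abort("titratable beads must carry a finite pKa")
  }
  coords <- as.matrix(beads[, c("x", "y", "z")])
  ctr <- colMeans(coords)
  beads$x <- beads$x - ctr[1]
  beads$y <- beads$y - ctr[2]
  beads$z <- beads$z - ctr[3]
  structure(
    list(
      beads = as_tibble(beads),
      com = as.numeric(com),
      orientation = orientation,
      net_charge = sum(beads$charge),
      rg = rg_points(as.matrix(beads[, c("x", "y", "z")])),
      model = model
    ),
    class = "cg_molecule"
  )
}

#' @export
print.cg_molecule <- function(x, ...) {
  cat(sprintf(
    "<cg_molecule> %s model: %d beads, net charge %+.2f e, Rg %.2f A\n",
    x$model, nrow(x$beads), x$net_charge, x$rg
  ))
  cat(sprintf("  titratable sites: %d\n", sum(x$beads$titratable)))
  invisible(x)
}

bead_coords <- function(mol) as.matrix(mol$beads[, c("x", "y", "z")])

# world-frame coordinates of a posed molecule
world_coords <- function(mol) {
  sweep(bead_coords(mol) %*% t(mol$orientation), 2, mol$com, "+")
}

rg_points <- function(coords) {
  if (nrow(coords) == 1) return(0)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Read residue records from a PDB structure
#'
#' Parses `ATOM` records (via \pkg{bio3d}) and reduces each residue to a single
#' point, by default its atomic centre of mass (falling back to the CA atom,
#' then to the unweighted atom mean, when element masses are unavailable).
#' Waters and other `HETATM` records are excluded.
#'
#' @param file path to a PDB file (or use `text`).
#' @param text PDB-format content as a character vector of lines or a single
#'   string.
#' @param reduce reduction point: `"com"` (atomic centre of mass) or `"ca"`.
#' @return tibble with columns `resno`, `chain`, `name` (3-letter code),
#'   `x`, `y`, `z` (Angstrom) and `mw` (g/mol, `NA` for non-standard codes).
#' @export
read_pdb <- function(file = NULL, text = NULL, reduce = c("com", "ca")) {
  reduce <- match.arg(reduce)
  if (is.null(file) == is.null(text)) abort("supply exactly one of `file` or `text`")
  if (!is.null(text)) {
    lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else {
    lines <- readLines(file, warn = FALSE)
  }
  is_atom <- startsWith(lines, "ATOM")
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad) > 0) {
    abort(sprintf("unparseable ATOM record at line %d (truncated)", bad[1]))
  }
  for (ln in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[ln], 31, 38), substr(lines[ln], 39, 46), substr(lines[ln], 47, 54)
    )))
    if (any(is.na(xyz))) {
      abort(sprintf("unparseable ATOM record at line %d (bad coordinates)", ln))
    }
  }
  if (!any(is_atom)) abort("no ATOM records found: empty input")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) abort("no ATOM records found: empty input")

  at$mass <- tryCatch(bio3d::atom2mass(at$elesy), error = function(e) NA_real_)
  key <- paste(at$chain, at$resno, at$insert)
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  wt <- residue_weights()
  rows <- lapply(groups, function(idx) {
    sub <- at[idx, , drop = FALSE]
    m <- sub$mass
    if (reduce == "ca" || any(!is.finite(m))) {
      ca <- which(sub$elety == "CA")
      if (length(ca) >= 1) {
        pos <- c(sub$x[ca[1]], sub$y[ca[1]], sub$z[ca[1]])
      } else {
        pos <- c(mean(sub$x), mean(sub$y), mean(sub$z))
      }
    } else {
      pos <- c(sum(sub$x * m), sum(sub$y * m), sum(sub$z * m)) / sum(m)
    }
    tibble(
      resno = sub$resno[1], chain = sub$chain[1], name = sub$resid[1],
      x = pos[1], y = pos[2], z = pos[3],
      mw = unname(wt[sub$resid[1]])
    )
  })
  out <- bind_rows(rows)
  unknown <- unique(out$name[is.na(out$mw)])
  if (length(unknown) > 0) {
    warning("non-standard residue code(s) without molecular weight: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' Coarse-grain residues to one bead per amino acid
#'
#' Each residue becomes a spherical bead of diameter
#' \eqn{\sigma = (6 M_W / \pi \rho)^{1/3}} (Angstrom), where \eqn{M_W} is the
#' residue molecular weight and \eqn{\rho} an average amino-acid density of
#' 1 g mol\eqn{^{-1}} A\eqn{^{-3}}.  Residues listed in `pka_table` become
#' titratable sites initialised in their deprotonated form (acids charged
#' \eqn{-1}, bases neutral); all other beads carry zero charge.
#'
#' @param residues residue tibble as returned by [read_pdb()].
#' @param pka_table tibble with `code`, `pka` ([default_pka_table()]).
#' @param charge_rules tibble with `code`, `q_protonated`, `q_deprotonated`
#'   ([default_charge_rules()]).
#' @param rho average residue density, g mol\eqn{^{-1}} A\eqn{^{-3}}.
#' @param weights named vector of molecular weights ([residue_weights()]).
#' @return a `cg_molecule` (amino-acid model).
#' @export
aa_coarse_grain <- function(residues, pka_table = default_pka_table(),
                            charge_rules = default_charge_rules(), rho = 1,
                            weights = residue_weights()) {
  mw <- residues$mw
  if (is.null(mw)) mw <- rep(NA_real_, nrow(residues))
  lookup <- unname(weights[residues$name])
  mw <- ifelse(is.na(mw), lookup, mw)
  if (any(is.na(mw))) {
    abort(paste0("no molecular weight for residue code(s): ",
                 paste(unique(residues$name[is.na(mw)]), collapse = ", ")))
  }
  pka <- setNames(pka_table$pka, pka_table$code)
  qp <- setNames(charge_rules$q_protonated, charge_rules$code)
  qd <- setNames(charge_rules$q_deprotonated, charge_rules$code)
  titr <- residues$name %in% pka_table$code
  beads <- tibble(
    label = residues$name,
    x = residues$x, y = residues$y, z = residues$z,
    diameter = (6 * mw / (pi * rho))^(1 / 3),
    charge = ifelse(titr, unname(qd[residues$name]), 0),
    titratable = titr,
    pka = ifelse(titr, unname(pka[residues$name]), NA_real_),
    q_protonated = ifelse(titr, unname(qp[residues$name]), 0),
    q_deprotonated = ifelse(titr, unname(qd[residues$name]), 0)
  )
  new_cg_molecule(beads, model = "amino_acid")
}

#' Build a Y-shaped N-bead antibody model
#'
#' Arranges identical tangent spheres along three straight arms meeting at a
#' junction: the two Fab arms separated by `fab_angle` and the Fc arm along
#' the negative bisector (C2v symmetry).  Supported sizes place 2, 3 or 4
#' beads per arm (6, 9, 12 beads); the 1-bead model is a single sphere.  Bead
#' positions scale linearly with the bead diameter, so `sigma` is solved in
#' closed form to make the point-bead radius of gyration match `target_rg`.
#' Charges are left at zero (assign `Q_eff / N_beads` later, e.g. with
#' [set_bead_charges()]).
#'
#' @param n_beads one of 1, 6, 9, 12.
#' @param target_rg target radius of gyration, Angstrom (ignored for
#'   `n_beads = 1` when `sigma_override` is given).
#' @param fab_angle angle between the two Fab arms, degrees.
#' @param sigma_override explicit bead diameter, Angstrom.  Required meaningful
#'   size for the 1-bead model, whose point-convention Rg is degenerate (zero);
#'   if absent the 1-bead diameter defaults to `2 * target_rg`.
#' @return a `cg_molecule` (bead model).
#' @export
build_bead_model <- function(n_beads, target_rg, fab_angle = 60,
                             sigma_override = NULL) {
  if (!n_beads %in% c(1, 6, 9, 12)) {
    abort("n_beads must be one of 1, 6, 9, 12")
  }
  if (n_beads == 1) {
    sigma <- sigma_override %||% (2 * target_rg)
    if (!is.finite(sigma) || sigma <= 0) abort("1-bead model needs a positive diameter")
    beads <- tibble(
      label = "bead", x = 0, y = 0, z = 0, diameter = sigma, charge = 0,
      titratable = FALSE, pka = NA_real_, q_protonated = 0, q_deprotonated = 0
    )
    return(new_cg_molecule(beads, model = "bead"))
  }
  if (!is.finite(target_rg) || target_rg <= 0) abort("target_rg must be > 0")
  m <- n_beads / 3
  half <- fab_angle / 2 * pi / 180
  dirs <- rbind(
    c(sin(half), cos(half), 0),
    c(-sin(half), cos(half), 0),
    c(0, -1, 0)
  )
  # unit geometry (sigma = 1): bead i of an arm at distance (i - 1/2) from the
  # junction, consecutive beads tangent
  unit <- do.call(rbind, lapply(1:3, function(a) {
    t(sapply(seq_len(m), function(i) (i - 0.5) * dirs[a, ]))
  }))
  rg_unit <- rg_points(unit)
  sigma <- if (!is.null(sigma_override)) sigma_override else target_rg / rg_unit
  coords <- unit * (target_rg / rg_unit)
  if (!is.finite(sigma) || sigma <= 0) abort("could not solve bead diameter for target_rg")
  beads <- tibble(
    label = rep(c("fab1", "fab2", "fc"), each = m),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    diameter = sigma, charge = 0, titratable = FALSE, pka = NA_real_,
    q_protonated = 0, q_deprotonated = 0
  )
  mol <- new_cg_molecule(beads, model = "bead")
  if (abs(mol$rg - target_rg) / target_rg > 1e-6) {
    abort("bead-model Rg solver failed to reach target_rg")
  }
  mol
}

#' Assign a total effective charge uniformly over the beads
#'
#' Distributes `q_total` equally (`q_bead = Q_eff / N_beads`), the convention
#' used by the bead models.
#'
#' @param mol a `cg_molecule`.
#' @param q_total net molecular charge, units of e.
#' @return the molecule with updated bead charges.
#' @export
set_bead_charges <- function(mol, q_total) {
  mol$beads$charge <- q_total / nrow(mol$beads)
  mol$net_charge <- sum(mol$beads$charge)
  mol
}

#' Radius of gyration over bead centres
#'
#' Uniform-weight point convention:
#' \eqn{R_g = \sqrt{\frac{1}{N}\sum_i |r_i - r_{cm}|^2}} (no bead-volume term).
#'
#' @param x a `cg_molecule` or an `n x 3` coordinate matrix.
#' @return radius of gyration, Angstrom.
#' @export
radius_of_gyration <- function(x) {
  coords <- if (inherits(x, "cg_molecule")) bead_coords(x) else as.matrix(x)
  if (nrow(coords) < 1) abort("need at least one bead")
  rg_points(coords)
}

#' Minimal RMSD between two conformations
#'
#' Root-mean-square deviation after optimal rigid superposition (translation
#' plus proper rotation, Kabsch), computed via \pkg{bio3d}.
#'
#' @param frame_a,frame_b `n x 3` coordinate matrices with equal row counts.
#' @param fit superpose before computing the deviation (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, fit = TRUE) {
  a <- as.matrix(frame_a)
  b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) {
    abort("frames must be n x 3 matrices with matching shapes")
  }
  as.numeric(bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = fit))
}

#' Cluster conformations by iterative RMSD neighbour counting
#'
#' The gromos-style scheme of Daura et al.: compute all pairwise (superposed)
#' RMSDs, repeatedly pick the frame with the most neighbours within `cutoff`
#' as a cluster centre, assign it and its neighbours to that cluster, remove
#' them, and iterate until all frames are assigned.  Ties are broken by the
#' lowest frame index.
#'
#' @param frames list of `n x 3` coordinate matrices (equal bead counts).
#' @param cutoff RMSD cutoff, Angstrom.
#' @return a `conformer_set`: list with `labels` (per-frame cluster id),
#'   `centers` (frame index of each cluster centre) and `n_frames`.
#' @export
daura_cluster <- function(frames, cutoff) {
  if (length(frames) < 1) abort("need at least one frame")
  if (!is.finite(cutoff) || cutoff <= 0) abort("cutoff must be > 0")
  n <- length(frames)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        d[i, j] <- d[j, i] <- rmsd(frames[[i]], frames[[j]])
      }
    }
  }
  neigh <- d <= cutoff
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- vapply(seq_len(n), function(i) {
      if (!remaining[i]) return(-1L)
      sum(neigh[i, ] & remaining)
    }, integer(1))
    center <- which.max(counts)
    members <- which(neigh[center, ] & remaining)
    labels[members] <- cl
    centers[cl] <- center
    remaining[members] <- FALSE
  }
  structure(
    list(labels = labels, centers = centers, n_frames = n, cutoff = cutoff),
    class = "conformer_set"
  )
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %d frames in %d cluster(s), cutoff %.3g A\n",
              x$n_frames, length(x$centers), x$cutoff))
  invisible(x)
}

#' Write a coarse-grained molecule as a plain-text bead table
#'
#' Columns: index, label, x, y, z (Angstrom), diameter (Angstrom), charge (e),
#' titratable flag and pKa.
#'
#' @param mol a `cg_molecule`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_beads <- function(mol, file) {
  b <- mol$beads
  df <- data.frame(
    index = seq_len(nrow(b)), label = b$label,
    x = b$x, y = b$y, z = b$z, diameter = b$diameter, charge = b$charge,
    titratable = b$titratable, pka = b$pka
  )
  writeLines(c(
    "# cgmab bead table",
    sprintf("# model = %s  net_charge = %.6g e  rg = %.6g A",
            mol$model, mol$net_charge, mol$rg)
  ), file)
  suppressWarnings(write.table(df, file, append = TRUE, row.names = FALSE,
                               quote = FALSE, sep = "\t"))
  invisible(file)
}

#' Write bead coordinates as an extended-XYZ frame
#'
#' @param mol a `cg_molecule` (or `n x 3` matrix with `labels`).
#' @param file output path.
#' @param labels per-bead element labels when `mol` is a matrix.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(mol, file, labels = NULL) {
  if (inherits(mol, "cg_molecule")) {
    coords <- bead_coords(mol)
    labels <- substr(mol$beads$label, 1, 2)
  } else {
    coords <- as.matrix(mol)
    labels <- labels %||% rep("X", nrow(coords))
  }
  lines <- c(
    as.character(nrow(coords)),
    "Properties=species:S:1:pos:R:3",
    sprintf("%s %.6f %.6f %.6f", labels, coords[, 1], coords[, 2], coords[, 3])
  )
  writeLines(lines, file)
  invisible(file)
}
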