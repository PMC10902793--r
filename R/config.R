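# Run configuration and the staged pipeline:
# structure -> titrate -> bead model -> simulate -> S_eff -> (optional) fit.

config_defaults <- function() {
  list(
    "run.outdir" = NULL,                 # required
    "run.seed" = 1,
    "structure.file" = "",               # PDB path; empty -> toy molecule
    "structure.toy_arm_residues" = 10,
    "structure.toy_arm_angle" = 60,
    "conditions.ph" = 6,
    "conditions.temperature" = 298.15,
    "conditions.eps_r" = 78.7,
    "conditions.ionic_strength" = 0.007,
    "conditions.buffer" = 0,
    "conditions.c_p" = 20,
    "conditions.mw" = 148000,
    "conditions.rg" = 48.2,
    "titration.n_sweeps" = 10000,
    "titration.moves_per_sweep" = 10,
    "titration.burn_in" = 200,
    "model.type" = "bead9",              # aa | bead1 | bead6 | bead9 | bead12
    "model.target_rg" = 48.2,
    "model.qeff" = NA,                   # NA -> titration mean net charge
    "simulate.n_p" = 50,
    "simulate.n_sweeps" = 600,
    "simulate.burn_in" = 200,
    "simulate.sample_stride" = 10,
    "simulate.eps" = 0.8,
    "scatter.p_max" = 25,
    "scatter.n_orientations" = 512,
    "fit.exp_file" = "",                 # SAXS curve path; empty -> skip fit
    "fit.qeff_grid" = "",                # "lo:hi:step"
    "fit.eps_grid" = "0.8"
  )
}

required_keys <- function() "run.outdir"

parse_grid_spec <- function(s) {
  if (is.numeric(s)) return(s)
  parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(parts) == 1) return(parts)
  if (length(parts) != 3) abort("grid spec must be a number or lo:hi:step")
  seq(parts[1], parts[2], by = parts[3])
}

#' Parse a run configuration
#'
#' Reads a flat `key = value` text file (`#` comments) and/or a named list of
#' flag overrides; flags win over file values, defaults fill the rest.
#' Unknown keys are rejected by name; all missing required keys are reported
#' at once.
#'
#' @param file optional config file path.
#' @param flags named list of overrides (e.g. `list("run.seed" = 7)`).
#' @return a `run_config` (named list of resolved values).
#' @export
parse_config <- function(file = NULL, flags = list()) {
  defaults <- config_defaults()
  vals <- defaults
  from_file <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) abort(sprintf("config file not found: %s", file))
    lines <- readLines(file, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) abort(sprintf("malformed config line: '%s'", ln))
      from_file[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  incoming <- modifyList(from_file, flags)
  unknown <- setdiff(names(incoming), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in names(incoming)) {
    v <- incoming[[k]]
    if (is.character(v) && is.numeric(defaults[[k]])) {
      vn <- suppressWarnings(as.numeric(v))
      v <- if (is.na(vn) && !identical(toupper(v), "NA")) v else vn
    }
    vals[[k]] <- v
  }
  missing <- required_keys()[vapply(required_keys(),
                                    function(k) is.null(vals[[k]]), logical(1))]
  if (length(missing) > 0) {
    abort(paste0("missing required config key(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(vals, class = "run_config")
}

write_config <- function(config, file) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.null(v)) "" else format(v))
  }, character(1))
  writeLines(c("# resolved cgmab run configuration", lines), file)
  invisible(file)
}

pipeline_log <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

#' Run the staged modelling pipeline
#'
#' Chains titration, coarse-graining, many-body simulation, effective
#' structure factor calculation and (when an experimental curve is supplied)
#' a chi-squared fit, writing every stage artifact plus the resolved config,
#' seed, package version and per-stage log into `run.outdir`.  Reruns with an
#' identical config and seed reproduce the artifacts bit-identically.
#'
#' @param config a [parse_config()] object (or a named list of flags).
#' @return list with `status` (0 on success), `artifacts` (named paths),
#'   `checksums` (md5 per artifact) and headline numbers per stage.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- parse_config(flags = config)
  outdir <- config[["run.outdir"]]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  if (file.exists(logfile)) unlink(logfile)
  seed <- as.integer(config[["run.seed"]])
  # named per-stage RNG streams derived from the single run seed
  streams <- list(titration = seed * 8 + 1, box = seed * 8 + 2,
                  mc = seed * 8 + 3, form = seed * 8 + 4, noise = seed * 8 + 5)
  artifacts <- character(0)
  stage <- "config"
  result <- list()
  run_stage <- function(name, code) {
    stage <<- name
    pipeline_log(logfile, name, "start")
    out <- tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    pipeline_log(logfile, name, "done")
    out
  }

  write_config(config, file.path(outdir, "config.resolved.txt"))
  artifacts["config"] <- file.path(outdir, "config.resolved.txt")

  cond <- solution_conditions(
    ph = config[["conditions.ph"]],
    temperature = config[["conditions.temperature"]],
    eps_r = config[["conditions.eps_r"]],
    ionic_strength = config[["conditions.ionic_strength"]],
    buffer = config[["conditions.buffer"]],
    c_p = config[["conditions.c_p"]],
    mw = config[["conditions.mw"]],
    rg = config[["conditions.rg"]]
  )

  aa_mol <- run_stage("structure", {
    if (nzchar(config[["structure.file"]])) {
      if (!file.exists(config[["structure.file"]])) {
        abort(sprintf("input structure not found: %s", config[["structure.file"]]))
      }
      res <- read_pdb(file = config[["structure.file"]])
      aa_coarse_grain(res)
    } else {
      toy_mab(n_res_per_arm = config[["structure.toy_arm_residues"]],
              arm_angle = config[["structure.toy_arm_angle"]],
              seed = seed)$molecule
    }
  })
  artifacts["aa_beads"] <- file.path(outdir, "aa_beads.txt")
  write_beads(aa_mol, artifacts["aa_beads"])

  titr <- run_stage("titrate", {
    run_constant_ph(aa_mol, cond,
                    n_sweeps = config[["titration.n_sweeps"]],
                    moves_per_sweep = config[["titration.moves_per_sweep"]],
                    burn_in = config[["titration.burn_in"]],
                    seed = streams$titration)
  })
  result$net_charge <- mean_net_charge(titr)
  artifacts["titration_trace"] <- file.path(outdir, "titration_trace.txt")
  write.table(titr$net_charge_trace, artifacts["titration_trace"],
              row.names = FALSE, quote = FALSE)
  pipeline_log(logfile, "titrate",
               sprintf("mean net charge %+0.3f e (lambda_D %.2f A)",
                       result$net_charge, titr$lambda_d))

  model <- run_stage("model", {
    type <- config[["model.type"]]
    qeff <- config[["model.qeff"]]
    if (is.character(qeff)) qeff <- suppressWarnings(as.numeric(qeff))
    if (is.na(qeff)) qeff <- result$net_charge
    result$qeff <- qeff
    if (identical(type, "aa")) {
      apply_titration_charges(aa_mol, titr)
    } else if (grepl("^bead(1|6|9|12)$", type)) {
      nb <- as.integer(sub("bead", "", type))
      set_bead_charges(
        build_bead_model(nb, target_rg = config[["model.target_rg"]]), qeff
      )
    } else {
      abort(sprintf("unknown model.type '%s'", type))
    }
  })
  artifacts["model_beads"] <- file.path(outdir, "model_beads.txt")
  write_beads(model, artifacts["model_beads"])

  traj <- run_stage("simulate", {
    box <- make_box(model, n_p = config[["simulate.n_p"]],
                    c_p = config[["conditions.c_p"]], conditions = cond,
                    eps_ij = config[["simulate.eps"]], seed = streams$box)
    run_simulation(box, n_sweeps = config[["simulate.n_sweeps"]],
                   burn_in = config[["simulate.burn_in"]],
                   sample_stride = config[["simulate.sample_stride"]],
                   seed = streams$mc)
  })
  result$acceptance <- traj$acceptance

  seff <- run_stage("sq", {
    ff <- form_factor(model, traj$box_l,
                      n_orientations = config[["scatter.n_orientations"]],
                      p_max = config[["scatter.p_max"]], seed = streams$form)
    effective_structure_factor(traj, form = ff)
  })
  artifacts["seff"] <- file.path(outdir, "seff.txt")
  write_saxs(seff, artifacts["seff"])
  result$seff_qmin <- seff$value[1]

  if (nzchar(config[["fit.exp_file"]])) {
    fit <- run_stage("fit", {
      if (!file.exists(config[["fit.exp_file"]])) {
        abort(sprintf("experimental curve not found: %s", config[["fit.exp_file"]]))
      }
      exp_curve <- read_saxs(config[["fit.exp_file"]])
      qgrid <- parse_grid_spec(config[["fit.qeff_grid"]])
      egrid <- parse_grid_spec(config[["fit.eps_grid"]])
      nb <- if (identical(config[["model.type"]], "aa")) 9L
            else as.integer(sub("bead", "", config[["model.type"]]))
      scan_chi2(
        bead_model_builder(nb, target_rg = config[["model.target_rg"]]),
        exp_curve, qeff_grid = qgrid, eps_grid = egrid,
        n_p = config[["simulate.n_p"]], c_p = config[["conditions.c_p"]],
        conditions = cond, n_sweeps = config[["simulate.n_sweeps"]],
        burn_in = config[["simulate.burn_in"]],
        sample_stride = config[["simulate.sample_stride"]],
        p_max = config[["scatter.p_max"]],
        n_orientations = config[["scatter.n_orientations"]],
        seed = streams$mc
      )
    })
    artifacts["chi2"] <- file.path(outdir, "chi2_table.csv")
    write.table(cbind(qeff = fit$qeff_grid, fit$chi2), artifacts["chi2"],
                sep = ",", row.names = FALSE, quote = FALSE)
    result$fit_qeff <- fit$argmin$qeff
    result$fit_eps <- fit$argmin$eps
  }

  meta <- file.path(outdir, "run_meta.txt")
  writeLines(c(
    sprintf("package_version = %s", as.character(utils::packageVersion("cgmab"))),
    sprintf("seed = %d", seed),
    sprintf("streams = %s", paste(sprintf("%s:%d", names(streams),
                                          unlist(streams)), collapse = " ")),
    sprintf("lambda_d_titration = %.6f", titr$lambda_d),
    sprintf("lambda_d_box = %.6f", traj$params$lambda_d),
    sprintf("phi = %.6g", traj$final_box$phi),
    sprintf("acceptance = %.4f", traj$acceptance)
  ), meta)
  artifacts["meta"] <- meta

  checks <- tools::md5sum(unname(artifacts[names(artifacts) != "meta"]))
  list(status = 0L, artifacts = artifacts, checksums = checks, result = result)
}
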