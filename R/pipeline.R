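# Deterministic per-stage seed derived from the global seed and stage name,
# so any stage can be re-run in isolation. Kept below 2^31.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647) + 1L
}

# Tiny FNV-1a hash over the deparsed config, for the manifest.
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline run configuration
#'
#' Bundles everything `run_all()` needs: which stages to run, the inputs
#' (sequences to scan, binding presets to simulate and fit, the receptor),
#' per-module options and a single global seed that fans out to per-stage
#' seeds by stage-name hashing.
#'
#' @param out_dir Output directory (created if missing at run time).
#' @param seed Global seed (default 1).
#' @param stages Stages to run, in order, among `"scan"`, `"fit"`,
#'   `"dock"`, `"traj"`.
#' @param sequences Named character vector of sequences for the scan stage;
#'   defaults to the five titration peptides.
#' @param fit_presets Preset names (see [binding_presets()]) to simulate
#'   and fit; defaults to the wild-type and mutant Fbw7gamma* complexes.
#' @param fit_noise_cv,fit_replicates,fit_points Titration simulation
#'   settings (defaults: 2% noise, triplicate, 25 points).
#' @param receptor `"toy"` (synthetic pentamer) or a path to a PDB file for
#'   the dock stage.
#' @param dock_peptide Peptide sequence to dock (default the 13-mer
#'   `PFCRRRMKRKLDH`, parent numbering from 44).
#' @param dock_first_residue Parent numbering of the docked peptide.
#' @param scan Scan options, a [scan_config()].
#' @param dock Docking options, a [docking_config()].
#' @param traj Trajectory options, a [trajectory_spec()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("scan", "fit", "dock", "traj"),
                       sequences = NULL, fit_presets = NULL,
                       fit_noise_cv = 0.02, fit_replicates = 3L,
                       fit_points = 25L, receptor = "toy",
                       dock_peptide = "PFCRRRMKRKLDH",
                       dock_first_residue = 44L,
                       scan = scan_config(), dock = docking_config(),
                       traj = trajectory_spec()) {
  if (is.null(sequences)) {
    pr <- binding_presets()
    keep <- c("wt_fbw7g", "wt_cenpw", "wt_tat", "unrelated_long",
              "unrelated_short")
    sequences <- vapply(pr[keep], `[[`, character(1), "sequence")
  }
  if (is.null(fit_presets)) {
    pr <- binding_presets()
    fit_presets <- names(pr)[vapply(pr, function(p) {
      !is.null(p$params) && p$peptide == "fbw7g"
    }, logical(1))]
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, sequences = sequences,
                 fit_presets = fit_presets, fit_noise_cv = fit_noise_cv,
                 fit_replicates = as.integer(fit_replicates),
                 fit_points = as.integer(fit_points), receptor = receptor,
                 dock_peptide = dock_peptide,
                 dock_first_residue = as.integer(dock_first_residue),
                 scan = scan, dock = dock, traj = traj),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: known stage names, existing input paths,
#' valid module options (e.g. positive search radius, scan threshold in
#' (0, 1]), and stage prerequisites (the dock stage needs a receptor).
#'
#' @param config A [run_config()].
#' @return A list with `ok` (logical) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(config) {
  errors <- character()
  add <- function(msg) errors <<- c(errors, msg)
  if (!inherits(config, "run_config")) {
    return(list(ok = FALSE, errors = "not a run_config object"))
  }
  bad <- setdiff(config$stages, c("scan", "fit", "dock", "traj"))
  if (length(bad)) add(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    add("seed: must be a single integer")
  }
  if ("scan" %in% config$stages) {
    if (!length(config$sequences)) add("sequences: none provided for scan stage")
    sc <- config$scan
    if (!inherits(sc, "scan_config")) {
      add("scan: not a scan_config")
    } else if (sc$threshold > 1 || sc$threshold <= 0) {
      add("scan$threshold: must be in (0, 1]")
    }
  }
  if ("fit" %in% config$stages) {
    pr <- binding_presets()
    missing <- setdiff(config$fit_presets, names(pr))
    if (length(missing)) {
      add(paste("fit_presets: unknown preset(s):",
                paste(missing, collapse = ", ")))
    }
    if (config$fit_noise_cv < 0) add("fit_noise_cv: must be >= 0")
    if (config$fit_points < 5L) add("fit_points: need >= 5 concentrations")
  }
  if ("dock" %in% config$stages) {
    if (is.null(config$receptor)) {
      add("receptor: required when the dock stage is requested")
    } else if (!identical(config$receptor, "toy") &&
               !file.exists(config$receptor)) {
      add(paste("receptor: file not found:", config$receptor))
    }
    dk <- config$dock
    if (!inherits(dk, "docking_config")) {
      add("dock: not a docking_config")
    } else if (dk$radius <= 0) {
      add("dock$radius: must be positive")
    }
    if (!is.null(config$dock_peptide) &&
        nchar(config$dock_peptide) < 3L) {
      add("dock_peptide: need at least a tripeptide")
    }
  }
  if ("traj" %in% config$stages &&
      !inherits(config$traj, "trajectory_spec")) {
    add("traj: not a trajectory_spec")
  }
  list(ok = !length(errors), errors = errors)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order — sequence scan, titration
#' simulation + fitting (with a Tables-1/2-style summary: complex,
#' K_D +/- s.d., fold vs wild type), hierarchical docking with its
#' salt-bridge contact report, and synthetic-trajectory RMSD analytics —
#' writing per-stage CSV outputs and a reproducibility manifest
#' (`manifest.json`: config hash, seed, per-stage seeds, package version)
#' under `config$out_dir`. Configuration is validated before any stage
#' runs. A stage failure is recorded in `error.log` and the remaining
#' stages still run; the returned report lists all errors.
#'
#' @param config A [run_config()].
#' @return A report list (class `npmhub_report`) with per-stage results,
#'   `errors`, and `manifest`.
#' @export
run_all <- function(config) {
  val <- validate_config(config)
  if (!val$ok) {
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(errors = character())
  log_err <- function(stage, e) {
    msg <- paste0(stage, ": ", conditionMessage(e))
    report$errors <<- c(report$errors, msg)
  }
  stage_seeds <- vapply(config$stages, function(s) {
    .stage_seed(config$seed, s)
  }, integer(1))

  if ("scan" %in% config$stages) {
    tryCatch({
      scans <- lapply(names(config$sequences), function(nm) {
        scan_nols(config$sequences[[nm]], config = config$scan, id = nm)
      })
      names(scans) <- names(config$sequences)
      write_scan_profile(scans, file.path(config$out_dir,
                                          "scan_profile.csv"))
      write_scan_segments(scans, file.path(config$out_dir,
                                           "scan_segments.bed"))
      report$scan <- scans
    }, error = function(e) log_err("scan", e))
  }

  if ("fit" %in% config$stages) {
    tryCatch({
      pr <- binding_presets()
      sd0 <- .stage_seed(config$seed, "fit")
      rows <- list()
      fits <- list()
      for (i in seq_along(config$fit_presets)) {
        nm <- config$fit_presets[i]
        p <- pr[[nm]]
        a_max <- if (p$params$kd <= 10) 200 else 400
        curve <- make_titration(p$params, titration_design(
          seq(0, a_max, length.out = config$fit_points),
          replicates = config$fit_replicates,
          noise_cv = config$fit_noise_cv, seed = sd0 + i))
        fits[[nm]] <- fit_titration(curve)
        rows[[nm]] <- data.frame(
          complex = nm, protein = p$protein, peptide = p$sequence,
          kd_uM = fits[[nm]]$kd_mean, kd_sd = fits[[nm]]$kd_sd)
      }
      summary_df <- do.call(rbind, rows)
      wt_row <- grep("^wt_", summary_df$complex)[1L]
      summary_df$fold_vs_wt <- if (!is.na(wt_row)) {
        summary_df$kd_uM / summary_df$kd_uM[wt_row]
      } else NA_real_
      rownames(summary_df) <- NULL
      write.csv(summary_df, file.path(config$out_dir,
                                      "binding_summary.csv"),
                row.names = FALSE)
      report$fit <- list(fits = fits, summary = summary_df)
    }, error = function(e) log_err("fit", e))
  }

  if ("dock" %in% config$stages) {
    tryCatch({
      rec <- if (identical(config$receptor, "toy")) {
        make_toy_receptor()
      } else {
        coarse_grain(read_pdb(config$receptor))
      }
      dk <- config$dock
      dk$seed <- .stage_seed(config$seed, "dock")
      hier <- run_hierarchy(rec, config$dock_peptide, dk,
                            first_residue = config$dock_first_residue)
      if (!is.null(hier$full_poses)) {
        write_pose_table(hier$full_poses,
                         file.path(config$out_dir, "docking_poses.csv"))
        write.csv(hier$salt_bridges,
                  file.path(config$out_dir, "salt_bridges.csv"),
                  row.names = FALSE)
      }
      report$dock <- hier
      report$dock_receptor <- rec
    }, error = function(e) log_err("dock", e))
  }

  if ("traj" %in% config$stages) {
    tryCatch({
      start <- if (!is.null(report$dock) && !is.null(report$dock$final)) {
        report$dock$final
      } else {
        peptide_model(config$dock_peptide,
                      first_residue = config$dock_first_residue)$coords
      }
      if (inherits(start, "pose")) {
        start <- start$coords[start$model$ca_idx, , drop = FALSE]
      } else if (nrow(start) > nchar(config$dock_peptide)) {
        start <- start[seq_len(nchar(config$dock_peptide)), , drop = FALSE]
      }
      sp <- config$traj
      sp$seed <- .stage_seed(config$seed, "traj")
      traj <- make_toy_trajectory(start, sp)
      ts <- rmsd_timeseries(traj, fit = NULL)
      prof <- per_residue_rmsd(traj, fit = NULL, selection = "all")
      write.csv(ts, file.path(config$out_dir, "traj_rmsd.csv"),
                row.names = FALSE)
      write.csv(prof, file.path(config$out_dir, "per_residue_rmsd.csv"),
                row.names = FALSE)
      report$traj <- list(trajectory = traj, timeseries = ts,
                          profile = prof)
    }, error = function(e) log_err("traj", e))
  }

  manifest <- list(
    package = "npmhub",
    version = as.character(utils::packageVersion("npmhub")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = as.list(stage_seeds),
    stages = config$stages,
    config_hash = .config_hash(unclass(config)),
    errors = report$errors)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(report$errors)) {
    writeLines(report$errors, file.path(config$out_dir, "error.log"))
    warning("pipeline finished with stage errors; see error.log")
  }
  report$manifest <- manifest
  class(report) <- "npmhub_report"
  report
}

#' @export
print.npmhub_report <- function(x, ...) {
  cat("Pipeline report (stages:",
      paste(x$manifest$stages, collapse = ", "), ")\n")
  if (!is.null(x$fit)) {
    cat("  binding summary:\n")
    print(x$fit$summary, digits = 3)
  }
  if (!is.null(x$dock)) {
    cat(sprintf("  docking: final energy %.2f kcal/mol, %d salt bridge(s)\n",
                x$dock$final$energy$total, nrow(x$dock$salt_bridges)))
  }
  if (length(x$errors)) cat("  ERRORS:", length(x$errors), "\n")
  invisible(x)
}
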