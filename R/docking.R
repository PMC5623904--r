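#' Docking protocol configuration
#'
#' Parameters of the hierarchical divide-and-conquer docking protocol.
#' Values fixed by the protocol: 20 A search radius, 10 runs per fragment,
#' 1.2 A pose-clustering cutoff, 100 full-peptide template groups, steepest
#' descent to RMS gradient 0.005 and conjugate gradients to maximum
#' gradient component 0.0004 (both in score units per A). The annealing
#' schedule, bias force constant and move sizes are this implementation's
#' own search settings.
#'
#' @param center Search-sphere centre (length-3, A) or `NULL` to centre on
#'   the receptor's largest cavity (falling back to the bead centroid).
#' @param radius Search-sphere radius, A (default 20).
#' @param runs Independent stochastic runs per fragment (default 10).
#' @param cluster_cutoff Pose-clustering RMSD cutoff, A (default 1.2).
#' @param hexamer_cap Maximum tripeptide-template combinations per hexamer
#'   window (default 25).
#' @param full_templates Number of top-scoring hexamer poses used as
#'   whole-peptide template groups (default 100).
#' @param bias_k Harmonic template-bias force constant, kcal/mol/A^2
#'   (default 10).
#' @param anneal_steps Simulated-annealing steps per run (default 3000).
#' @param t_start,t_end Annealing temperature schedule (geometric),
#'   in energy units (defaults 5 and 0.05).
#' @param quench_steps Zero-temperature (downhill-only) steps appended
#'   after annealing (default 300).
#' @param step_trans,step_rot,step_tor Proposal scales: translation (A),
#'   rigid rotation (rad), torsion change (rad).
#' @param eps_rep Soft-sphere repulsion strength, kcal/mol (default 2).
#' @param cutoff Interaction cutoff, A (default 40).
#' @param sd_tol Steepest-descent RMS-gradient threshold (default 0.005).
#' @param cg_tol Conjugate-gradient maximum-derivative threshold
#'   (default 0.0004).
#' @param seed Base RNG seed (default 1).
#' @return An object of class `docking_config`.
#' @export
docking_config <- function(center = NULL, radius = 20, runs = 10L,
                           cluster_cutoff = 1.2, hexamer_cap = 25L,
                           full_templates = 100L, bias_k = 10,
                           anneal_steps = 3000L, t_start = 5, t_end = 0.05,
                           quench_steps = 300L, step_trans = 1.5,
                           step_rot = 0.35, step_tor = 0.6, eps_rep = 2,
                           cutoff = 40, sd_tol = 0.005, cg_tol = 4e-4,
                           seed = 1L) {
  stopifnot(radius > 0, runs >= 1L, cluster_cutoff > 0, hexamer_cap >= 1L,
            full_templates >= 1L, bias_k >= 0, anneal_steps >= 1L,
            t_start > 0, t_end > 0, t_end <= t_start, eps_rep >= 0,
            cutoff > 0, sd_tol > 0, cg_tol > 0)
  if (!is.null(center)) stopifnot(length(center) == 3L, all(is.finite(center)))
  structure(list(center = center, radius = radius, runs = as.integer(runs),
                 cluster_cutoff = cluster_cutoff,
                 hexamer_cap = as.integer(hexamer_cap),
                 full_templates = as.integer(full_templates),
                 bias_k = bias_k, anneal_steps = as.integer(anneal_steps),
                 t_start = t_start, t_end = t_end,
                 quench_steps = as.integer(quench_steps),
                 step_trans = step_trans, step_rot = step_rot,
                 step_tor = step_tor, eps_rep = eps_rep, cutoff = cutoff,
                 sd_tol = sd_tol, cg_tol = cg_tol,
                 seed = as.integer(seed)),
            class = "docking_config")
}

# Resolve the search centre: explicit > cavity > bead centroid.
.search_center <- function(receptor, config) {
  if (!is.null(config$center)) return(config$center)
  cav <- find_cavity(receptor)
  if (cav$found) cav$center else colMeans(.receptor_coords(receptor))
}

#' Score a pose against a receptor
#'
#' Coarse-grained energy of a placed peptide: screened-Coulomb
#' electrostatics (`332 q_i q_j / (4 r^2)`, 40 A cutoff), soft-sphere
#' repulsion (`eps_rep (sigma_ij / r)^8`, `sigma_ij` the sum of bead
#' radii), and — when a template is active — a harmonic bias
#' `bias_k * sum |x - x_template|^2` over the mapped beads. Energies in
#' kcal/mol. Near-coincident beads are evaluated at a capped distance and
#' flagged.
#'
#' @param receptor A [receptor_model()].
#' @param pose A `pose` (from the docking functions) or bare 2n x 3
#'   coordinate matrix with `model` supplied.
#' @param config A [docking_config()].
#' @param template Optional template: `list(bead_idx, coords)` mapping pose
#'   bead rows to target coordinates.
#' @param model The `peptide_model` (required when `pose` is a matrix).
#' @return A list: `elec`, `steric`, `bias`, `total`
#'   (= elec + steric + bias) and `capped` (count of capped pairs).
#' @export
score_pose <- function(receptor, pose, config = docking_config(),
                       template = NULL, model = NULL) {
  if (inherits(pose, "pose")) {
    coords <- pose$coords
    model <- pose$model
  } else {
    coords <- pose
    if (is.null(model)) stop("supply `model` when scoring raw coordinates")
  }
  b <- receptor$beads
  e <- .cg_pair_energy(coords, model$charge, model$radius,
                       .receptor_coords(receptor), b$charge, b$radius,
                       config$eps_rep, config$cutoff)
  bias <- 0
  if (!is.null(template)) {
    d <- coords[template$bead_idx, , drop = FALSE] - template$coords
    bias <- config$bias_k * sum(d * d)
  }
  list(elec = e[1L], steric = e[2L], bias = bias,
       total = e[1L] + e[2L] + bias, capped = as.integer(e[3L]))
}

.new_pose <- function(coords, model, energy, provenance) {
  structure(list(coords = coords, model = model, energy = energy,
                 provenance = provenance), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("Pose [%s] %s: E = %.3f kcal/mol (elec %.3f, steric %.3f)\n",
              x$provenance$stage, x$model$sequence, x$energy$total,
              x$energy$elec, x$energy$steric))
  invisible(x)
}

# One simulated-annealing search. Returns the best pose seen (scored on the
# biased energy during search); caller recomputes/reports unbiased energy.
.sa_search <- function(receptor, model, config, template = NULL,
                       init_coords = NULL) {
  center <- config$.center
  radius <- config$radius
  rec_xyz <- .receptor_coords(receptor)
  rq <- receptor$beads$charge
  rr <- receptor$beads$radius
  n <- model$n_res
  if (is.null(init_coords)) {
    # random placement: uniform point in the sphere + random orientation
    repeat {
      p <- runif(3, -1, 1)
      if (sum(p * p) <= 1) break
    }
    coords <- model$coords
    ctr <- colMeans(coords)
    ax <- rnorm(3)
    coords <- .rotate_about(coords, ctr, ax, runif(1, 0, 2 * pi))
    coords <- sweep(coords, 2L, center + radius * 0.8 * p - colMeans(coords),
                    "+")
  } else {
    coords <- init_coords
  }
  tpl_idx <- if (is.null(template)) integer() else as.integer(template$bead_idx)
  tpl_coords <- if (is.null(template)) {
    matrix(0, 0L, 3L)
  } else {
    as.matrix(template$coords)
  }
  bias_k <- if (is.null(template)) 0 else config$bias_k
  res <- .sa_run(coords, n, model$charge, model$radius, rec_xyz, rq, rr,
                 config$eps_rep, config$cutoff, center, radius,
                 config$anneal_steps, config$quench_steps, config$t_start,
                 config$t_end, config$step_trans, config$step_rot,
                 config$step_tor, tpl_idx, tpl_coords, bias_k)
  list(coords = res$coords, energy = res$energy)
}

#' Dock a peptide fragment by stochastic search
#'
#' Runs `config$runs` independent seeded simulated-annealing searches over
#' the rigid-body and virtual-torsion space, each starting from a random
#' placement inside the search sphere and returning its best pose. The
#' search constrains every accepted configuration to keep at least one bead
#' inside the sphere. Identical `(config, seed)` give bit-identical output.
#'
#' @param receptor A [receptor_model()].
#' @param model A [peptide_model()] (the fragment).
#' @param config A [docking_config()].
#' @param seed_offset Integer mixed into the per-run seed, used by
#'   [run_hierarchy()] to decorrelate fragments (default 0).
#' @return A `pose_set`: list of `pose` objects (one per run), sorted by
#'   energy.
#' @export
dock_fragment <- function(receptor, model, config = docking_config(),
                          seed_offset = 0L) {
  stopifnot(inherits(receptor, "receptor_model"),
            inherits(model, "peptide_model"))
  if (config$runs < 1L) stop("config$runs must be >= 1")
  config$.center <- .search_center(receptor, config)
  poses <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    run_seed <- (config$seed + 104729 * seed_offset + 7919 * r) %% 2147483647L
    res <- with_seed(run_seed, .sa_search(receptor, model, config))
    en <- score_pose(receptor, res$coords, config, model = model)
    poses[[r]] <- .new_pose(res$coords, model, en,
                            list(stage = "fragment", run = r,
                                 seed = run_seed,
                                 fragment = model$numbering[1L]))
  }
  poses <- poses[order(vapply(poses, function(p) p$energy$total, numeric(1)))]
  structure(poses, class = "pose_set")
}

#' Template-biased docking
#'
#' Like [dock_fragment()], but each search adds a harmonic bias pulling the
#' mapped beads toward a template's coordinates, and the search starts from
#' the model rigidly superposed onto its template. The bias steers the
#' search only: reported pose energies exclude it.
#'
#' @inheritParams dock_fragment
#' @param templates List of templates, each `list(bead_idx, coords)` with
#'   `bead_idx` indexing rows of the model's coordinate matrix (Calpha rows
#'   1..n, then sidechain rows) and `coords` the matching target positions.
#' @param runs_per_template Searches per template (default 1).
#' @return A `pose_set` sorted by (unbiased) energy; each pose's provenance
#'   records its template index.
#' @export
template_dock <- function(receptor, model, templates,
                          config = docking_config(), seed_offset = 0L,
                          runs_per_template = 1L) {
  stopifnot(inherits(model, "peptide_model"), length(templates) >= 1L)
  nb <- nrow(model$coords)
  for (t in templates) {
    if (is.null(t$bead_idx) || is.null(t$coords) ||
        any(t$bead_idx < 1L) || any(t$bead_idx > nb) ||
        nrow(t$coords) != length(t$bead_idx)) {
      stop("template/model residue mismatch")
    }
  }
  config$.center <- .search_center(receptor, config)
  # with a zero bias constant the search degenerates to dock_fragment:
  # same random initialisation and per-run seeds give identical poses
  degenerate <- config$bias_k == 0
  poses <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    # initial placement: rigid superposition of mapped beads onto template
    init <- if (degenerate) NULL else tryCatch({
      k <- kabsch_superpose(model$coords[tpl$bead_idx, , drop = FALSE],
                            tpl$coords)
      sweep(model$coords %*% k$rotation, 2L, k$translation, "+")
    }, error = function(e) NULL)
    for (r in seq_len(runs_per_template)) {
      run_seed <- if (degenerate) {
        (config$seed + 104729 * seed_offset + 7919 * r) %% 2147483647L
      } else {
        (config$seed + 104729 * seed_offset + 7919 * ti +
           15485863 * r) %% 2147483647L
      }
      res <- with_seed(run_seed,
                       .sa_search(receptor, model, config,
                                  template = if (degenerate) NULL else tpl,
                                  init_coords = init))
      en <- score_pose(receptor, res$coords, config, model = model)
      poses[[length(poses) + 1L]] <-
        .new_pose(res$coords, model, en,
                  list(stage = "template", template = ti, run = r,
                       seed = run_seed, fragment = model$numbering[1L]))
    }
  }
  poses <- poses[order(vapply(poses, function(p) p$energy$total, numeric(1)))]
  structure(poses, class = "pose_set")
}

# RMSD between two conformations in the receptor frame (no superposition).
.pose_rmsd <- function(a, b) {
  d <- a - b
  sqrt(mean(rowSums(d * d)))
}

#' Cluster poses by RMSD and pick representatives
#'
#' Greedy energy-ordered clustering: the best-energy pose seeds a cluster
#' and absorbs every pose within the RMSD cutoff (computed in the receptor
#' frame, no re-superposition); the process repeats on the remainder.
#' Energy ties break on provenance (run, then template index).
#'
#' @param poses A `pose_set` or list of `pose` objects sharing a topology.
#' @param cutoff RMSD cutoff, A (default 1.2).
#' @return A list: `representatives` (a `pose_set`, energy-sorted, each
#'   with a `cluster_size` field in its provenance) and `assignment`
#'   (integer vector: representative index for each input pose).
#' @export
cluster_poses <- function(poses, cutoff = 1.2) {
  if (!length(poses)) {
    return(list(representatives = structure(list(), class = "pose_set"),
                assignment = integer()))
  }
  en <- vapply(poses, function(p) p$energy$total, numeric(1))
  tie1 <- vapply(poses, function(p) {
    as.numeric(p$provenance$run %||% 0)
  }, numeric(1))
  tie2 <- vapply(poses, function(p) {
    as.numeric(p$provenance$template %||% 0)
  }, numeric(1))
  ord <- order(en, tie1, tie2)
  assignment <- integer(length(poses))
  reps <- list()
  remaining <- ord
  while (length(remaining)) {
    seed_i <- remaining[1L]
    reps[[length(reps) + 1L]] <- seed_i
    rid <- length(reps)
    keep <- logical(length(remaining))
    for (j in seq_along(remaining)) {
      if (.pose_rmsd(poses[[seed_i]]$coords,
                     poses[[remaining[j]]]$coords) < cutoff) {
        assignment[remaining[j]] <- rid
      } else {
        keep[j] <- TRUE
      }
    }
    remaining <- remaining[keep]
  }
  representatives <- lapply(seq_along(reps), function(rid) {
    p <- poses[[reps[[rid]]]]
    p$provenance$cluster_size <- sum(assignment == rid)
    p
  })
  list(representatives = structure(representatives, class = "pose_set"),
       assignment = assignment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report salt bridges between receptor and a docked peptide
#'
#' All acidic receptor sidechain beads within `cutoff` of a basic peptide
#' sidechain bead, sorted by distance. One acidic bead close to two basic
#' beads yields two pairs (and vice versa). Peptide residues are labelled
#' in parent-protein numbering (e.g. `R47`).
#'
#' @param receptor A [receptor_model()].
#' @param pose A `pose`.
#' @param cutoff Distance cutoff, A (default 4).
#' @return Data frame: `receptor_residue`, `receptor_chain`,
#'   `peptide_residue`, `distance`.
#' @export
salt_bridges <- function(receptor, pose, cutoff = 4) {
  b <- receptor$beads
  acid <- which(b$role == "sidechain" & b$charge < 0)
  model <- pose$model
  basic <- model$sc_idx[model$charge[model$sc_idx] > 0]
  out <- data.frame(receptor_residue = character(),
                    receptor_chain = character(),
                    peptide_residue = character(), distance = numeric())
  if (!length(acid) || !length(basic)) return(out)
  axyz <- as.matrix(b[acid, c("x", "y", "z")])
  pxyz <- pose$coords[basic, , drop = FALSE]
  d <- sqrt(outer(rowSums(axyz^2), rowSums(pxyz^2), "+") -
              2 * axyz %*% t(pxyz))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(out)
  rl <- .AA3TO1[b$resname[acid[hit[, 1L]]]]
  rl[is.na(rl)] <- "X"
  pep_res <- which(model$sc_idx %in% basic[hit[, 2L]])
  # map back per hit row
  pep_i <- match(basic[hit[, 2L]], model$sc_idx)
  out <- data.frame(
    receptor_residue = paste0(rl, b$res_id[acid[hit[, 1L]]]),
    receptor_chain = b$chain[acid[hit[, 1L]]],
    peptide_residue = paste0(model$residues[pep_i],
                             model$numbering[pep_i]),
    distance = d[hit])
  out[order(out$distance), , drop = FALSE]
}

# --- gradient minimization ---------------------------------------------------

# Pose coordinates as a function of the DOF vector theta =
# (translation[3], rotation vector[3], torsion increments[n-3]) applied to
# the reference coordinates `ref`.
.pose_from_dof <- function(theta, ref, model) {
  .pose_dof(theta, ref, model$n_res)
}

#' Minimize a docked pose
#'
#' Gradient minimization over the pose degrees of freedom (rigid body plus
#' virtual torsions): steepest descent with backtracking line search until
#' the RMS gradient falls below `config$sd_tol`, then Polak-Ribiere
#' conjugate gradients until the maximum gradient component falls below
#' `config$cg_tol` (score units per A / per rad). Gradients are central
#' finite differences. Energy is non-increasing over accepted steps; an
#' energy increase beyond tolerance aborts with a flag.
#'
#' @param receptor A [receptor_model()].
#' @param pose A `pose` with finite starting energy.
#' @param config A [docking_config()].
#' @param template Optional template bias kept active during minimization
#'   (used in tests with constructed quadratic basins); the hierarchy's
#'   final minimization runs unbiased.
#' @param max_iter Iteration cap for each phase (default 300).
#' @return The minimized `pose`; its provenance gains `minimized = TRUE`,
#'   `converged` and `aborted` flags and the energy trace.
#' @export
minimize_pose <- function(receptor, pose, config = docking_config(),
                          template = NULL, max_iter = 300L) {
  stopifnot(inherits(pose, "pose"))
  model <- pose$model
  ref <- pose$coords
  rec_xyz <- .receptor_coords(receptor)
  rq <- receptor$beads$charge
  rr <- receptor$beads$radius
  e_of <- function(theta) {
    coords <- .pose_from_dof(theta, ref, model)
    e <- .cg_pair_energy(coords, model$charge, model$radius, rec_xyz, rq, rr,
                         config$eps_rep, config$cutoff)
    tot <- e[1L] + e[2L]
    if (!is.null(template)) {
      d <- coords[template$bead_idx, , drop = FALSE] - template$coords
      tot <- tot + config$bias_k * sum(d * d)
    }
    tot
  }
  np <- 6L + model$n_torsions
  grad_of <- function(theta) {
    g <- numeric(np)
    h <- 1e-5
    for (j in seq_len(np)) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      g[j] <- (e_of(tp) - e_of(tm)) / (2 * h)
    }
    g
  }
  line_search <- function(theta, e, d, step0 = 0.2) {
    step <- step0
    for (i in 1:30) {
      cand <- theta + step * d
      ec <- e_of(cand)
      if (is.finite(ec) && ec < e) return(list(theta = cand, e = ec))
      step <- step / 2
    }
    NULL
  }
  theta <- numeric(np)
  e <- e_of(theta)
  if (!is.finite(e)) stop("non-finite starting energy")
  trace <- e
  aborted <- FALSE
  # phase 1: steepest descent to RMS gradient <= sd_tol
  sd_ok <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad_of(theta)
    if (sqrt(mean(g * g)) <= config$sd_tol) { sd_ok <- TRUE; break }
    ls <- line_search(theta, e, -g / max(sqrt(sum(g * g)), 1e-12))
    if (is.null(ls)) break
    if (ls$e > e + 1e-9) { aborted <- TRUE; break }
    theta <- ls$theta; e <- ls$e
    trace <- c(trace, e)
  }
  # phase 2: conjugate gradients to max |gradient| <= cg_tol
  cg_ok <- FALSE
  g <- grad_of(theta)
  d <- -g
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) <= config$cg_tol) { cg_ok <- TRUE; break }
    dn <- sqrt(sum(d * d))
    if (dn < 1e-15) { d <- -g; dn <- sqrt(sum(d * d)) }
    ls <- line_search(theta, e, d / dn, step0 = 0.05)
    if (is.null(ls)) {
      # restart along steepest descent once before giving up
      ls <- line_search(theta, e, -g / max(sqrt(sum(g * g)), 1e-15))
      if (is.null(ls)) break
      d <- -g
    }
    if (ls$e > e + 1e-9) { aborted <- TRUE; break }
    theta <- ls$theta; e <- ls$e
    trace <- c(trace, e)
    g_new <- grad_of(theta)
    beta <- max(0, sum(g_new * (g_new - g)) / max(sum(g * g), 1e-15))
    d <- -g_new + beta * d
    g <- g_new
    if (it %% np == 0L) d <- -g
  }
  coords <- .pose_from_dof(theta, ref, model)
  en <- score_pose(receptor, coords, config, model = model)
  prov <- pose$provenance
  prov$minimized <- TRUE
  prov$converged <- sd_ok && cg_ok
  prov$aborted <- aborted
  prov$energy_trace <- trace
  .new_pose(coords, model, en, prov)
}

# --- the hierarchical protocol ----------------------------------------------

#' Run the hierarchical divide-and-conquer docking protocol
#'
#' Stage 1 exhaustively enumerates tripeptides of the target sequence and
#' docks each with `config$runs` stochastic runs, clustering the per-run
#' best poses at the RMSD cutoff into representatives. Stage 2 docks every
#' contiguous hexamer window, template-biased by the representative poses
#' of its two constituent tripeptides (positions 1-3 and 4-6), pooling up
#' to `config$hexamer_cap` template combinations per window. Stage 3
#' template-docks the whole peptide, each of the `config$full_templates`
#' top-scoring hexamer poses anchoring its own sequence window. Stage 4
#' minimizes the top pose. Sequences shorter than 6 residues stop after
#' stage 1 with an explicit notice.
#'
#' @param receptor A [receptor_model()].
#' @param sequence Peptide sequence (one-letter codes).
#' @param config A [docking_config()].
#' @param first_residue Parent numbering of the first peptide residue.
#' @return An object of class `dock_hierarchy`: `tripeptide_representatives`
#'   (per fragment), `hexamer_poses`, `full_poses` (energy-ranked),
#'   `final` (minimized top pose), `top10_mean_rmsd` (mean pairwise RMSD of
#'   the top <= 10 full-peptide poses), `salt_bridges` (for the final
#'   pose), `notice`, and the effective `config`.
#' @export
run_hierarchy <- function(receptor, sequence, config = docking_config(),
                          first_residue = 1L) {
  chars <- .check_seq(sequence)
  L <- length(chars)
  if (L < 3L) stop("need at least a tripeptide")
  config$center <- .search_center(receptor, config)

  # stage 1: exhaustive tripeptide docking + clustering
  frags <- enumerate_fragments(sequence, 3L)
  tri_reps <- vector("list", nrow(frags))
  for (i in seq_len(nrow(frags))) {
    m <- peptide_model(frags$sequence[i],
                       first_residue = first_residue + frags$start[i] - 1L)
    ps <- dock_fragment(receptor, m, config, seed_offset = i)
    tri_reps[[i]] <- cluster_poses(ps, config$cluster_cutoff)$representatives
  }
  names(tri_reps) <- frags$sequence

  if (L < 6L) {
    out <- list(tripeptide_representatives = tri_reps,
                hexamer_poses = NULL, full_poses = NULL, final = NULL,
                top10_mean_rmsd = NA_real_, salt_bridges = NULL,
                notice = "sequence shorter than 6 residues: stopped after stage 1 (tripeptide docking)",
                config = config)
    class(out) <- "dock_hierarchy"
    return(out)
  }

  # stage 2: hexamer windows guided by their two constituent tripeptides
  tri_template <- function(rep_pose, hex_model, offset) {
    # map hexamer residues offset..offset+2 (Calpha + sidechain beads)
    res <- offset:(offset + 2L)
    idx <- c(hex_model$ca_idx[res], hex_model$sc_idx[res])
    list(bead_idx = idx, coords = rep_pose$coords)
  }
  hex_poses <- list()
  for (w in seq_len(L - 5L)) {
    hex_model <- peptide_model(paste(chars[w:(w + 5L)], collapse = ""),
                               first_residue = first_residue + w - 1L)
    repsA <- tri_reps[[w]]
    repsB <- tri_reps[[w + 3L]]
    if (!length(repsA) || !length(repsB)) next
    combos <- expand.grid(a = seq_along(repsA), b = seq_along(repsB))
    esum <- vapply(seq_len(nrow(combos)), function(i) {
      repsA[[combos$a[i]]]$energy$total + repsB[[combos$b[i]]]$energy$total
    }, numeric(1))
    combos <- combos[order(esum), , drop = FALSE]
    combos <- head(combos, config$hexamer_cap)
    templates <- lapply(seq_len(nrow(combos)), function(i) {
      ta <- tri_template(repsA[[combos$a[i]]], hex_model, 1L)
      tb <- tri_template(repsB[[combos$b[i]]], hex_model, 4L)
      list(bead_idx = c(ta$bead_idx, tb$bead_idx),
           coords = rbind(ta$coords, tb$coords))
    })
    ps <- template_dock(receptor, hex_model, templates, config,
                        seed_offset = 1000L + w)
    for (p in ps) {
      p$provenance$stage <- "hexamer"
      p$provenance$window <- w
      hex_poses[[length(hex_poses) + 1L]] <- p
    }
  }
  hex_en <- vapply(hex_poses, function(p) p$energy$total, numeric(1))
  hex_poses <- hex_poses[order(hex_en)]

  # stage 3: whole peptide anchored by the top-scoring hexamer poses
  full_model <- peptide_model(sequence, first_residue = first_residue)
  top_hex <- head(hex_poses, config$full_templates)
  templates <- lapply(top_hex, function(p) {
    w <- p$provenance$window
    res <- w:(w + 5L)
    list(bead_idx = c(full_model$ca_idx[res], full_model$sc_idx[res]),
         coords = p$coords)
  })
  full_poses <- template_dock(receptor, full_model, templates, config,
                              seed_offset = 5000L)
  for (i in seq_along(full_poses)) {
    full_poses[[i]]$provenance$stage <- "full"
  }

  # stage 4: minimize the top pose
  final <- minimize_pose(receptor, full_poses[[1L]], config)
  final$provenance$stage <- "final"

  top10 <- head(full_poses, 10L)
  mean_rmsd <- if (length(top10) >= 2L) {
    pr <- utils::combn(length(top10), 2L)
    mean(vapply(seq_len(ncol(pr)), function(i) {
      .pose_rmsd(top10[[pr[1L, i]]]$coords, top10[[pr[2L, i]]]$coords)
    }, numeric(1)))
  } else NA_real_

  out <- list(tripeptide_representatives = tri_reps,
              hexamer_poses = structure(hex_poses, class = "pose_set"),
              full_poses = full_poses, final = final,
              top10_mean_rmsd = mean_rmsd,
              salt_bridges = salt_bridges(receptor, final),
              notice = NULL, config = config)
  class(out) <- "dock_hierarchy"
  out
}

#' @export
print.dock_hierarchy <- function(x, ...) {
  cat("Hierarchical docking result\n")
  if (!is.null(x$notice)) cat("  NOTE:", x$notice, "\n")
  cat("  tripeptide fragments:", length(x$tripeptide_representatives), "\n")
  if (!is.null(x$final)) {
    cat(sprintf("  final pose energy: %.3f kcal/mol (elec %.3f, steric %.3f)\n",
                x$final$energy$total, x$final$energy$elec,
                x$final$energy$steric))
    cat(sprintf("  mean pairwise RMSD of top %d poses: %.2f A\n",
                min(10L, length(x$full_poses)), x$top10_mean_rmsd))
    cat("  salt bridges:", nrow(x$salt_bridges), "\n")
  }
  invisible(x)
}

#' Export a ranked pose table as CSV
#'
#' @param poses A `pose_set` (e.g. `full_poses` of a hierarchy result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(poses, path) {
  df <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    data.frame(rank = i, stage = p$provenance$stage %||% NA,
               elec = p$energy$elec, steric = p$energy$steric,
               total = p$energy$total)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
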