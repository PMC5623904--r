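#' Coarse-grained trajectory container
#'
#' @param frames List of n x 3 coordinate matrices over a fixed topology.
#' @param times Frame times (ns), strictly increasing; defaults to
#'   `0, dt, 2 dt, ...` with `dt = 0.005` ns (one frame per 5 ps).
#' @param info Data frame describing the beads: columns `residue` (integer
#'   id) and `segment` (e.g. `"receptor"` / `"peptide"`). Defaults to one
#'   peptide segment.
#' @return An object of class `cg_trajectory`.
#' @export
trajectory <- function(frames, times = NULL, info = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok)) stop("all frames must be n x 3 matrices over one topology")
  if (is.null(times)) times <- (seq_along(frames) - 1L) * 0.005
  stopifnot(length(times) == length(frames))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(info)) {
    info <- data.frame(residue = seq_len(n), segment = "peptide")
  }
  stopifnot(nrow(info) == n, all(c("residue", "segment") %in% names(info)))
  structure(list(frames = frames, times = times, info = info),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,", nrow(x$info), "beads (",
      paste(unique(x$info$segment), collapse = ", "), "), ",
      sprintf("%.3f ns\n", max(x$times)))
  invisible(x)
}

#' Synthetic-trajectory specification
#'
#' Parameters of the anchored Ornstein-Uhlenbeck trajectory generator:
#' every bead fluctuates about its start position with a stationary
#' per-coordinate standard deviation of `sigma_anchor` (anchored residues)
#' or `sigma_free` (all others) and mean-reversion `relaxation` per frame.
#' This emulates a bound peptide whose N-terminal residues hold their
#' docked position while the rest explores conformations; it carries no
#' force field and nominal time units.
#'
#' @param n_frames Number of frames (>= 2; default 500).
#' @param dt Time per frame, ns (default 0.005, i.e. 5 ps).
#' @param anchor_residues Residue ids held near their start position
#'   (default 1:6).
#' @param sigma_anchor,sigma_free Stationary per-coordinate fluctuation
#'   scales, A (defaults 0.5 and 3; `sigma_anchor <= sigma_free`).
#' @param relaxation Mean-reversion rate per frame, in (0, 1] (default 0.1).
#' @param seed RNG seed.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 500L, dt = 0.005,
                            anchor_residues = 1:6, sigma_anchor = 0.5,
                            sigma_free = 3, relaxation = 0.1, seed = NULL) {
  stopifnot(n_frames >= 2L, dt > 0, relaxation > 0, relaxation <= 1,
            sigma_anchor >= 0, sigma_free >= 0,
            sigma_anchor <= sigma_free)
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 anchor_residues = as.integer(anchor_residues),
                 sigma_anchor = sigma_anchor, sigma_free = sigma_free,
                 relaxation = relaxation, seed = seed),
            class = "trajectory_spec")
}

#' Generate an anchored synthetic trajectory
#'
#' Per-residue Ornstein-Uhlenbeck fluctuation about the start coordinates:
#' `x[t+1] = x0 + (1 - relaxation) (x[t] - x0) + eta`, with the innovation
#' scaled so the stationary per-coordinate s.d. equals `sigma_anchor` for
#' anchored residues and `sigma_free` otherwise. Frame 0 equals the start
#' coordinates exactly.
#'
#' @param start A `pose` (its Calpha beads are used), or an n x 3
#'   coordinate matrix (one bead per residue).
#' @param spec A [trajectory_spec()].
#' @param segment Segment label(s) for the beads (default `"peptide"`).
#' @return A [trajectory()].
#' @export
make_toy_trajectory <- function(start, spec = trajectory_spec(),
                                segment = "peptide") {
  x0 <- if (inherits(start, "pose")) {
    start$coords[start$model$ca_idx, , drop = FALSE]
  } else {
    as.matrix(start)
  }
  stopifnot(ncol(x0) == 3L)
  n <- nrow(x0)
  if (length(spec$anchor_residues) &&
      max(spec$anchor_residues) > n) {
    stop("anchor_residues exceed the number of residues")
  }
  sigma <- rep(spec$sigma_free, n)
  sigma[spec$anchor_residues] <- spec$sigma_anchor
  phi <- 1 - spec$relaxation
  step_sd <- sigma * sqrt(1 - phi^2)
  frames <- vector("list", spec$n_frames)
  frames[[1L]] <- x0
  noise <- with_seed(spec$seed, {
    array(rnorm((spec$n_frames - 1L) * n * 3L), dim = c(n, 3L,
                                                        spec$n_frames - 1L))
  })
  x <- x0
  for (t in 2L:spec$n_frames) {
    x <- x0 + phi * (x - x0) + step_sd * noise[, , t - 1L]
    frames[[t]] <- x
  }
  trajectory(frames, times = (seq_len(spec$n_frames) - 1L) * spec$dt,
             info = data.frame(residue = seq_len(n),
                               segment = rep(segment, length.out = n)))
}

#' Write / read a trajectory as a multi-model PDB
#'
#' One MODEL per frame, one CA pseudo-atom per bead; bead segment is stored
#' as the chain identifier (first letter, uppercased).
#'
#' @param traj A `cg_trajectory`.
#' @param path File path.
#' @return `write_trajectory_pdb()` returns `path` invisibly;
#'   `read_trajectory_pdb()` returns a `cg_trajectory` (times reconstructed
#'   at `dt` ns per frame).
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  chain <- toupper(substr(traj$info$segment, 1L, 1L))
  models <- lapply(traj$frames, function(f) {
    data.frame(record = "ATOM", serial = seq_len(nrow(f)), name = "CA",
               altloc = "", resname = "ALA", chain = chain,
               resseq = traj$info$residue, icode = "",
               x = f[, 1L], y = f[, 2L], z = f[, 3L],
               occupancy = 1, bfactor = 0, element = "C")
  })
  write_pdb(models, path)
}

#' @rdname write_trajectory_pdb
#' @param dt Time per frame when reading, ns (default 0.005).
#' @export
read_trajectory_pdb <- function(path, dt = 0.005) {
  s <- read_pdb(path)
  frames <- lapply(s$models, function(m) {
    as.matrix(m[, c("x", "y", "z")])
  })
  m1 <- s$models[[1L]]
  segment <- ifelse(m1$chain == "R", "receptor", "peptide")
  trajectory(frames, times = (seq_along(frames) - 1L) * dt,
             info = data.frame(residue = m1$resseq, segment = segment))
}
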