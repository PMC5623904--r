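#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (determinant +1) and translation minimizing
#' the (optionally weighted) RMSD between two paired point sets, via the
#' SVD of the weighted covariance matrix. The transformed mobile set is
#' `mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @param weights Optional non-negative per-point weights.
#' @return A list: `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (the minimized weighted RMSD) and `transformed` (the superposed
#'   mobile coordinates).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(12), 4)
#' kabsch_superpose(x, x)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L) {
    stop("mobile and reference must be matched n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2L, cm)
  R <- sweep(reference, 2L, cr)
  H <- t(M * w) %*% R
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-300)) {
    stop("degenerate (collinear) point set: superposition not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transformed <- sweep(M %*% rot, 2L, cr, "+")
  diff <- transformed - reference
  rmsd <- sqrt(sum(w * rowSums(diff * diff)))
  list(rotation = rot, translation = cr - as.numeric(cm %*% rot),
       rmsd = rmsd, transformed = transformed)
}

# Plain (unweighted) coordinate RMSD without superposition.
rmsd_coords <- function(a, b) {
  d <- a - b
  sqrt(mean(rowSums(d * d)))
}

.resolve_selection <- function(traj, sel) {
  if (is.null(sel) || identical(sel, "all")) return(seq_len(nrow(traj$info)))
  if (is.character(sel)) {
    idx <- which(traj$info$segment %in% sel)
  } else {
    idx <- as.integer(sel)
  }
  if (!length(idx)) stop("empty selection")
  idx
}

#' Calpha RMSD time series
#'
#' For each frame: superpose onto the reference frame using the fit
#' selection (typically the receptor Calphas), then compute the RMSD over
#' the measure selection (e.g. the whole complex or the peptide). With
#' `fit = NULL` no superposition is applied.
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame index (default 1).
#' @param fit Fit selection: segment name(s), bead indices, or `NULL`
#'   (default `"receptor"` when present, else no fit).
#' @param measure Measure selection (default `"all"`).
#' @return Data frame with columns `time_ns` and `rmsd_A`.
#' @export
rmsd_timeseries <- function(traj, reference = 1L, fit = "receptor",
                            measure = "all") {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (identical(fit, "receptor") && !"receptor" %in% traj$info$segment) {
    fit <- NULL
  }
  fit_idx <- if (is.null(fit)) NULL else .resolve_selection(traj, fit)
  meas_idx <- .resolve_selection(traj, measure)
  ref <- traj$frames[[reference]]
  rmsd <- vapply(traj$frames, function(f) {
    if (!is.null(fit_idx)) {
      k <- kabsch_superpose(f[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
      f <- sweep(f %*% k$rotation, 2L, k$translation, "+")
    }
    rmsd_coords(f[meas_idx, , drop = FALSE],
                ref[meas_idx, , drop = FALSE])
  }, numeric(1))
  data.frame(time_ns = traj$times, rmsd_A = rmsd)
}

#' Per-residue time-averaged RMSD profile
#'
#' After per-frame superposition on the fit selection, computes for each
#' selected bead the quadratic-mean displacement from its reference
#' position over frames: `sqrt(mean_t |x_i(t) - x_i(ref)|^2)`. All
#' averaging is quadratic, so the residue-wise quadratic mean of the
#' profile equals the quadratic time-average of the selection RMSD.
#'
#' @inheritParams rmsd_timeseries
#' @param selection Beads to profile (default `"peptide"`).
#' @param burn_in Number of initial frames to drop from the average
#'   (default 0: full-trajectory average).
#' @return Data frame with columns `residue`, `segment`, `rmsd_A`.
#' @export
per_residue_rmsd <- function(traj, reference = 1L, fit = "receptor",
                             selection = "peptide", burn_in = 0L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (identical(fit, "receptor") && !"receptor" %in% traj$info$segment) {
    fit <- NULL
  }
  if (identical(selection, "peptide") &&
      !"peptide" %in% traj$info$segment) {
    selection <- "all"
  }
  fit_idx <- if (is.null(fit)) NULL else .resolve_selection(traj, fit)
  sel_idx <- .resolve_selection(traj, selection)
  ref <- traj$frames[[reference]]
  use <- which(seq_along(traj$frames) > burn_in)
  if (!length(use)) stop("burn_in removes every frame")
  acc <- matrix(0, length(sel_idx), 1L)
  for (t in use) {
    f <- traj$frames[[t]]
    if (!is.null(fit_idx)) {
      k <- kabsch_superpose(f[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
      f <- sweep(f %*% k$rotation, 2L, k$translation, "+")
    }
    d <- f[sel_idx, , drop = FALSE] - ref[sel_idx, , drop = FALSE]
    acc <- acc + rowSums(d * d)
  }
  data.frame(residue = traj$info$residue[sel_idx],
             segment = traj$info$segment[sel_idx],
             rmsd_A = sqrt(acc[, 1L] / length(use)))
}
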