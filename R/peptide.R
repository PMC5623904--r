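# --- small geometry helpers -------------------------------------------------

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for axis-angle (Rodrigues); coords are row vectors, so
# apply as  x %*% t(R).
.rot_axis_angle <- function(axis, angle) {
  u <- .unit(axis)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
}

# Rotate rows of `coords` about the line through `origin` with `axis`.
.rotate_about <- function(coords, origin, axis, angle) {
  R <- .rot_axis_angle(axis, angle)
  sweep(sweep(coords, 2L, origin) %*% t(R), 2L, origin, "+")
}

# --- peptide construction ---------------------------------------------------

# Extended virtual-Calpha chain: bond 3.8 A, virtual bond angle 120 deg,
# torsions (n-3 of them) default 180 deg (trans).
.build_ca_chain <- function(n, torsions = NULL) {
  stopifnot(n >= 1L)
  L <- 3.8
  theta <- 120 * pi / 180
  ca <- matrix(0, n, 3)
  if (n >= 2L) ca[2L, ] <- c(L, 0, 0)
  if (n >= 3L) ca[3L, ] <- ca[2L, ] + L * c(cos(pi - theta), sin(pi - theta), 0)
  if (n >= 4L) {
    if (is.null(torsions)) torsions <- rep(pi, n - 3L)
    stopifnot(length(torsions) == n - 3L)
    for (i in 4L:n) {
      tau <- torsions[i - 3L]
      p1 <- ca[i - 3L, ]; p2 <- ca[i - 2L, ]; p3 <- ca[i - 1L, ]
      bc <- .unit(p3 - p2)
      nrm <- .unit(.cross3(p2 - p1, bc))
      m <- .cross3(nrm, bc)
      d <- L * (-bc * cos(theta) + m * sin(theta) * cos(tau) +
                  nrm * sin(theta) * sin(tau))
      ca[i, ] <- p3 + d
    }
  }
  ca
}

# Sidechain bead positions given Calpha coordinates: along the local
# "outward" direction (sum of unit vectors away from the flanking Calphas),
# at the per-residue sidechain length. Glycine stays on the Calpha.
.place_sidechains <- function(ca, residues) {
  n <- nrow(ca)
  sc <- ca
  for (i in seq_len(n)) {
    len <- unname(.CG_PARAMS$sc_length[residues[i]])
    if (is.na(len)) len <- 2.5
    if (len == 0 || n == 1L) next
    d <- if (i == 1L) {
      .unit(ca[1L, ] - ca[2L, ])
    } else if (i == n) {
      .unit(ca[n, ] - ca[n - 1L, ])
    } else {
      v <- .unit(ca[i, ] - ca[i - 1L, ]) + .unit(ca[i, ] - ca[i + 1L, ])
      if (sqrt(sum(v * v)) < 1e-8) {
        ax <- .cross3(ca[i + 1L, ] - ca[i - 1L, ], c(0, 0, 1))
        if (sqrt(sum(ax * ax)) < 1e-8) ax <- c(0, 1, 0)
        ax
      } else v
    }
    sc[i, ] <- ca[i, ] + len * .unit(d)
  }
  sc
}

#' Coarse-grained flexible peptide model
#'
#' Two beads per residue: a backbone bead on the virtual Calpha trace
#' (consecutive Calpha distance fixed at 3.8 A) and a sidechain bead at the
#' residue's sidechain-centroid distance, carrying the formal charge
#' (K/R +1, D/E -1). Degrees of freedom are the six rigid-body ones plus
#' virtual torsions about consecutive Calpha-Calpha axes. The model is
#' built in an extended (trans) conformation.
#'
#' @param sequence One-letter amino-acid string (length >= 1).
#' @param first_residue Parent-protein number of the first residue, used in
#'   reports (e.g. 44 for the docked Fbw7gamma peptide PFCRRRMKRKLDH,
#'   residues 44-56).
#' @param charge_rules Named charges per one-letter code.
#' @return An object of class `peptide_model`: fields `sequence`,
#'   `residues`, `numbering`, `n_res`, `coords` (2n x 3 reference
#'   coordinates: Calpha rows then sidechain rows), `ca_idx`, `sc_idx`,
#'   `charge`, `radius`, `n_torsions`.
#' @examples
#' pep <- peptide_model("PFCRRRMKRKLDH", first_residue = 44)
#' sum(pep$charge)  # +5: six basic residues, one aspartate
#' @export
peptide_model <- function(sequence, first_residue = 1L,
                          charge_rules = .DEFAULT_CHARGE_RULES) {
  residues <- .check_seq(sequence)
  n <- length(residues)
  ca <- .build_ca_chain(n)
  sc <- .place_sidechains(ca, residues)
  q_sc <- vapply(residues, function(r) {
    if (r %in% names(charge_rules)) unname(charge_rules[r]) else 0
  }, numeric(1), USE.NAMES = FALSE)
  rad_sc <- unname(.CG_PARAMS$sc_radius[residues])
  rad_sc[is.na(rad_sc)] <- 1.8
  structure(list(
    sequence = paste(residues, collapse = ""),
    residues = residues,
    numbering = seq.int(first_residue, length.out = n),
    n_res = n,
    coords = rbind(ca, sc),
    ca_idx = seq_len(n),
    sc_idx = n + seq_len(n),
    charge = c(rep(0, n), q_sc),
    radius = c(rep(.CG_PARAMS$bb_radius, n), rad_sc),
    n_torsions = max(n - 3L, 0L)
  ), class = "peptide_model")
}

#' @export
print.peptide_model <- function(x, ...) {
  cat("Coarse-grained peptide ", x$sequence, " (residues ",
      x$numbering[1L], "-", x$numbering[x$n_res], "), net charge ",
      sum(x$charge), " e, ", x$n_torsions, " virtual torsion(s)\n",
      sep = "")
  invisible(x)
}

# Apply a torsion increment about the Calpha(i)-Calpha(i+1) axis: rotates
# every bead beyond the bond (Calphas i+2..n, their sidechains, and the
# sidechain of residue i+1, whose orientation rides on the dihedral).
.apply_torsion <- function(coords, model, bond, dangle) {
  n <- model$n_res
  stopifnot(bond >= 2L, bond <= n - 2L)
  o <- coords[model$ca_idx[bond], ]
  axis <- coords[model$ca_idx[bond + 1L], ] - o
  move <- c(model$ca_idx[(bond + 2L):n], model$sc_idx[(bond + 1L):n])
  coords[move, ] <- .rotate_about(coords[move, , drop = FALSE], o, axis,
                                  dangle)
  coords
}

#' Enumerate contiguous sequence fragments
#'
#' All `L - k + 1` contiguous k-mers of a sequence with their 1-based
#' parent start positions, in order.
#'
#' @param sequence One-letter amino-acid string of length L >= k.
#' @param k Fragment length (default 3: tripeptides).
#' @return Data frame with columns `start`, `end`, `sequence`.
#' @examples
#' nrow(enumerate_fragments("PFCRRRMKRKLDH", 3))  # 11
#' @export
enumerate_fragments <- function(sequence, k = 3L) {
  chars <- .check_seq(sequence)
  L <- length(chars)
  if (L < k) stop("sequence shorter than fragment length k")
  stopifnot(k >= 1L)
  starts <- seq_len(L - k + 1L)
  data.frame(start = starts, end = starts + k - 1L,
             sequence = vapply(starts, function(s) {
               paste(chars[s:(s + k - 1L)], collapse = "")
             }, character(1)))
}
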