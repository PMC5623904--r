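# Shared fixtures and small independent oracles.

# One toy receptor reused across tests (construction is deterministic).
toy_rec <- make_toy_receptor()

toy_acid_xyz <- function(rec = toy_rec) {
  as.matrix(rec$beads[rec$beads$charge < 0, c("x", "y", "z")])
}

# How many basic sidechain beads of a pose are within `cutoff` of any
# acidic receptor bead.
n_basic_contacts <- function(pose, rec = toy_rec, cutoff = 4) {
  acid <- toy_acid_xyz(rec)
  sc <- pose$coords[pose$model$sc_idx, , drop = FALSE]
  basic <- pose$model$charge[pose$model$sc_idx] > 0
  sc <- sc[basic, , drop = FALSE]
  sum(apply(sc, 1L, function(v) {
    min(sqrt(colSums((t(acid) - v)^2))) <= cutoff
  }))
}

# Independent equilibrium oracle: solve (n - c)(a - c) = kd * c for the
# complex concentration by root bracketing (no closed form used).
bound_complex_oracle <- function(a, n, kd) {
  vapply(a, function(ai) {
    if (ai == 0) return(0)
    f <- function(cc) (n - cc) * (ai - cc) - kd * cc
    stats::uniroot(f, c(0, min(n, ai)), tol = 1e-14)$root
  }, numeric(1))
}

# Brute-force rigid-superposition oracle: minimize RMSD over rotations
# parameterised by Euler angles, multistart + Nelder-Mead refinement.
kabsch_oracle_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2L, cm)
  R <- sweep(reference, 2L, cr)
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) {
    d <- M %*% t(rot_euler(ang)) - R
    sqrt(mean(rowSums(d * d)))
  }
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(-pi / 3, 0.4, pi / 3),
                                  c = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (r$value < best) best <- r$value
  }
  best
}

# Write a small hand-built PDB fixture; returns the path.
write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          record = "ATOM", element = "C") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resseq, x, y, z, 1, 0,
          element)
}
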