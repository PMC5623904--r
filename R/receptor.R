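# Per-residue coarse-grain parameters: sidechain bead distance from CA (A)
# and bead radius (A). Radii are deliberately compact so that an ion pair
# (sigma ~ 3.4-3.6 A) equilibrates below the 4 A salt-bridge cutoff.
.CG_PARAMS <- local({
  aa <- c("G", "A", "S", "C", "T", "P", "V", "N", "D", "I", "L", "E", "Q",
          "M", "K", "H", "F", "R", "Y", "W")
  len <- c(0, 1.5, 1.9, 2.0, 1.9, 1.9, 2.0, 2.5, 2.5, 2.3, 2.6, 3.1, 3.1,
           2.9, 3.5, 3.0, 3.4, 4.1, 3.8, 3.9)
  rad <- c(1.5, 1.6, 1.7, 1.7, 1.7, 1.8, 1.8, 1.8, 1.8, 1.9, 1.9, 1.9, 1.9,
           1.9, 1.8, 1.9, 2.0, 1.9, 2.0, 2.0)
  list(sc_length = setNames(len, aa), sc_radius = setNames(rad, aa),
       bb_radius = 1.9)
})

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.DEFAULT_CHARGE_RULES <- c(K = 1, R = 1, D = -1, E = -1)

#' Construct a coarse-grained receptor model
#'
#' @param beads Data frame with columns `res_id`, `resname`, `chain`,
#'   `role` (`"backbone"` or `"sidechain"`), `x`, `y`, `z`, `charge` (in
#'   units of e, each 0 or +/-1), `radius` (A).
#' @param metadata Optional list (symmetry order, planted optimum for
#'   synthetic receptors, source info).
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(beads, metadata = list()) {
  need <- c("res_id", "resname", "chain", "role", "x", "y", "z",
            "charge", "radius")
  stopifnot(is.data.frame(beads), all(need %in% names(beads)))
  stopifnot(all(abs(beads$charge) %in% c(0, 1)),
            all(beads$radius > 0),
            all(is.finite(beads$x)), all(is.finite(beads$y)),
            all(is.finite(beads$z)))
  structure(list(beads = beads, metadata = metadata),
            class = "receptor_model")
}

#' @export
print.receptor_model <- function(x, ...) {
  b <- x$beads
  cat("Coarse-grained receptor:", nrow(b), "beads,",
      length(unique(paste(b$chain, b$res_id))), "residues, net charge",
      sum(b$charge), "e\n")
  if (!is.null(x$metadata$symmetry)) {
    cat("  ", x$metadata$symmetry, "-fold symmetric synthetic receptor\n",
        sep = "")
  }
  invisible(x)
}

.receptor_coords <- function(receptor) {
  as.matrix(receptor$beads[, c("x", "y", "z")])
}

#' Coarse-grain a structure into charged beads
#'
#' Reduces each residue to one backbone bead at the Calpha position and one
#' sidechain bead at the centroid of its sidechain heavy atoms (glycine's
#' sidechain bead is co-located with the Calpha). Sidechain beads carry the
#' residue formal charge (by default K/R +1, D/E -1, others 0); radii come
#' from a per-residue table. Residues without a Calpha are skipped with a
#' warning.
#'
#' @param structure A `pdb_structure` from [read_pdb()].
#' @param charge_rules Named numeric vector mapping one-letter residue
#'   codes to formal charges.
#' @param model Which model of a multi-model file to use (default 1).
#' @return A [receptor_model()].
#' @export
coarse_grain <- function(structure, charge_rules = .DEFAULT_CHARGE_RULES,
                         model = 1L) {
  stopifnot(inherits(structure, "pdb_structure"))
  at <- structure$models[[model]]
  at <- at[at$record %in% c("ATOM", "HETATM") & at$element != "H", ]
  key <- paste(at$chain, at$resseq, at$icode, sep = "|")
  rows <- list()
  skipped <- 0L
  for (k in unique(key)) {
    res <- at[key == k, ]
    ca <- res[res$name == "CA", ]
    if (!nrow(ca)) {
      skipped <- skipped + 1L
      next
    }
    ca <- ca[1L, ]
    aa1 <- unname(.AA3TO1[ca$resname])
    if (is.na(aa1)) aa1 <- "A"  # unknown residues treated as neutral/compact
    side <- res[!res$name %in% c("N", "CA", "C", "O", "OXT"), ]
    sc_pos <- if (nrow(side)) {
      c(mean(side$x), mean(side$y), mean(side$z))
    } else {
      c(ca$x, ca$y, ca$z)  # glycine and missing sidechains
    }
    q <- if (aa1 %in% names(charge_rules)) unname(charge_rules[aa1]) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      res_id = rep(ca$resseq, 2L), resname = rep(ca$resname, 2L),
      chain = rep(ca$chain, 2L), role = c("backbone", "sidechain"),
      x = c(ca$x, sc_pos[1L]), y = c(ca$y, sc_pos[2L]),
      z = c(ca$z, sc_pos[3L]), charge = c(0, q),
      radius = c(.CG_PARAMS$bb_radius,
                 unname(.CG_PARAMS$sc_radius[aa1]))
    )
  }
  if (skipped) {
    warning(skipped, " residue(s) without Calpha skipped")
  }
  if (!length(rows)) stop("no residues with Calpha found")
  receptor_model(do.call(rbind, rows),
                 metadata = list(source = structure$path))
}

#' Specification of a synthetic crown-shaped receptor
#'
#' Describes a pentamer-like toy receptor: `n_fold` monomers arranged with
#' exact rotational symmetry about the z axis, each contributing
#' `acidic_per_monomer` acidic (-1) beads lining a central pore of radius
#' `ring_radius`, and a shell of neutral body beads at `neutral_radius`.
#'
#' @param n_fold Rotational symmetry order (>= 3; default 5, a pentamer).
#' @param ring_radius Radius of the acidic pore lining, A (default 3.6;
#'   must exceed twice the bead radius).
#' @param acidic_per_monomer Acidic beads per monomer (default 3).
#' @param neutral_count Neutral shell beads per monomer (default 8).
#' @param neutral_radius Radius of the neutral shell, A (default 9).
#' @param bead_radius Bead radius, A (default 1.7).
#' @return An object of class `toy_receptor_spec`.
#' @export
toy_receptor_spec <- function(n_fold = 5L, ring_radius = 3.6,
                              acidic_per_monomer = 3L, neutral_count = 8L,
                              neutral_radius = 9, bead_radius = 1.7) {
  stopifnot(n_fold >= 3L, ring_radius > 2 * bead_radius,
            acidic_per_monomer >= 0L, neutral_count >= 0L,
            neutral_radius > 0, bead_radius > 0)
  structure(list(n_fold = as.integer(n_fold), ring_radius = ring_radius,
                 acidic_per_monomer = as.integer(acidic_per_monomer),
                 neutral_count = as.integer(neutral_count),
                 neutral_radius = neutral_radius, bead_radius = bead_radius),
            class = "toy_receptor_spec")
}

#' Build a synthetic crown-shaped receptor
#'
#' Places beads with exact `n_fold` rotational symmetry about the z axis:
#' acidic beads form stacked rings (z levels 6 A apart, 36 degree angular
#' stagger per level): a tight equatorial ring that focuses the
#' electrostatic funnel on the pore centre within salt-bridge range (4 A)
#' of a buried bead, flanked above and below by rings flared 2 A outward
#' whose rims offer multivalent contacts to a peptide exiting the pore.
#' Neutral beads form an outer body wall.
#' The total charge is `-n_fold * acidic_per_monomer`. The pore centre
#' (the origin) is recorded in the metadata as the planted optimum
#' location, making docking recovery tests objective. Overlapping beads
#' (pairwise distance below the sum of radii) are rejected.
#'
#' @param spec A [toy_receptor_spec()].
#' @return A [receptor_model()] with metadata fields `symmetry`, `axis`,
#'   `planted_optimum`, `synthetic` and `spec`.
#' @examples
#' rec <- make_toy_receptor(toy_receptor_spec())
#' sum(rec$beads$charge)  # -15
#' @export
make_toy_receptor <- function(spec = toy_receptor_spec()) {
  stopifnot(inherits(spec, "toy_receptor_spec"))
  z_step_acid <- 6.0
  z_step_shell <- 3.5
  stagger <- 36 * pi / 180
  flare <- 2.0
  rows <- list()
  rid <- 0L
  for (m in seq_len(spec$n_fold)) {
    theta <- 2 * pi * (m - 1L) / spec$n_fold
    ch <- LETTERS[m]
    A <- spec$acidic_per_monomer
    for (j in seq_len(A)) {
      # symmetric crown profile: a tight equatorial ring focusing the
      # electrostatic funnel on the origin, flanked by rings flaring
      # outward above and below that offer multivalent rim contacts
      off <- j - (A + 1) / 2
      phi <- theta + off * stagger
      r_j <- spec$ring_radius + abs(off) * flare
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        res_id = rid, resname = "GLU", chain = ch, role = "sidechain",
        x = r_j * cos(phi), y = r_j * sin(phi),
        z = off * z_step_acid, charge = -1, radius = spec$bead_radius)
    }
    nc <- spec$neutral_count
    if (nc > 0L) {
      nlvl <- ceiling(nc / 2)
      for (kk in seq_len(nc)) {
        col <- (kk - 1L) %% 2L
        lvl <- (kk - 1L) %/% 2L
        phi <- theta + (col - 0.5) * (pi / spec$n_fold)
        rid <- rid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          res_id = rid, resname = "ALA", chain = ch, role = "backbone",
          x = spec$neutral_radius * cos(phi),
          y = spec$neutral_radius * sin(phi),
          z = (lvl - (nlvl - 1) / 2) * z_step_shell, charge = 0,
          radius = spec$bead_radius)
      }
    }
  }
  beads <- do.call(rbind, rows)
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  if (nrow(xyz) > 1L) {
    dmin <- min(dist(xyz))
    if (dmin < 2 * spec$bead_radius) {
      stop(sprintf(
        "overlapping beads in toy receptor (min distance %.2f A < %.2f A)",
        dmin, 2 * spec$bead_radius))
    }
  }
  receptor_model(beads, metadata = list(
    symmetry = spec$n_fold, axis = c(0, 0, 1),
    planted_optimum = c(0, 0, 0), synthetic = TRUE, spec = spec))
}

#' Export a coarse-grained receptor as a single-model PDB
#'
#' One pseudo-atom per bead (`CA` for backbone beads, `CB` for sidechain
#' beads); the bead charge is stored in the B-factor column.
#'
#' @param receptor A [receptor_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  b <- receptor$beads
  df <- data.frame(
    record = "ATOM", serial = seq_len(nrow(b)),
    name = ifelse(b$role == "backbone", "CA", "CB"),
    altloc = "", resname = b$resname, chain = b$chain,
    resseq = b$res_id, icode = "", x = b$x, y = b$y, z = b$z,
    occupancy = 1, bfactor = b$charge, element = "C")
  write_pdb(df, path)
}

#' Read a coarse-grained receptor written by [write_receptor_pdb()]
#'
#' @param path PDB path (charges in the B-factor column).
#' @return A [receptor_model()].
#' @export
read_receptor_pdb <- function(path) {
  at <- read_pdb(path)$models[[1L]]
  receptor_model(data.frame(
    res_id = at$resseq, resname = at$resname, chain = at$chain,
    role = ifelse(at$name == "CA", "backbone", "sidechain"),
    x = at$x, y = at$y, z = at$z, charge = at$bfactor,
    radius = ifelse(at$name == "CA", .CG_PARAMS$bb_radius, 1.7)),
    metadata = list(source = path))
}
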