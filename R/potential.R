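# Axis-aligned probe grid over the receptor bounding box. Returns the probe
# points (N x 3), their integer grid indices and the spacing.
.probe_grid <- function(receptor, spacing, padding) {
  xyz <- .receptor_coords(receptor)
  lo <- floor(apply(xyz, 2, min) - padding)
  hi <- ceiling(apply(xyz, 2, max) + padding)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  idx <- as.matrix(expand.grid(ix = seq_along(gx), iy = seq_along(gy),
                               iz = seq_along(gz)))
  list(points = pts, idx = idx, dims = c(length(gx), length(gy),
                                         length(gz)))
}

# Minimum (distance - per-bead clearance) from each point to any bead,
# chunked to bound memory.
.min_clearance <- function(points, beads_xyz, clearance) {
  n <- nrow(points)
  out <- numeric(n)
  chunk <- 4000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(beads_xyz^2), "+") -
      2 * p %*% t(beads_xyz)
    d <- sqrt(pmax(d2, 0))
    out[s:e] <- apply(sweep(d, 2L, clearance, "-"), 1L, min)
  }
  out
}

#' Screened-Coulomb surface potential on a probe grid
#'
#' Evaluates the electrostatic potential of the coarse-grained receptor at
#' solvent-accessible grid points, per unit probe charge:
#' `V(p) = sum_i 332 q_i / (eps(r_i) r_i)` with the distance-dependent
#' dielectric `eps(r) = 4r` and a 40 A cutoff (kcal/mol/e). Probes inside
#' beads — within bead radius plus the solvent probe radius — are excluded.
#' This is a qualitative surrogate for Poisson-Boltzmann surface maps: it
#' locates charged patches, not absolute potentials.
#'
#' @param receptor A [receptor_model()] with at least one charged bead.
#' @param spacing Grid spacing, A (default 1).
#' @param padding Grid padding beyond the bead bounding box, A (default 4).
#' @param cutoff Electrostatic cutoff, A (default 40).
#' @param probe Solvent probe radius added to bead radii when excluding
#'   interior points, A (default 1.4).
#' @return A `potential_map`: data frame with columns `x`, `y`, `z`,
#'   `potential`, with the generating parameters as attributes.
#' @export
surface_potential <- function(receptor, spacing = 1, padding = 4,
                              cutoff = 40, probe = 1.4) {
  stopifnot(inherits(receptor, "receptor_model"))
  b <- receptor$beads
  if (!any(b$charge != 0)) stop("receptor has no charged bead")
  g <- .probe_grid(receptor, spacing, padding)
  xyz <- .receptor_coords(receptor)
  keep <- .min_clearance(g$points, xyz, b$radius + probe) > 0
  pts <- g$points[keep, , drop = FALSE]
  v <- .cg_potential(pts, xyz, b$charge, cutoff)
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], potential = v)
  structure(out, spacing = spacing, cutoff = cutoff, probe = probe,
            padding = padding, class = c("potential_map", "data.frame"))
}

#' Locate the most negatively charged surface patch
#'
#' Takes the probes in the lowest-potential quantile (negative only),
#' clusters them by single linkage at 3 A, keeps the largest cluster, and
#' reports every receptor residue having a charged bead within 6 A of that
#' cluster, together with the patch centroid.
#'
#' @param map A `potential_map` computed on `receptor`.
#' @param receptor The matching [receptor_model()].
#' @param quantile Lower-tail quantile defining "lowest potential"
#'   (default 0.05).
#' @param link_cutoff Single-linkage distance, A (default 3).
#' @param residue_cutoff Charged-bead-to-patch distance, A (default 6).
#' @return A list with `residues` (data frame `res_id`, `chain`, `resname`),
#'   `centroid` (length-3 vector) and `n_probes`. Empty `residues` and
#'   `NULL` centroid when no probe is negative.
#' @export
acidic_patch <- function(map, receptor, quantile = 0.05, link_cutoff = 3,
                         residue_cutoff = 6) {
  stopifnot(inherits(map, "potential_map"),
            inherits(receptor, "receptor_model"))
  thr <- stats::quantile(map$potential, quantile)
  sel <- map$potential <= thr & map$potential < 0
  if (!any(sel)) {
    return(list(residues = data.frame(res_id = integer(),
                                      chain = character(),
                                      resname = character()),
                centroid = NULL, n_probes = 0L))
  }
  pts <- as.matrix(map[sel, c("x", "y", "z")])
  cl <- if (nrow(pts) == 1L) {
    1L
  } else {
    cutree(hclust(dist(pts), method = "single"), h = link_cutoff)
  }
  main <- which(cl == as.integer(names(which.max(table(cl)))))
  patch <- pts[main, , drop = FALSE]
  centroid <- colMeans(patch)
  b <- receptor$beads
  charged <- b[b$charge != 0, ]
  if (nrow(charged)) {
    cxyz <- as.matrix(charged[, c("x", "y", "z")])
    d2 <- outer(rowSums(cxyz^2), rowSums(patch^2), "+") -
      2 * cxyz %*% t(patch)
    near <- apply(d2, 1L, min) <= residue_cutoff^2
    res <- unique(charged[near, c("res_id", "chain", "resname")])
  } else {
    res <- data.frame(res_id = integer(), chain = character(),
                      resname = character())
  }
  rownames(res) <- NULL
  list(residues = res, centroid = unname(centroid), n_probes = nrow(patch))
}

#' Detect the largest buried cavity of a receptor
#'
#' Grid-based cavity detection: solvent-accessible grid points (outside
#' bead radius + probe) are classified as buried when rays in at least
#' `min_blocked` of 14 scan directions (the 6 axes and 8 cube diagonals)
#' hit a receptor bead, where a bead blocks a ray passing within its radius
#' plus the probe radius. Buried points are connected-component labelled
#' (6-connectivity) and the largest component is returned with volume
#' `n_points * spacing^3` and its centroid.
#'
#' @param receptor A [receptor_model()].
#' @param spacing Grid spacing, A (default 1).
#' @param probe Solvent probe radius, A (default 1.4).
#' @param min_blocked Burial criterion: minimum blocked directions out of
#'   14 (default 9).
#' @param padding Grid padding, A (default 2).
#' @return A list of class `cavity`: `found` (logical), and when found
#'   `center` (length-3), `volume` (A^3), `n_points` and `points`
#'   (n x 3 matrix).
#' @export
find_cavity <- function(receptor, spacing = 1, probe = 1.4,
                        min_blocked = 9L, padding = 2) {
  stopifnot(inherits(receptor, "receptor_model"))
  b <- receptor$beads
  xyz <- .receptor_coords(receptor)
  g <- .probe_grid(receptor, spacing, padding)
  keep <- .min_clearance(g$points, xyz, b$radius + probe) > 0
  pts <- g$points[keep, , drop = FALSE]
  idx <- g$idx[keep, , drop = FALSE]
  if (!nrow(pts)) return(structure(list(found = FALSE), class = "cavity"))
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) /
                  sqrt(3))
  block_r2 <- (b$radius + probe)^2
  blocked <- matrix(FALSE, nrow(pts), nrow(dirs))
  p2 <- rowSums(pts^2)
  b2 <- rowSums(xyz^2)
  cross <- pts %*% t(xyz)            # N x M
  d2all <- outer(p2, b2, "+") - 2 * cross
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    t_along <- outer(as.numeric(pts %*% d), as.numeric(xyz %*% d),
                     function(pd, bd) bd - pd)   # N x M
    perp2 <- d2all - t_along^2
    hit <- (t_along >= 0) & (perp2 <= matrix(block_r2, nrow(pts),
                                             nrow(xyz), byrow = TRUE))
    blocked[, k] <- rowSums(hit) > 0
  }
  buried <- rowSums(blocked) >= min_blocked
  if (!any(buried)) return(structure(list(found = FALSE), class = "cavity"))
  bpts <- pts[buried, , drop = FALSE]
  bidx <- idx[buried, , drop = FALSE]
  # connected components, 6-connectivity on the integer grid
  nx <- g$dims[1]; ny <- g$dims[2]
  key <- bidx[, 1] + nx * (bidx[, 2] - 1L) + nx * ny * (bidx[, 3] - 1L)
  comp <- integer(length(key))
  lookup <- seq_along(key)
  names(lookup) <- as.character(key)
  offs <- c(1L, -1L, nx, -nx, nx * ny, -nx * ny)
  cid <- 0L
  for (s in seq_along(key)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      nb <- lookup[as.character(key[cur] + offs)]
      nb <- nb[!is.na(nb)]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  main <- which(comp == as.integer(names(which.max(table(comp)))))
  cav <- bpts[main, , drop = FALSE]
  structure(list(found = TRUE, center = unname(colMeans(cav)),
                 volume = nrow(cav) * spacing^3, n_points = nrow(cav),
                 points = cav),
            class = "cavity")
}

#' @export
print.cavity <- function(x, ...) {
  if (!x$found) {
    cat("No buried cavity detected\n")
  } else {
    cat(sprintf("Cavity: volume %.0f A^3 (%d grid points), centre (%.2f, %.2f, %.2f)\n",
                x$volume, x$n_points, x$center[1], x$center[2], x$center[3]))
  }
  invisible(x)
}

#' Write a potential map as CSV (x, y, z, value)
#'
#' @param map A `potential_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
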