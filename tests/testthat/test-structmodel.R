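test_that("read_pdb parses fixtures and preserves structure", {
  p <- write_fixture_pdb(c(
    pdb_atom_line(1, "N", "GLU", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "GLU", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CD", "GLU", "A", 1, 2.5, 1.2, 0),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 5.3, 0, 0),
    "END"))
  s <- read_pdb(p)
  expect_length(s$models, 1L)
  at <- s$models[[1L]]
  expect_equal(nrow(at), 4L)
  expect_equal(unique(at$resseq), c(1L, 2L))
  expect_equal(at$x[2L], 1.5)
  expect_equal(at$element[1L], "N")
})

test_that("multi-model files yield ordered models with equal topology", {
  mk <- function(x) c("MODEL     1",
                      pdb_atom_line(1, "CA", "ALA", "A", 1, x, 0, 0),
                      pdb_atom_line(2, "CA", "ALA", "A", 2, x + 3.8, 0, 0),
                      "ENDMDL")
  lines <- c(mk(0), sub("MODEL     1", "MODEL     2", mk(1)),
             sub("MODEL     1", "MODEL     3", mk(2)), "END")
  s <- read_pdb(write_fixture_pdb(lines))
  expect_length(s$models, 3L)
  for (m in s$models) expect_equal(nrow(m), 2L)
  expect_equal(vapply(s$models, function(m) m$x[1L], numeric(1)), 0:2)
})

test_that("malformed coordinate fields raise an error naming the line", {
  bad <- write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    substr(pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0), 1, 40),
    "END"))
  expect_error(read_pdb(bad), "line 2")
  expect_error(read_pdb(tempfile()), "no such file")
})

test_that("PDB writing round-trips structures", {
  s <- read_pdb(write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "LYS", "B", 10, 1.234, -5.678, 9.1),
    pdb_atom_line(2, "CB", "LYS", "B", 10, 2.0, -6.0, 9.5), "END")))
  out <- tempfile(fileext = ".pdb")
  write_pdb(s, out)
  back <- read_pdb(out)
  expect_equal(back$models[[1L]]$x, s$models[[1L]]$x, tolerance = 1e-3)
  expect_equal(back$models[[1L]]$resseq, s$models[[1L]]$resseq)
  expect_equal(back$models[[1L]]$chain, s$models[[1L]]$chain)
})

test_that("coarse_grain applies the residue charge and placement rules", {
  p <- write_fixture_pdb(c(
    # glutamate with a sidechain; glycine without; lysine
    pdb_atom_line(1, "N", "GLU", "A", 1, -1.2, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "GLU", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "CB", "GLU", "A", 1, 1, 1, 0),
    pdb_atom_line(4, "CD", "GLU", "A", 1, 2, 2, 0),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(6, "CA", "LYS", "A", 3, 7.6, 0, 0),
    pdb_atom_line(7, "NZ", "LYS", "A", 3, 9.0, 2, 0, element = "N"),
    "END"))
  rec <- coarse_grain(read_pdb(p))
  b <- rec$beads
  expect_equal(nrow(b), 6L)  # 2 beads per residue
  glu_sc <- b[b$resname == "GLU" & b$role == "sidechain", ]
  expect_equal(glu_sc$charge, -1)
  expect_equal(c(glu_sc$x, glu_sc$y), c(1.5, 1.5))  # sidechain centroid
  gly_sc <- b[b$resname == "GLY" & b$role == "sidechain", ]
  gly_ca <- b[b$resname == "GLY" & b$role == "backbone", ]
  expect_equal(c(gly_sc$x, gly_sc$y, gly_sc$z),
               c(gly_ca$x, gly_ca$y, gly_ca$z))  # co-located with Calpha
  lys_sc <- b[b$resname == "LYS" & b$role == "sidechain", ]
  expect_equal(lys_sc$charge, 1)
  # net formal charge preserved
  expect_equal(sum(b$charge), 0)
  expect_true(all(b$radius > 0))
})

test_that("residues without a Calpha are skipped with a warning", {
  p <- write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ASP", "A", 2, 3.8, 0, 0),  # no CA
    "END"))
  expect_warning(rec <- coarse_grain(read_pdb(p)), "skipped")
  expect_equal(length(unique(rec$beads$res_id)), 1L)
})

test_that("surface potential has the declared sign/linearity structure", {
  one <- function(q) receptor_model(data.frame(
    res_id = 1L, resname = if (q > 0) "LYS" else "GLU", chain = "A",
    role = "sidechain", x = 0, y = 0, z = 0, charge = q, radius = 1.7))
  vp <- surface_potential(one(1), spacing = 2, padding = 6)
  expect_true(all(vp$potential > 0))
  vm <- surface_potential(one(-1), spacing = 2, padding = 6)
  # antisymmetric under charge swap
  expect_equal(vm$potential, -vp$potential)
  # explicit closed-form spot check: V = 83 q / r^2 at an arbitrary probe
  i <- 10L
  r2 <- vp$x[i]^2 + vp$y[i]^2 + vp$z[i]^2
  expect_equal(vp$potential[i], 83 / r2, tolerance = 1e-10)
  expect_error(surface_potential(receptor_model(data.frame(
    res_id = 1L, resname = "ALA", chain = "A", role = "backbone",
    x = 0, y = 0, z = 0, charge = 0, radius = 1.7))), "charged")
})

test_that("potential is rigid-motion equivariant", {
  pm <- surface_potential(toy_rec, spacing = 2, padding = 3)
  # rotate receptor and probes together: identical potentials
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rec2 <- toy_rec
  xyz <- as.matrix(rec2$beads[, c("x", "y", "z")]) %*% t(R)
  rec2$beads$x <- xyz[, 1L]; rec2$beads$y <- xyz[, 2L]
  rec2$beads$z <- xyz[, 3L]
  probes <- as.matrix(pm[, c("x", "y", "z")]) %*% t(R)
  v2 <- npmhub:::.cg_potential(probes,
                               as.matrix(rec2$beads[, c("x", "y", "z")]),
                               rec2$beads$charge, 40)
  expect_equal(v2, pm$potential, tolerance = 1e-9)
})

test_that("acidic_patch reports the pore lining on the toy receptor", {
  pm <- surface_potential(toy_rec)
  patch <- acidic_patch(pm, toy_rec)
  # all 15 acidic ring residues, nothing else
  expect_equal(nrow(patch$residues), 15L)
  expect_true(all(patch$residues$resname == "GLU"))
  expect_lt(sqrt(sum(patch$centroid[1:2]^2)), 2)  # centred on the pore axis
  # all-neutral receptor: empty result
  neutral <- receptor_model(toy_rec$beads[toy_rec$beads$charge == 0, ])
  fake_map <- structure(data.frame(x = 0, y = 0, z = 0, potential = 1),
                        class = c("potential_map", "data.frame"))
  expect_equal(nrow(acidic_patch(fake_map, neutral)$residues), 0L)
})

test_that("find_cavity locates the pore and behaves monotonically", {
  cav <- find_cavity(toy_rec)
  expect_true(cav$found)
  ring_centroid <- colMeans(toy_acid_xyz())
  expect_lt(sqrt(sum((cav$center - ring_centroid)^2)), 2)
  # a solid slab of beads has no buried cavity
  g <- expand.grid(x = seq(-3, 3, 3), y = seq(-3, 3, 3), z = seq(-3, 3, 3))
  slab <- receptor_model(data.frame(
    res_id = seq_len(nrow(g)), resname = "ALA", chain = "A",
    role = "backbone", g, charge = 0, radius = 1.7))
  expect_false(find_cavity(slab)$found)
  # widening the pore grows the cavity
  big <- make_toy_receptor(toy_receptor_spec(ring_radius = 5.4,
                                             neutral_radius = 11))
  expect_gt(find_cavity(big)$volume, cav$volume)
})

test_that("cavity detection is invariant under rigid motion", {
  cav <- find_cavity(toy_rec)
  th <- 0.61
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  shift <- c(3.2, -1.1, 0.7)
  rec2 <- toy_rec
  xyz <- sweep(as.matrix(rec2$beads[, c("x", "y", "z")]) %*% t(R), 2L,
               shift, "+")
  rec2$beads$x <- xyz[, 1L]; rec2$beads$y <- xyz[, 2L]
  rec2$beads$z <- xyz[, 3L]
  cav2 <- find_cavity(rec2)
  expect_true(cav2$found)
  # grid re-sampling allows small differences only
  expect_equal(cav2$volume, cav$volume, tolerance = 0.2)
  back <- as.numeric((cav2$center - shift) %*% R)
  expect_lt(sqrt(sum((back - cav$center)^2)), 1.5)
})

test_that("receptor PDB export stores charges in the B-factor column", {
  path <- tempfile(fileext = ".pdb")
  write_receptor_pdb(toy_rec, path)
  back <- read_receptor_pdb(path)
  expect_equal(sum(back$beads$charge), -15)
  expect_equal(nrow(back$beads), nrow(toy_rec$beads))
  expect_equal(back$beads$x, toy_rec$beads$x, tolerance = 1e-3)
})
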