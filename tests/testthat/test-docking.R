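test_that("enumerate_fragments yields all contiguous k-mers", {
  fr <- enumerate_fragments("PFCRRRMKRKLDH", 3)
  expect_equal(nrow(fr), 11L)
  expect_equal(fr$sequence[1L], "PFC")
  expect_equal(fr$start[1L], 1L)
  expect_equal(fr$sequence[11L], "LDH")
  expect_equal(nrow(enumerate_fragments("RRR", 3)), 1L)
  expect_equal(nrow(enumerate_fragments("PFCRRRMKRKLDH", 6)), 8L)
  expect_error(enumerate_fragments("AC", 3), "shorter")
})

test_that("peptide models have fixed virtual bonds and residue charges", {
  pep <- peptide_model("PFCRRRMKRKLDH", first_residue = 44)
  ca <- pep$coords[pep$ca_idx, ]
  bonds <- sqrt(rowSums(diff(ca)^2))
  expect_equal(bonds, rep(3.8, 12), tolerance = 1e-9)
  expect_equal(sum(pep$charge), 5)  # six basic (4R + 2K) minus one D
  expect_equal(pep$numbering, 44:56)
  expect_equal(pep$n_torsions, 10L)
  # torsion moves preserve the bond geometry
  co2 <- npmhub:::.apply_torsion(pep$coords, pep, 5L, 0.7)
  ca2 <- co2[pep$ca_idx, ]
  expect_equal(sqrt(rowSums(diff(ca2)^2)), rep(3.8, 12), tolerance = 1e-9)
  expect_equal(co2[1:6, ], pep$coords[1:6, ])  # head untouched
  # glycine sidechain bead rides on the Calpha
  g <- peptide_model("AGA")
  expect_equal(g$coords[g$sc_idx[2L], ], g$coords[g$ca_idx[2L], ])
})

test_that("score_pose matches closed forms", {
  one_bead_rec <- receptor_model(data.frame(
    res_id = 1L, resname = "GLU", chain = "A", role = "sidechain",
    x = 0, y = 0, z = 0, charge = -1, radius = 1.7))
  m <- peptide_model("R")
  cfg <- docking_config(center = c(0, 0, 0), eps_rep = 0)
  # +1/-1 pair at 5 A: 332/(4*5*5) = 3.32 kcal/mol, attractive;
  # the neutral Calpha bead is parked far away to isolate one pair
  co2 <- matrix(c(100, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  s2 <- score_pose(one_bead_rec, co2, cfg, model = m)
  expect_equal(s2$elec, -3.32)
  # beyond the 40 A cutoff the term vanishes
  co3 <- matrix(c(100, 0, 0, 45, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(score_pose(one_bead_rec, co3, cfg, model = m)$elec, 0)
  # bilinearity: swapping all charge signs preserves the product q_i q_j
  pos_rec <- one_bead_rec
  pos_rec$beads$charge <- 1
  m_neg <- m
  m_neg$charge <- -m$charge
  s3 <- score_pose(pos_rec, co2, cfg, model = m_neg)
  expect_equal(s3$elec, s2$elec)
  # coincident beads are capped and flagged
  co4 <- matrix(c(100, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  s4 <- score_pose(one_bead_rec, co4, docking_config(center = c(0, 0, 0)),
                   model = m)
  expect_equal(s4$capped, 1L)
  expect_true(is.finite(s4$total))
})

test_that("energy is invariant under joint rigid motion", {
  cfg <- docking_config(center = c(0, 0, 0))
  m <- peptide_model("RKD")
  co <- sweep(m$coords, 2L, c(0, 0, 8), "+")
  e0 <- score_pose(toy_rec, co, cfg, model = m)$total
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  shift <- c(5, -3, 2)
  rec2 <- toy_rec
  xyz <- sweep(as.matrix(rec2$beads[, c("x", "y", "z")]) %*% t(R), 2L,
               shift, "+")
  rec2$beads$x <- xyz[, 1L]; rec2$beads$y <- xyz[, 2L]
  rec2$beads$z <- xyz[, 3L]
  co2 <- sweep(co %*% t(R), 2L, shift, "+")
  e1 <- score_pose(rec2, co2, cfg, model = m)$total
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("dock_fragment funnels basic tripeptides into the acidic pore", {
  cfg <- docking_config(center = c(0, 0, 0), seed = 7)
  ps <- dock_fragment(toy_rec, peptide_model("RRR"), cfg)
  expect_length(ps, 10L)
  en <- vapply(ps, function(p) p$energy$total, numeric(1))
  expect_true(!is.unsorted(en))
  # the best-scoring pose of the 10-run search places >= 2 basic beads in
  # salt-bridge range of the planted acidic lining, in >= 9/10 seeds
  hits <- vapply(1:10, function(sd) {
    top <- dock_fragment(toy_rec, peptide_model("RRR"),
                         docking_config(center = c(0, 0, 0),
                                        seed = sd))[[1L]]
    n_basic_contacts(top) >= 2L
  }, logical(1))
  expect_gte(sum(hits), 9L)
  # all poses respect the search sphere
  for (p in ps) {
    d <- sqrt(rowSums(sweep(p$coords, 2L, cfg$center)^2))
    expect_true(any(d <= cfg$radius))
  }
})

test_that("neutral fragments find essentially no binding energy", {
  cfg <- docking_config(center = c(0, 0, 0), seed = 5)
  ps <- dock_fragment(toy_rec, peptide_model("AAA"), cfg)
  expect_lt(abs(ps[[1L]]$energy$total), 1)
})

test_that("docking is bit-identical under a fixed seed", {
  cfg <- docking_config(center = c(0, 0, 0), seed = 123)
  a <- dock_fragment(toy_rec, peptide_model("RRR"), cfg)
  b <- dock_fragment(toy_rec, peptide_model("RRR"), cfg)
  expect_identical(a, b)
  expect_error(dock_fragment(toy_rec, peptide_model("RRR"),
                             docking_config(runs = 0)))
})

test_that("cluster_poses groups by RMSD with energy-ordered greediness", {
  m <- peptide_model("RRR")
  mk <- function(shift, e) {
    npmhub:::.new_pose(sweep(m$coords, 2L, shift, "+"), m,
                       list(elec = e, steric = 0, bias = 0, total = e),
                       list(stage = "test", run = abs(e)))
  }
  # identical poses collapse to one representative
  same <- lapply(1:5, function(i) mk(c(0, 0, 0), -i))
  cl <- cluster_poses(same, 1.2)
  expect_length(cl$representatives, 1L)
  expect_equal(cl$representatives[[1L]]$provenance$cluster_size, 5L)
  expect_equal(cl$representatives[[1L]]$energy$total, -5)
  # two poses 10 A apart stay separate
  two <- list(mk(c(0, 0, 0), -1), mk(c(10, 0, 0), -2))
  expect_length(cluster_poses(two, 1.2)$representatives, 2L)
  expect_equal(cluster_poses(list(), 1.2)$assignment, integer())
  # random pose sets: every pose within cutoff of its representative,
  # representatives pairwise farther than the cutoff (brute-force check)
  set.seed(99)
  for (rep in 1:5) {
    poses <- lapply(1:25, function(i) {
      mk(c(runif(1, 0, 6), runif(1, 0, 6), 0), -runif(1))
    })
    cl <- cluster_poses(poses, 1.2)
    reps <- cl$representatives
    for (i in seq_along(poses)) {
      rmsd_i <- npmhub:::.pose_rmsd(poses[[i]]$coords,
                                    reps[[cl$assignment[i]]]$coords)
      expect_lt(rmsd_i, 1.2)
    }
    if (length(reps) > 1L) {
      pr <- utils::combn(length(reps), 2L)
      for (k in seq_len(ncol(pr))) {
        expect_gte(npmhub:::.pose_rmsd(reps[[pr[1, k]]]$coords,
                                       reps[[pr[2, k]]]$coords), 1.2)
      }
    }
  }
})

test_that("template bias pins mapped beads in the stiff-spring limit", {
  m <- peptide_model("RRR")
  target <- sweep(m$coords, 2L, c(0, 0, 30), "+")  # far from the receptor
  tpl <- list(bead_idx = seq_len(nrow(m$coords)), coords = target)
  cfg <- docking_config(center = c(0, 0, 30), radius = 20, bias_k = 1000,
                        seed = 2, anneal_steps = 2000, quench_steps = 500)
  ps <- template_dock(toy_rec, m, list(tpl), cfg)
  dev <- sqrt(rowSums((ps[[1L]]$coords - target)^2))
  expect_lt(max(dev), 0.5)
  # reported energy excludes the bias
  e <- score_pose(toy_rec, ps[[1L]]$coords, cfg, model = m)
  expect_equal(ps[[1L]]$energy$total, e$elec + e$steric)
  expect_error(template_dock(toy_rec, m,
                             list(list(bead_idx = 99L,
                                       coords = matrix(0, 1, 3))), cfg),
               "mismatch")
})

test_that("zero bias degenerates template docking to free docking", {
  m <- peptide_model("RRR")
  cfg <- docking_config(center = c(0, 0, 0), seed = 31, bias_k = 0)
  free <- dock_fragment(toy_rec, m, cfg)
  tpl <- list(bead_idx = seq_len(nrow(m$coords)), coords = m$coords)
  biased <- template_dock(toy_rec, m, list(tpl), cfg,
                          runs_per_template = cfg$runs)
  expect_equal(lapply(free, `[[`, "coords"),
               lapply(biased, `[[`, "coords"))
})

test_that("minimize_pose descends to the declared gradient thresholds", {
  # constructed quadratic basin: pure harmonic template far from receptor
  m <- peptide_model("AAA")
  target <- sweep(m$coords, 2L, c(0, 0, 50), "+")
  tpl <- list(bead_idx = seq_len(nrow(m$coords)), coords = target)
  cfg <- docking_config(center = c(0, 0, 50), bias_k = 5)
  # pose already at the minimum stays put
  p0 <- npmhub:::.new_pose(target, m,
                           list(elec = 0, steric = 0, bias = 0, total = 0),
                           list(stage = "test"))
  m0 <- minimize_pose(toy_rec, p0, cfg, template = tpl)
  expect_lt(max(abs(m0$coords - target)), 1e-6)
  # pose displaced 0.5 A returns within 0.05 A of the basin minimum
  p1 <- npmhub:::.new_pose(sweep(target, 2L, c(0.3, -0.3, 0.2), "+"), m,
                           list(elec = 0, steric = 0, bias = 0, total = 0),
                           list(stage = "test"))
  m1 <- minimize_pose(toy_rec, p1, cfg, template = tpl)
  expect_true(m1$provenance$converged)
  expect_lt(max(sqrt(rowSums((m1$coords - target)^2))), 0.05)
  # energy trace is monotone non-increasing over accepted steps
  expect_true(all(diff(m1$provenance$energy_trace) <= 1e-9))
})

test_that("minimization relaxes docked poses without raising the energy", {
  cfg <- docking_config(center = c(0, 0, 0), seed = 8)
  ps <- dock_fragment(toy_rec, peptide_model("RKR"), cfg)
  mp <- minimize_pose(toy_rec, ps[[1L]], cfg)
  expect_lte(mp$energy$total, ps[[1L]]$energy$total + 1e-9)
  expect_true(all(diff(mp$provenance$energy_trace) <= 1e-9))
  expect_false(mp$provenance$aborted)
})

test_that("salt_bridges reports acidic/basic sidechain pairs by distance", {
  rec <- receptor_model(data.frame(
    res_id = c(36L, 37L), resname = c("ASP", "GLU"), chain = "A",
    role = "sidechain", x = c(0, 10), y = 0, z = 0, charge = -1,
    radius = 1.7))
  m <- peptide_model("RR", first_residue = 47)
  # place sidechain beads by hand: R47 at 3.5 A from D36, R48 at 4.5 A
  co <- m$coords
  co[m$sc_idx[1L], ] <- c(3.5, 0, 0)
  co[m$sc_idx[2L], ] <- c(4.5, 0, 0)
  co[m$ca_idx, ] <- matrix(c(3.5, 5, 0, 4.5, 5, 0), 2, 3, byrow = TRUE)
  pose <- npmhub:::.new_pose(co, m, list(total = 0), list(stage = "t"))
  sb <- salt_bridges(rec, pose, cutoff = 4)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$receptor_residue, "D36")
  expect_equal(sb$peptide_residue, "R47")
  expect_equal(sb$distance, 3.5)
  # one acidic bead within 4 A of two basic beads yields two pairs
  co[m$sc_idx[2L], ] <- c(-3.5, 0, 0)
  pose2 <- npmhub:::.new_pose(co, m, list(total = 0), list(stage = "t"))
  sb2 <- salt_bridges(rec, pose2, cutoff = 4)
  expect_equal(nrow(sb2), 2L)
  expect_true(all(sb2$receptor_residue == "D36"))
  expect_setequal(sb2$peptide_residue, c("R47", "R48"))
})
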