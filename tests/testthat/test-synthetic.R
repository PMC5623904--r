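test_that("binding presets cover all measured complexes with valid params", {
  pr <- binding_presets()
  # 3 wild-type + 2 controls + 12 mutants vs Fbw7g* + 8 mutant rows vs
  # CENP-W*/Tat*
  expect_length(pr, 25L)
  expect_equal(sum(vapply(pr, function(p) p$table == 1L, logical(1))), 5L)
  expect_equal(sum(vapply(pr, function(p) p$table == 2L, logical(1))), 12L)
  expect_equal(sum(vapply(pr, function(p) p$table == 3L, logical(1))), 8L)
  binders <- pr[!vapply(pr, function(p) is.null(p$params), logical(1))]
  for (p in binders) {
    expect_s3_class(p$params, "binding_params")
    expect_gt(p$params$kd, 0)
    expect_gt(p$kd_sd, 0)
    # documented optical defaults
    expect_equal(p$params$n, 5)
    expect_equal(p$params$b, 1)
    expect_equal(p$params$c, 0)
    expect_equal(p$params$k, 0.001)
  }
  # non-binders carry sequences but no parameters
  expect_null(pr$unrelated_long$params)
  expect_equal(pr$unrelated_long$sequence, "DDEAQTLAKFVLSQK")
  # parent numbering of the NoLS peptides
  expect_equal(pr$wt_fbw7g$first_residue, 43L)
  expect_equal(pr$wt_tat$first_residue, 47L)
})

test_that("noise-free titrations lie exactly on the quadratic model", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  a <- seq(0, 200, length.out = 25)
  cur <- make_titration(wt, titration_design(a, replicates = 2L,
                                             noise_cv = 0))
  expect_equal(cur$fluorescence, rep(quadratic_model(a, wt), 2L),
               tolerance = 1e-12)
  expect_equal(cur$fluorescence[1L], wt$c)  # zero-protein intercept
  # bit-identical across calls
  cur2 <- make_titration(wt, titration_design(a, replicates = 2L,
                                              noise_cv = 0))
  expect_identical(cur, cur2)
})

test_that("titration noise behaves as a 2% multiplicative CV", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  a <- seq(8, 200, length.out = 25)  # skip a = 0 where F = 0
  cur <- make_titration(wt, titration_design(a, replicates = 3L,
                                             noise_cv = 0.02, seed = 1))
  m <- matrix(cur$fluorescence, nrow = length(a))
  cv <- apply(m, 1L, sd) / rowMeans(m)
  expect_true(all(cv >= 0.0005 & cv <= 0.08))
  # Monte-Carlo: pooled CV over many replicates approaches 0.02
  cur2 <- make_titration(wt, titration_design(a, replicates = 200L,
                                              noise_cv = 0.02, seed = 2))
  m2 <- matrix(cur2$fluorescence, nrow = length(a))
  cv2 <- apply(m2, 1L, sd) / rowMeans(m2)
  expect_true(all(cv2 >= 0.005 & cv2 <= 0.05))
  # seeded generation is reproducible and restores the RNG state
  before <- runif(1)
  cur3 <- make_titration(wt, titration_design(a, replicates = 3L,
                                              noise_cv = 0.02, seed = 1))
  expect_identical(cur, cur3)
  expect_error(titration_design(c(5, 0, 10)), "increasing")
  expect_error(titration_design(c(-1, 5)), "non-negative")
})

test_that("titration CSV round-trips", {
  wt <- binding_presets()[["wt_fbw7g"]]$params
  cur <- make_titration(wt, titration_design(seq(0, 100, 10),
                                             replicates = 2L,
                                             noise_cv = 0.02, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_titration(cur, path)
  back <- read_titration(path)
  expect_equal(attr(back, "n_fixed"), 5)
  expect_equal(back$fluorescence, cur$fluorescence, tolerance = 1e-12)
  expect_equal(back$replicate, cur$replicate)
})

test_that("toy receptor has the specified charge, symmetry and count", {
  spec <- toy_receptor_spec()
  rec <- make_toy_receptor(spec)
  expect_equal(sum(rec$beads$charge),
               -spec$n_fold * spec$acidic_per_monomer)  # -15
  expect_equal(nrow(rec$beads),
               spec$n_fold * (spec$acidic_per_monomer + spec$neutral_count))
  # exact n-fold rotational symmetry about z
  xyz <- as.matrix(rec$beads[, c("x", "y", "z")])
  th <- 2 * pi / spec$n_fold
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- xyz %*% t(R)
  mismatch <- max(apply(rot, 1L, function(p) {
    min(sqrt(colSums((t(xyz) - p)^2)))
  }))
  expect_lt(mismatch, 1e-9)
  expect_equal(rec$metadata$planted_optimum, c(0, 0, 0))
  # overlap rejection: a wall drawn through the acidic rings collides
  expect_error(make_toy_receptor(toy_receptor_spec(neutral_radius = 4)),
               "overlap")
})

test_that("pore-axis potential is the grid minimum on the toy receptor", {
  # brute-force evaluation of the module's own screened-Coulomb score on
  # the accessible probe grid
  pm <- surface_potential(toy_rec, spacing = 1, padding = 4)
  i <- which.min(pm$potential)
  expect_lt(sqrt(pm$x[i]^2 + pm$y[i]^2), 2)
})

test_that("toy trajectories honour anchors, seeds and zero-noise limits", {
  pep <- peptide_model("PFCRRRMKRKLDH", first_residue = 44)
  start <- pep$coords[pep$ca_idx, ]
  # zero noise: all frames identical to the start
  tr0 <- make_toy_trajectory(start, trajectory_spec(
    n_frames = 10, sigma_anchor = 0, sigma_free = 0, seed = 1))
  for (f in tr0$frames) expect_equal(f, start)
  # frame 0 exact; seeded reproducibility
  sp <- trajectory_spec(n_frames = 50, anchor_residues = 1:6,
                        sigma_anchor = 0.5, sigma_free = 3, seed = 9)
  tr1 <- make_toy_trajectory(start, sp)
  tr2 <- make_toy_trajectory(start, sp)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$frames[[1L]], start)
  expect_error(make_toy_trajectory(start[1:4, ], sp), "anchor_residues")
  expect_error(trajectory_spec(sigma_anchor = 2, sigma_free = 1))
})

test_that("free residues move more than anchored ones in >99% of seeds", {
  pep <- peptide_model("PFCRRRMKRKLDH", first_residue = 44)
  start <- pep$coords[pep$ca_idx, ]
  wins <- vapply(1:100, function(s) {
    tr <- make_toy_trajectory(start, trajectory_spec(
      n_frames = 120, anchor_residues = 1:6, sigma_anchor = 0.5,
      sigma_free = 3, seed = s))
    prof <- per_residue_rmsd(tr, fit = NULL, selection = "all")
    mean(prof$rmsd_A[7:13]) > mean(prof$rmsd_A[1:6])
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("free-residue variance scales with sigma_free^2", {
  pep <- peptide_model("PFCRRRMKRKLDH")
  start <- pep$coords[pep$ca_idx, ]
  plateau <- function(sigma) {
    mean(vapply(1:30, function(s) {
      tr <- make_toy_trajectory(start, trajectory_spec(
        n_frames = 300, anchor_residues = integer(), sigma_anchor = 0,
        sigma_free = sigma, relaxation = 0.3, seed = s))
      prof <- per_residue_rmsd(tr, fit = NULL, selection = "all",
                               burn_in = 30)
      mean(prof$rmsd_A)
    }, numeric(1)))
  }
  p1 <- plateau(1.5)
  p2 <- plateau(3)
  expect_equal(p2 / p1, 2, tolerance = 0.15)
})
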