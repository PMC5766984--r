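test_that("PDB structures and multi-model trajectories round trip", {
  g <- gen_trajectory(4, 0.3, n_frames = 3, seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(g$trajectory, f)
  rt <- read_trajectory(f)
  expect_identical(nrow(rt$frames), 3L)
  expect_identical(ncol(rt$frames), ncol(g$trajectory$frames))
  # PDB precision is 1e-3 A
  expect_lt(max(abs(rt$frames - g$trajectory$frames)), 1e-3 + 1e-9)
  s <- structure_model(g$trajectory$topology$atoms, g$trajectory$frames[2, ])
  f2 <- tempfile(fileext = ".pdb")
  write_pdb_file(s, f2)
  s2 <- read_structure(f2)
  expect_lt(max(abs(s2$xyz - s$xyz)), 1e-3 + 1e-9)
  expect_identical(s2$atoms$resno, s$atoms$resno)
})

test_that("container constructors validate congruence", {
  s <- toy_chain_structure(3)
  expect_error(md_trajectory(s, matrix(0, 2, 6)), "atom count")
  expect_error(md_trajectory(s, matrix(0, 2, 9), frame_spacing_ns = 0),
               "positive")
  expect_error(structure_model(s$atoms, c(1, 2)), "3 \\* number of atoms")
})

test_that("superposition is exact on rigid copies and idempotent", {
  set.seed(8)
  n <- 12
  atoms <- do.call(rbind, lapply(1:n, function(i)
    data.frame(eleno = i, elety = "CA", resid = "ALA", chain = "A",
               resno = i, b = 0)))
  xyz <- as.numeric(t(cbind(3 * (1:n), stats::runif(n), stats::runif(n))))
  moved <- rigid_move(xyz)
  traj <- md_trajectory(structure_model(atoms, xyz), rbind(xyz, moved))
  sup <- superpose_trajectory(traj, 1, selection = "calpha")
  expect_equal(sup$frames[1, ], xyz, tolerance = 1e-9)   # self RMSD 0
  expect_lt(max(abs(sup$frames[2, ] - xyz)), 1e-8)       # rigid copy
  sup2 <- superpose_trajectory(sup, 1, selection = "calpha")
  expect_lt(max(abs(sup2$frames - sup$frames)), 1e-9)
  expect_error(superpose_trajectory(
    md_trajectory(toy_chain_structure(2), matrix(0, 2, 6)), 1, "calpha"),
    "at least 3")
})

test_that("RMSF matches the isotropic closed form and is zero when static", {
  g0 <- gen_trajectory(5, 0, n_frames = 10, seed = 1)
  expect_equal(rmsf_profile(g0$trajectory, "calpha")$rmsf, rep(0, 5))
  g <- gen_trajectory(10, 0.5, n_frames = 5000, seed = 11)
  prof <- rmsf_profile(g$trajectory, "calpha")
  expect_equal(prof$rmsf, rep(0.5 * sqrt(3), 10), tolerance = 0.03)
  # per-residue sigma profile recovered rank-identically
  sig <- seq(0.2, 1.2, length.out = 8)
  g2 <- gen_trajectory(8, sig, n_frames = 2000, seed = 12)
  p2 <- rmsf_profile(g2$trajectory, "calpha")
  expect_identical(order(p2$rmsf), order(sig))
  # RMSF invariant under a global rigid motion of every frame
  tr <- g2$trajectory
  moved <- t(apply(tr$frames, 1, rigid_move))
  p3 <- rmsf_profile(md_trajectory(tr$topology, moved), "calpha")
  expect_equal(p3$rmsf, p2$rmsf, tolerance = 1e-9)
})

test_that("block averaging reports mean and spread across contiguous blocks", {
  g <- gen_trajectory(6, 0.5, n_frames = 200, frame_spacing_ns = 0.05,
                      seed = 3)
  prof <- rmsf_profile(g$trajectory, "calpha", block_ns = 2.5)
  expect_named(prof, c("resno", "rmsf", "sd"))
  expect_true(all(prof$sd >= 0))
  expect_equal(prof$rmsf, rep(0.5 * sqrt(3), 6), tolerance = 0.1)
  expect_error(rmsf_profile(g$trajectory, "calpha", block_ns = 100),
               "block longer")
})

test_that("native contacts reproduce the toy-chain oracle and rigid invariance", {
  s <- toy_chain_structure(5, spacing = 3)
  nc <- native_contacts(s, cutoff = 6.5)
  expect_equal(unname(nc$counts), c(2, 3, 4, 3, 2))
  expect_identical(nc$total, 14)
  # brute-force cross-check of the pair list
  brute <- 0
  for (i in 1:5) for (j in 1:5)
    if (i != j && abs(i - j) * 3 <= 6.5) brute <- brute + 1
  expect_identical(nc$total, brute)
  # two residues 10 A apart: no contacts
  far <- toy_chain_structure(2, spacing = 10)
  expect_identical(native_contacts(far)$total, 0)
  # invariance under rigid motion
  nc2 <- native_contacts(structure_model(s$atoms, rigid_move(s$xyz)))
  expect_identical(nc2$total, nc$total)
  expect_equal(unname(nc2$counts), unname(nc$counts))
})

test_that("retained-contact counts equal the reference total on the reference frame", {
  s <- toy_chain_structure(5, spacing = 3)
  nc <- native_contacts(s)
  traj <- md_trajectory(s, rbind(s$xyz, rigid_move(s$xyz)))
  ret <- count_retained(traj, nc)
  expect_equal(ret$total_contacts, c(14, 14))
  # pulling the chain apart loses contacts
  stretched <- as.numeric(t(cbind(10 * (0:4), 0, 0)))
  ret2 <- count_retained(md_trajectory(s, matrix(stretched, 1)), nc)
  expect_identical(ret2$total_contacts, 0)
})

test_that("minimum inter-selection distances match brute force and are symmetric", {
  s <- toy_chain_structure(12, spacing = 3)
  traj <- md_trajectory(s, matrix(s$xyz, nrow = 1))
  A <- residue_selection(1:3); B <- residue_selection(10:12)
  md <- min_distance_series(traj, A, B)
  expect_equal(md$min_dist, 21)  # 9 atom pairs, closest residues 3 and 10
  expect_equal(min_distance_series(traj, B, A)$min_dist, md$min_dist)
  # coincident atoms across selections give zero
  xyz0 <- s$xyz; xyz0[1:3] <- xyz0[28:30]
  md0 <- min_distance_series(md_trajectory(s, matrix(xyz0, 1)), A, B)
  expect_equal(md0$min_dist, 0)
  expect_error(min_distance_series(traj, A, residue_selection(3:5)),
               "overlap")
})

test_that("distance histograms conserve the frame count", {
  g <- gen_trajectory(12, 0.4, n_frames = 100, seed = 21)
  traj <- g$trajectory
  md <- min_distance_series(traj, residue_selection(1:3),
                            residue_selection(9:12))
  h <- dist_histogram(md, bin_width = 0.5)
  expect_identical(sum(h$count), 100L)
  expect_equal(diff(h$bin_left), rep(0.5, nrow(h) - 1))
})

test_that("B-factor profiles extract, remap and validate", {
  s <- toy_chain_structure(3, b = c(10, 20, 30))
  expect_equal(bfactor_profile(s)$b, c(10, 20, 30))
  uni <- toy_chain_structure(4, b = rep(20, 4))
  expect_equal(bfactor_profile(uni)$b, rep(20, 4))
  mp <- stats::setNames(c(1L, 3L), c("1", "3"))  # skips residue 2
  got <- bfactor_profile(s, map = mp)
  expect_equal(got$b, c(10, 30))
  expect_identical(got$ref_position, c(1L, 3L))
  expect_error(bfactor_profile(s, chain = "Z"), "chain")
})
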