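# Trajectory analyses: H-bond occupancy, distance histograms, RMSD,
# interaction-energy decomposition.

test_that("hydrogen-bond criteria gate on distance AND angle", {
  crit <- hbond_criteria(3.0, 135, block_size = 10)
  contacts <- data.frame(donor = "DON", hydrogen = "HYD", acceptor = "ACC")
  # 2.8 A at 165 deg: always bonded
  occ1 <- hbond_occupancy(make_hbond_traj(30, 2.8, 165), contacts, crit)
  expect_equal(occ1$occupancy, rep(1, 3))
  # 2.8 A but only 120 deg at the hydrogen: never bonded
  occ2 <- hbond_occupancy(make_hbond_traj(30, 2.8, 120), contacts, crit)
  expect_equal(occ2$occupancy, rep(0, 3))
  # 3.4 A at 165 deg: distance alone fails
  occ3 <- hbond_occupancy(make_hbond_traj(10, 3.4, 165), contacts, crit)
  expect_equal(occ3$occupancy, 0)
  expect_error(hbond_occupancy(make_hbond_traj(5, 2.8, 165),
                               data.frame(donor = "XXX", hydrogen = "HYD",
                                          acceptor = "ACC"), crit),
               class = "fepkin_input_error")
  expect_error(hbond_criteria(angle_cutoff = 200), "180")
})

test_that("occupancy is exact for quota placement and robust to frame order", {
  traj <- gen_trajectory(trajectory_spec(n_frames = 200, block_size = 50,
                                         occupancy = 0.6, seed = 4))
  contacts <- data.frame(donor = "DON", hydrogen = "HYD", acceptor = "ACC")
  crit <- hbond_criteria(block_size = 50)
  occ <- hbond_occupancy(traj, contacts, crit)
  expect_equal(occ$occupancy, rep(0.6, 4))
  # permuting frames inside one block leaves its occupancy unchanged
  perm <- traj
  set.seed(9)
  shuffle <- sample(1:50)
  perm$frames[, , 1:50] <- perm$frames[, , shuffle]
  expect_equal(hbond_occupancy(perm, contacts, crit)$occupancy,
               occ$occupancy)
  # whole-trajectory occupancy is the frame-count-weighted block mean
  tot <- hbond_occupancy(traj, contacts, hbond_criteria())
  expect_equal(tot$occupancy,
               sum(occ$occupancy * occ$n_frames) / sum(occ$n_frames))
  # a trailing partial block is reported with its own frame count
  occ_part <- hbond_occupancy(gen_trajectory(
    trajectory_spec(n_frames = 130, block_size = 50, occupancy = 1, seed = 1)),
    contacts, crit)
  expect_equal(occ_part$n_frames, c(50L, 50L, 30L))
  # heat-map table is contact x block
  wide <- occupancy_table(occ)
  expect_equal(dim(wide), c(1L, 5L))
})

test_that("distance histograms normalize and find the prescribed modes", {
  traj <- gen_trajectory(trajectory_spec(n_frames = 5000, seed = 11))
  h <- distance_histogram(traj, c("PRB1", "PRB2"), bin_width = 0.1)
  expect_equal(sum(h$density) * h$bin_width, 1)
  expect_length(h$modes, 2)
  expect_lt(abs(h$modes[1] - 2.2), 0.1 + 1e-9)
  expect_lt(abs(h$modes[2] - 4.3), 0.1 + 1e-9)
  # constant distance: one occupied bin, one mode
  traj1 <- make_hbond_traj(20, 2.8, 165)
  h1 <- distance_histogram(traj1, c("DON", "ACC"), bin_width = 0.1)
  expect_equal(sum(h1$counts > 0), 1L)
  expect_length(h1$modes, 1)
  # bin width wider than the data range: degenerate single bin
  h2 <- distance_histogram(traj, c("PRB1", "PRB2"), bin_width = 50)
  expect_length(h2$modes, 1)
})

test_that("RMSD removes rigid-body motion only when asked", {
  base <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.2, 0, 0.3, 0.4, 2), ncol = 3,
                 byrow = TRUE)
  n <- 6
  frames <- array(0, dim = c(4, 3, n))
  for (f in 1:n) frames[, , f] <- base
  top <- data.frame(name = paste0("A", 1:4), resid = 1L, resname = "MOL",
                    group = "P1", charge = 0, sigma = 0, epsilon = 0)
  traj_id <- trajectory_bundle(frames, top)
  expect_equal(rmsd_series(traj_id), rep(0, n))
  # rigid translation by 2 A along y
  frames_t <- frames
  for (f in 2:n) frames_t[, 2, f] <- frames_t[, 2, f] + 2
  traj_t <- trajectory_bundle(frames_t, top)
  expect_equal(rmsd_series(traj_t, superpose = TRUE), rep(0, n),
               tolerance = 1e-12)
  expect_equal(rmsd_series(traj_t, superpose = FALSE), c(0, rep(2, n - 1)))
  # random rigid rotations: superposition recovers zero; bio3d is the oracle
  set.seed(33)
  frames_r <- frames
  for (f in 2:n) {
    th <- stats::runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, byrow = TRUE)
    frames_r[, , f] <- base %*% (Rz %*% Rx) + matrix(th, 4, 3, byrow = TRUE)
  }
  traj_r <- trajectory_bundle(frames_r, top)
  expect_true(all(rmsd_series(traj_r, superpose = TRUE) <= 1e-6))
  ref_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(base)),
                   mobile = t(apply(frames_r, 3, function(m)
                     as.numeric(t(m))))))
  oracle <- sqrt(rowMeans((ref_fit - matrix(as.numeric(t(base)),
                                            n, 12, byrow = TRUE))^2) * 3)
  expect_equal(rmsd_series(traj_r, superpose = TRUE), oracle,
               tolerance = 1e-6)
  # fitting never increases the deviation
  set.seed(44)
  frames_n <- frames + array(stats::rnorm(length(frames), 0, 0.3),
                             dim = dim(frames))
  traj_n <- trajectory_bundle(frames_n, top)
  expect_true(all(rmsd_series(traj_n, superpose = TRUE) <=
                    rmsd_series(traj_n, superpose = FALSE) + 1e-12))
  expect_error(rmsd_series(traj_id, selection = integer(0)), "selection")
})

test_that("interaction decomposition reproduces hand-evaluated pair energies", {
  f_elec <- fepkin_constants$f_elec
  mk_pair <- function(r, q1, q2, sig, eps) {
    frames <- array(0, dim = c(2, 3, 1))
    frames[2, 1, 1] <- r
    trajectory_bundle(frames, data.frame(
      name = c("L1", "R1"), resid = c(1L, 2L), resname = c("INH", "RES"),
      group = c("P1", "protein"), charge = c(q1, q2),
      sigma = sig, epsilon = eps))
  }
  # unit charges at r = f/100: E_elec = 100 kcal/mol exactly
  rec <- interaction_decomposition(mk_pair(3.320636, 1, 1, 0, 0))
  expect_equal(rec$e_elec, 100.0)
  expect_equal(rec$e_lj, 0)
  # LJ minimum: r = 2^(1/6) sigma gives exactly -epsilon
  rec2 <- interaction_decomposition(mk_pair(2^(1 / 6) * 3.4, 0, 0, 3.4, 0.12))
  expect_equal(rec2$e_lj, -0.12)
  expect_equal(rec2$mean, -0.12)
  # all parameters zero: zero energy, zero variance
  rec3 <- interaction_decomposition(mk_pair(3, 0, 0, 0, 0))
  expect_equal(c(rec3$mean, rec3$variance), c(0, 0))
})

test_that("decomposition is pairwise additive over residues and validates input", {
  set.seed(7)
  n_at <- 7
  frames <- array(stats::rnorm(n_at * 3 * 4, sd = 3), dim = c(n_at, 3, 4))
  top <- data.frame(
    name = paste0("A", 1:n_at),
    resid = c(1L, 1L, 10L, 10L, 11L, 12L, 12L),
    resname = c("INH", "INH", "GLY", "GLY", "GLN", "TRP", "TRP"),
    group = c("P1", "P1", rep("protein", 5)),
    charge = round(stats::runif(n_at, -0.5, 0.5), 3),
    sigma = round(stats::runif(n_at, 2.5, 3.8), 3),
    epsilon = round(stats::runif(n_at, 0.05, 0.2), 4))
  traj <- trajectory_bundle(frames, top)
  per_res <- interaction_decomposition(traj)
  # group-versus-all energy equals the sum over its residue records
  all_res <- trajectory_bundle(frames, transform(top, resid = ifelse(
    group == "protein", 99L, resid)))
  lumped <- interaction_decomposition(all_res)
  expect_equal(sum(per_res$mean), lumped$mean, tolerance = 1e-12)
  expect_equal(sum(per_res$e_elec), lumped$e_elec, tolerance = 1e-12)
  # a cutoff inside the pair distances removes energy
  cut <- interaction_decomposition(traj, cutoff = 1e-3)
  expect_equal(cut$mean, rep(0, nrow(cut)))
  # missing parameters are reported by atom name
  top_bad <- top; top_bad$charge[3] <- NA
  expect_error(interaction_decomposition(trajectory_bundle(frames, top_bad)),
               "A3", class = "fepkin_input_error")
})

test_that("trajectories round-trip through multi-model PDB + topology CSV", {
  traj <- gen_trajectory(trajectory_spec(n_frames = 8, block_size = 4,
                                         occupancy = 0.5, seed = 6))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  top <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, pdb, top)
  back <- read_trajectory(pdb, top)
  expect_equal(back$frames, traj$frames, tolerance = 1e-3)
  expect_equal(back$topology$name, traj$topology$name)
  expect_equal(back$topology$charge, traj$topology$charge)
  # analyses agree on the round-tripped bundle
  contacts <- data.frame(donor = "DON", hydrogen = "HYD", acceptor = "ACC")
  expect_equal(hbond_occupancy(back, contacts, hbond_criteria(block_size = 4)),
               hbond_occupancy(traj, contacts, hbond_criteria(block_size = 4)))
})
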