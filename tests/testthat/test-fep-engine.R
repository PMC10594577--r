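# FEP estimator, profile assembly, window partitioning.

kB <- fepkin_constants$kB

test_that("perturbation increment handles degenerate and constant windows", {
  w1 <- ensemble_window(rep(2.5, 40), temperature = 298)
  expect_equal(as.numeric(perturbation_increment(w1, "zwanzig")), 2.5)
  expect_equal(as.numeric(perturbation_increment(w1, "mean")), 2.5)
  w0 <- ensemble_window(0)
  expect_equal(as.numeric(perturbation_increment(w0)), 0)
  expect_error(ensemble_window(numeric(0)), "at least one")
  expect_error(ensemble_window(c(1, NA)), "finite")
  # log-sum-exp keeps huge samples finite
  whuge <- ensemble_window(c(5000, 5001), temperature = 298)
  expect_true(is.finite(perturbation_increment(whuge)))
})

test_that("Gaussian windows recover the closed-form cumulant at large n", {
  temperature <- 298; kT <- kB * temperature
  mu <- 1.2; sigma <- 0.25; n <- 1e5
  set.seed(314)
  x <- stats::rnorm(n, mu, sigma)
  w <- ensemble_window(x, temperature = temperature)
  zw <- perturbation_increment(w, "zwanzig")
  mn <- perturbation_increment(w, "mean")
  expect_lt(abs(as.numeric(zw) - (mu - sigma^2 / (2 * kT))), 3 * attr(zw, "se"))
  expect_lt(abs(as.numeric(mn) - mu), 3 * attr(mn, "se"))
  # estimator gap converges to sigma^2 / (2 kT)
  expect_equal(as.numeric(mn) - as.numeric(zw), sigma^2 / (2 * kT),
               tolerance = 0.05)
})

test_that("profile assembly reduces to the vacuum limit and fills components", {
  coords <- matrix(seq(0, 1, length.out = 6), ncol = 1)
  e_qm0 <- c(0, 2, 5, 3, 1, -2)
  path <- reaction_path(coords, masses = 1, e_qm0 = e_qm0, zpe = rep(0.7, 6))
  wins <- lapply(1:5, function(i) ensemble_window(rep(0, 10), index = i))
  prof <- assemble_profile(path, wins)
  expect_equal(prof$dG, e_qm0 - e_qm0[1])
  expect_equal(prof$components$d_zpe, rep(0, 5))
  expect_equal(prof$forward_barrier, 5)
  expect_equal(prof$reverse_barrier, 7)
  expect_error(assemble_profile(path, wins[1:3]), "need 5 windows")
})

test_that("barrier arithmetic identity holds exactly for any profile", {
  set.seed(20)
  for (rep in 1:20) {
    dg <- cumsum(stats::rnorm(15))
    prof <- free_energy_profile(seq_len(15), dg)
    expect_identical(prof$forward_barrier - prof$reverse_barrier,
                     prof$reaction_free_energy)
  }
  # the published barrier pattern: forward 17.7 with exergonicity -7.3
  p1 <- free_energy_profile(0:2, c(0, 17.7, -7.3))
  expect_equal(p1$reverse_barrier, 25.0)
  p2 <- free_energy_profile(0:2, c(0, 21.5, -6.9))
  expect_equal(p2$reverse_barrier, 28.4)
})

test_that("assembled model-system profile matches the analytic oracle", {
  spec <- default_spec()
  g <- gen_fep_windows(spec, default_irc(), n_windows = 15, n_samples = 800,
                       seed = 23)
  prof <- assemble_profile(g$path, g$windows)
  exact <- analytic_free_profile(spec, g$path$coords[, 1])
  err <- abs(prof$dG - (exact - exact[1]))
  tol <- pmax(3 * prof$se, 1e-9)
  expect_true(all(err <= tol))
  # saddle height recovered independent of bath size
  dry <- model_surface_spec(k_bath = numeric(0), c_bath = numeric(0))
  sp <- optimize_saddle(model_energy_fn(dry), 0.3, threshold = 1e-9)
  pth <- trace_irc(model_energy_fn(dry), sp, step = 0.02)
  g0 <- gen_fep_windows(dry, pth, n_windows = 11, n_samples = 10, seed = 2)
  pr0 <- assemble_profile(g0$path, g0$windows)
  expect_equal(pr0$forward_barrier, dry$a * dry$q0^4, tolerance = 1e-4)
})

test_that("forward and reverse window sets are Crooks-consistent", {
  spec <- default_spec()
  fwd <- gen_fep_windows(spec, default_irc(), n_windows = 9, n_samples = 3000,
                         seed = 101, direction = "forward")
  rev <- gen_fep_windows(spec, default_irc(), n_windows = 9, n_samples = 3000,
                         seed = 202, direction = "reverse")
  inc_f <- lapply(fwd$windows, perturbation_increment)
  inc_r <- lapply(rev$windows, perturbation_increment)
  tot_f <- sum(vapply(inc_f, as.numeric, numeric(1)))
  tot_r <- sum(vapply(inc_r, as.numeric, numeric(1)))
  se <- sqrt(sum(vapply(inc_f, attr, numeric(1), "se")^2) +
               sum(vapply(inc_r, attr, numeric(1), "se")^2))
  expect_lt(abs(tot_f + tot_r), max(3 * se, 1e-9))
})

test_that("window anchors are evenly spaced and keep the mandatory structures", {
  coords <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  energy <- sin(seq(0, pi, length.out = 21))
  path <- compute_s(reaction_path(coords, 1, energy = energy))
  # identity when every structure is an anchor
  expect_equal(partition_windows(path, 21), 1:21)
  # evenly spaced path, 5 anchors: s quantiles {0, 1/4, 1/2, 3/4, 1}
  idx <- partition_windows(path, 5)
  expect_equal(path$s[idx] / max(path$s), c(0, 0.25, 0.5, 0.75, 1))
  # the maximal-energy structure is always an anchor
  energy2 <- c(seq(0, 1, length.out = 8), 5, seq(1, 0, length.out = 12))
  path2 <- compute_s(reaction_path(coords, 1, energy = energy2))
  for (nw in c(3, 5, 9, 14)) {
    anchors <- partition_windows(path2, nw)
    expect_length(anchors, nw)
    expect_true(all(c(1L, 21L, which.max(energy2)) %in% anchors))
  }
  expect_error(partition_windows(path, 1), "n_windows")
  expect_error(partition_windows(path, 22), "exceeds")
})

test_that("windows and profiles round-trip through CSV", {
  wins <- lapply(1:3, function(i)
    ensemble_window(stats::rnorm(5, i), index = i, s = i / 10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_windows(wins, f)
  back <- read_windows(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$samples, wins[[2]]$samples)
  expect_equal(back[[2]]$s, wins[[2]]$s)
  prof <- free_energy_profile(0:3, c(0, 4, 9, 2),
                              components = data.frame(d_eqm0 = c(4, 5, -7),
                                                      d_zpe = 0,
                                                      d_ensemble = 0))
  pf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".txt")
  write_profile(prof, pf, sf)
  tab <- read.csv(pf)
  expect_equal(tab$dG, prof$dG)
  expect_match(readLines(sf)[1], "forward_barrier: 9")
})
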