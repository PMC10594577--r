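## Seeded generators for every input class the pipeline consumes: noisy
## progress curves with known kinetic truth, toy trajectories with
## prescribed hydrogen-bond occupancies and bimodal distance populations,
## and FEP window ensembles drawn from the model system. Each generator is
## a closed loop with its analysis stage.

#' Fluorometric assay design for synthetic progress curves
#'
#' Defaults mirror a plate-reader inactivation assay: an eight-step two-fold
#' inhibitor dilution ladder topping out at 1000 nM, 30 minutes of
#' monitoring, one reading every 10 s.
#'
#' @param concentrations inhibitor ladder in molar, positive and sorted
#'   ascending; default \code{1000e-9 / 2^(7:0)} (7.8125 to 1000 nM).
#' @param duration assay length in seconds (default 1800).
#' @param interval sampling interval in seconds (default 10).
#' @param noise_model \code{"gaussian"} (additive, sd = scale x curve
#'   maximum) or \code{"proportional"} (sd = scale x instantaneous signal).
#' @param noise_scale dimensionless noise scale (default 0.02).
#' @param seed integer RNG seed.
#' @return An object of class \code{"assay_design"}.
#' @export
assay_design <- function(concentrations = 1000e-9 / 2^(7:0),
                         duration = 1800, interval = 10,
                         noise_model = c("gaussian", "proportional"),
                         noise_scale = 0.02, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (any(concentrations <= 0) || is.unsorted(concentrations))
    stop_fepkin("fepkin_input_error", "ladder must be positive and ascending")
  if (duration <= 0 || interval <= 0)
    stop_fepkin("fepkin_input_error", "duration and interval must be > 0")
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop_fepkin("fepkin_input_error", "noise scale must be >= 0")
  structure(list(concentrations = concentrations, duration = duration,
                 interval = interval, noise_model = noise_model,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "assay_design")
}

#' Generate synthetic progress curves with known kinetic truth
#'
#' Each curve follows \code{\link{simulate_progress}} with
#' \eqn{k_{obs} = k_{inact} [I] / (K_i + [I])} and initial rate
#' \eqn{v_0 = v_{0,uninh} / (1 + [I]/K_i)} (instantaneous reversible
#' binding), plus the design's noise. Negative noisy readings are clipped at
#' zero. Identical seeds give identical curves; the caller's RNG state is
#' untouched.
#'
#' @param design an \code{\link{assay_design}}.
#' @param K_i inhibition constant (molar).
#' @param k_inact inactivation rate constant (s^-1).
#' @param v0_uninhibited uninhibited initial rate (signal s^-1).
#' @return List of \code{\link{progress_curve}}s, one per ladder
#'   concentration, with the generating truth attached as attribute
#'   \code{"truth"}.
#' @export
gen_progress_curves <- function(design, K_i, k_inact, v0_uninhibited = 10) {
  stopifnot(inherits(design, "assay_design"))
  times <- seq(design$interval, design$duration, by = design$interval)
  curves <- with_seed(design$seed, lapply(design$concentrations, function(I) {
    k_obs <- k_inact * I / (K_i + I)
    v0 <- v0_uninhibited / (1 + I / K_i)
    y <- simulate_progress(v0, k_obs, times)
    if (design$noise_scale > 0) {
      sdv <- switch(design$noise_model,
                    gaussian = design$noise_scale * max(y),
                    proportional = design$noise_scale * abs(y))
      y <- pmax(y + stats::rnorm(length(y), 0, sdv), 0)
    }
    progress_curve(times, y, I)
  }))
  attr(curves, "truth") <- list(K_i = K_i, k_inact = k_inact,
                                v0_uninhibited = v0_uninhibited)
  curves
}

#' Specification of a synthetic trajectory fixture
#'
#' @param n_frames total frame count.
#' @param block_size frames per occupancy block.
#' @param occupancy target hydrogen-bond occupancy, one value recycled over
#'   blocks or one value per block, each in [0, 1].
#' @param mix_means,mix_sd,mix_weights Gaussian mixture for the probe-pair
#'   distance (defaults: a reactive 2.2 A and nonreactive 4.3 A population,
#'   sd 0.15 A, equal weights).
#' @param placement \code{"deterministic"} (quota-exact per block, default)
#'   or \code{"bernoulli"}.
#' @param seed integer RNG seed.
#' @return An object of class \code{"trajectory_spec"}.
#' @export
trajectory_spec <- function(n_frames = 500L, block_size = 50L,
                            occupancy = 0.6,
                            mix_means = c(2.2, 4.3), mix_sd = 0.15,
                            mix_weights = c(0.5, 0.5),
                            placement = c("deterministic", "bernoulli"),
                            seed = 1L) {
  placement <- match.arg(placement)
  if (any(occupancy < 0 | occupancy > 1))
    stop_fepkin("fepkin_input_error", "occupancies must lie in [0, 1]")
  if (abs(sum(mix_weights) - 1) > 1e-12)
    stop_fepkin("fepkin_input_error", "mixture weights must sum to 1")
  if (length(mix_means) != length(mix_weights))
    stop_fepkin("fepkin_input_error", "one weight per mixture component")
  structure(list(n_frames = as.integer(n_frames),
                 block_size = as.integer(block_size),
                 occupancy = occupancy, mix_means = mix_means,
                 mix_sd = mix_sd, mix_weights = mix_weights,
                 placement = placement, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a minimal trajectory with prescribed contact statistics
#'
#' Builds a five-atom system: a donor-hydrogen-acceptor triplet whose
#' geometry is switched frame by frame between a bonded pose (donor-acceptor
#' 2.8 A, angle at hydrogen 180 deg) and a broken pose (4.5 A), so that each
#' block contains exactly the prescribed fraction of bonded frames
#' (deterministic placement) or a Bernoulli draw of it; plus a probe pair
#' whose distance is drawn from the prescribed Gaussian mixture.
#'
#' Atom names: \code{DON}, \code{HYD}, \code{ACC} (contact), \code{PRB1},
#' \code{PRB2} (distance probe). All charges and LJ parameters are zero;
#' the fixture exercises geometry-driven analyses only.
#'
#' @param spec a \code{\link{trajectory_spec}}.
#' @return A \code{\link{trajectory_bundle}} with the generating truth as
#'   attribute \code{"truth"}.
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- spec$n_frames
  blocks <- split(seq_len(n), ceiling(seq_len(n) / spec$block_size))
  occ <- rep(spec$occupancy, length.out = length(blocks))
  dists <- with_seed(spec$seed, {
    comp <- sample.int(length(spec$mix_means), n, replace = TRUE,
                       prob = spec$mix_weights)
    d <- stats::rnorm(n, spec$mix_means[comp], spec$mix_sd)
    bonded <- logical(n)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      bonded[idx] <- if (spec$placement == "deterministic") {
        k <- round(occ[b] * length(idx))
        seq_along(idx) <= k
      } else stats::runif(length(idx)) < occ[b]
    }
    list(d = d, bonded = bonded)
  })
  frames <- array(0, dim = c(5L, 3L, n))
  for (f in seq_len(n)) {
    frames[1, , f] <- c(0, 0, 0)                        # DON
    frames[2, , f] <- c(1, 0, 0)                        # HYD
    frames[3, , f] <- c(if (dists$bonded[f]) 2.8 else 4.5, 0, 0)  # ACC
    frames[4, , f] <- c(10, 0, 0)                       # PRB1
    frames[5, , f] <- c(10, 0, dists$d[f])              # PRB2
  }
  topology <- data.frame(
    name = c("DON", "HYD", "ACC", "PRB1", "PRB2"),
    resid = c(1L, 1L, 2L, 3L, 1L),
    resname = c("INH", "INH", "RES", "RES", "INH"),
    group = c("P1", "P1", "protein", "protein", "P1p"),
    charge = 0, sigma = 0, epsilon = 0)
  traj <- trajectory_bundle(frames, topology)
  attr(traj, "truth") <- list(occupancy = occ, bonded = dists$bonded,
                              distances = dists$d)
  traj
}

#' Generate FEP windows by sampling the model-system bath along a path
#'
#' For each consecutive pair of anchor structures, bath configurations are
#' drawn at the earlier structure's reactive coordinates
#' (\code{\link{sample_bath}}) and the interaction-energy difference to the
#' later structure is recorded, exactly the role the per-window MM dynamics
#' plays in an FEP along an IRC. The returned path carries the gas-phase
#' ("QM") energies of the anchors, so \code{\link{assemble_profile}} on the
#' result closes the loop against \code{\link{analytic_free_profile}}.
#'
#' @param spec the \code{\link{model_surface_spec}} the path was traced on.
#' @param path a \code{"reaction_path"} in the model's generalized
#'   coordinates (from \code{\link{trace_irc}} on the same spec).
#' @param n_windows optional anchor count passed to
#'   \code{\link{partition_windows}}; default: all structures.
#' @param n_samples bath draws per window.
#' @param temperature kelvin.
#' @param seed integer seed; window w uses sub-seed \code{seed + w}.
#' @param direction \code{"forward"} (sample at the earlier state, default)
#'   or \code{"reverse"} (sample at the later state, energy difference
#'   toward the earlier one) for Crooks-style consistency checks.
#' @return List with \code{path} (the anchor subpath, gas-phase energies and
#'   zero ZPE filled, s recomputed) and \code{windows} (list of
#'   \code{\link{ensemble_window}}s aligned with consecutive anchor pairs).
#' @export
gen_fep_windows <- function(spec, path, n_windows = NULL, n_samples = 500L,
                            temperature = 298, seed = 1L,
                            direction = c("forward", "reverse")) {
  stopifnot(inherits(spec, "surface_spec"), inherits(path, "reaction_path"))
  direction <- match.arg(direction)
  n_dim <- spec$n_reactive + spec$n_bath
  if (!is.matrix(path$coords) || ncol(path$coords) != n_dim)
    stop_fepkin("fepkin_input_error",
                "path coordinates do not match the surface dimensions")
  idx <- if (is.null(n_windows)) seq_len(path$n_struct)
  else partition_windows(path, n_windows)
  q_anchor <- path$coords[idx, seq_len(spec$n_reactive), drop = FALSE]
  sub <- reaction_path(path$coords[idx, , drop = FALSE], path$masses,
                       energy = path$energy[idx],
                       e_qm0 = apply(q_anchor, 1L, qm_energy, spec = spec),
                       zpe = rep(0, length(idx)))
  sub <- compute_s(sub)
  u_int <- function(q1, x) sum(0.5 * spec$k_bath * (x - spec$c_bath * q1)^2)
  windows <- lapply(seq_len(length(idx) - 1L), function(w) {
    qa <- q_anchor[w, ]; qb <- q_anchor[w + 1L, ]
    at <- if (direction == "forward") qa else qb
    to <- if (direction == "forward") qb else qa
    bs <- sample_bath(spec, at, temperature, n_samples,
                      seed = seed + w, window = w)
    dE <- if (spec$n_bath == 0L) rep(0, n_samples)
    else apply(bs$x, 1L, function(x) u_int(to[1], x) - u_int(at[1], x))
    ensemble_window(dE, index = w, s = sub$s[w], temperature = temperature)
  })
  list(path = sub, windows = windows)
}
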