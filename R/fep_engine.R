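## Free-energy perturbation along a reaction path: per-window exponential
## (Zwanzig) or simple-mean increments, profile assembly from gas-phase
## energies + ZPE + ensemble terms, and barrier extraction.

#' Construct an ensemble window for the FEP estimator
#'
#' A window holds samples of the interaction-energy difference between one
#' path state and the next, evaluated on configurations of the environment
#' sampled with the reactive region fixed at the earlier state.
#'
#' @param samples numeric vector of interaction-energy differences
#'   (kcal mol^-1), at least one, all finite.
#' @param index window index along the path.
#' @param s path coordinate of the window's anchor state.
#' @param temperature kelvin, > 0.
#' @return An object of class \code{"ensemble_window"}.
#' @export
ensemble_window <- function(samples, index = NA_integer_, s = NA_real_,
                            temperature = 298) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop_fepkin("fepkin_input_error", "window needs at least one sample")
  if (any(!is.finite(samples)))
    stop_fepkin("fepkin_input_error", "window samples must be finite")
  if (temperature <= 0) stop_fepkin("fepkin_input_error", "temperature must be > 0")
  structure(list(index = index, s = s, samples = samples,
                 temperature = temperature),
            class = "ensemble_window")
}

# overflow-safe log-mean-exp
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Free-energy increment of one FEP window
#'
#' The default estimator is the exponential (Zwanzig) average
#' \deqn{\Delta G = -k_B T \ln \langle \exp(-\Delta E / k_B T) \rangle,}
#' evaluated through a log-sum-exp so the result is finite whenever the
#' samples are. The simple arithmetic mean \eqn{\langle \Delta E \rangle} is
#' selectable; for Gaussian samples the two differ by \eqn{\sigma^2/(2 k_B T)}
#' in the large-sample limit.
#'
#' @param window an \code{\link{ensemble_window}}.
#' @param estimator \code{"zwanzig"} (default) or \code{"mean"}.
#' @return The increment (kcal mol^-1), with its delta-method standard error
#'   as attribute \code{"se"}.
#' @export
perturbation_increment <- function(window, estimator = c("zwanzig", "mean")) {
  stopifnot(inherits(window, "ensemble_window"))
  estimator <- match.arg(estimator)
  x <- window$samples
  n <- length(x)
  kT <- fepkin_constants$kB * window$temperature
  if (estimator == "mean") {
    val <- mean(x)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  } else {
    val <- -kT * log_mean_exp(-x / kT)
    # delta method on the mean Boltzmann weight, computed in shifted space
    # for overflow safety: Var(-kT ln wbar) ~ (kT)^2 Var(w) / (n wbar^2)
    w <- exp(-(x - min(x)) / kT)
    se <- if (n > 1) kT * stats::sd(w) / (sqrt(n) * mean(w)) else 0
  }
  attr(val, "se") <- se
  val
}

#' Construct a free-energy profile and extract its barriers
#'
#' Anchors the profile at the first state, then fills the barrier fields:
#' forward barrier \eqn{= \max \Delta G - \Delta G(first)}, reverse barrier
#' \eqn{= \max \Delta G - \Delta G(last)}, and reaction free energy
#' \eqn{= \Delta G(last) - \Delta G(first)}; by construction
#' forward - reverse = reaction free energy, exactly.
#'
#' @param s path-coordinate values, non-decreasing.
#' @param dG free energies along the path (kcal mol^-1); re-anchored so the
#'   first value is 0.
#' @param components optional data frame of per-step contributions
#'   (\code{d_eqm0}, \code{d_zpe}, \code{d_ensemble}).
#' @param se optional per-state standard errors (cumulative sampling error).
#' @param temperature kelvin.
#' @return An object of class \code{"free_energy_profile"}.
#' @export
free_energy_profile <- function(s, dG, components = NULL, se = NULL,
                                temperature = 298) {
  if (length(s) != length(dG))
    stop_fepkin("fepkin_input_error", "s and dG must have equal length")
  if (is.unsorted(s)) stop_fepkin("fepkin_input_error", "s must be non-decreasing")
  dG <- dG - dG[1]
  fwd <- max(dG) - dG[1]
  rev <- max(dG) - dG[length(dG)]
  # the identity forward - reverse = dG_rxn is enforced bitwise, not just
  # algebraically, so downstream arithmetic can rely on it
  structure(list(s = s, dG = dG, components = components, se = se,
                 forward_barrier = fwd, reverse_barrier = rev,
                 reaction_free_energy = fwd - rev,
                 temperature = temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Free-energy profile:", length(x$s), "states\n")
  cat(sprintf("  forward barrier  %8.3f kcal/mol\n", x$forward_barrier))
  cat(sprintf("  reverse barrier  %8.3f kcal/mol\n", x$reverse_barrier))
  cat(sprintf("  reaction dG      %8.3f kcal/mol\n", x$reaction_free_energy))
  invisible(x)
}

#' Assemble a free-energy profile from a path and FEP windows
#'
#' The free energy accumulates per step as
#' \deqn{\Delta G(s_{i+1}) = \Delta G(s_i) + [E^0_{QM,i+1} - E^0_{QM,i}] +
#'   [ZPE_{i+1} - ZPE_i] + \delta G^{ens}_i,}
#' with the ensemble term \eqn{\delta G^{ens}_i} estimated from window
#' \eqn{i}'s samples by \code{\link{perturbation_increment}}. The profile is
#' anchored at the first (reactant-side) state.
#'
#' @param path a \code{"reaction_path"} carrying \code{e_qm0}, \code{zpe}
#'   and \code{s} (run \code{\link{compute_s}} first if needed).
#' @param windows list of \code{\link{ensemble_window}}s, one per
#'   consecutive structure pair, in path order.
#' @param estimator passed to \code{\link{perturbation_increment}}.
#' @return A \code{"free_energy_profile"} with component breakdown and the
#'   accumulated Monte-Carlo standard error per state.
#' @export
assemble_profile <- function(path, windows, estimator = c("zwanzig", "mean")) {
  stopifnot(inherits(path, "reaction_path"))
  estimator <- match.arg(estimator)
  n <- path$n_struct
  if (length(windows) != n - 1L)
    stop_fepkin("fepkin_input_error", "need ", n - 1L, " windows for ", n,
                " structures (got ", length(windows), ")")
  if (is.null(path$e_qm0) || is.null(path$zpe))
    stop_fepkin("fepkin_input_error", "path must carry e_qm0 and zpe")
  if (is.null(path$s)) path <- compute_s(path)
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) != 1L)
    stop_fepkin("fepkin_input_error", "windows must share one temperature")
  inc <- lapply(windows, perturbation_increment, estimator = estimator)
  d_ens <- vapply(inc, as.numeric, numeric(1))
  se_step <- vapply(inc, attr, numeric(1), "se")
  d_eqm0 <- diff(path$e_qm0)
  d_zpe <- diff(path$zpe)
  dG <- c(0, cumsum(d_eqm0 + d_zpe + d_ens))
  se <- c(0, sqrt(cumsum(se_step^2)))
  free_energy_profile(path$s, dG,
                      components = data.frame(d_eqm0 = d_eqm0, d_zpe = d_zpe,
                                              d_ensemble = d_ens),
                      se = se, temperature = temps[1])
}

#' Select FEP window anchors along a path
#'
#' Picks \code{n_windows} structures evenly spaced in the path coordinate
#' \code{s} as window anchor states, always retaining the first structure,
#' the last structure, and the structure of maximal energy (the barrier top
#' must never be skipped by coarsening).
#'
#' @param path a \code{"reaction_path"} with \code{s} (and, if available,
#'   energies used to protect the barrier-top structure).
#' @param n_windows number of anchor states, between 2 and the structure
#'   count.
#' @return Integer vector of structure indices (sorted, unique, length
#'   \code{n_windows}).
#' @export
partition_windows <- function(path, n_windows) {
  stopifnot(inherits(path, "reaction_path"))
  n_windows <- as.integer(n_windows)
  n <- path$n_struct
  if (is.na(n_windows) || n_windows < 2L)
    stop_fepkin("fepkin_input_error", "n_windows must be >= 2")
  if (n_windows > n)
    stop_fepkin("fepkin_input_error", "n_windows exceeds structure count")
  if (is.null(path$s)) path <- compute_s(path)
  targets <- seq(0, max(path$s), length.out = n_windows)
  idx <- vapply(targets, function(t) which.min(abs(path$s - t)), integer(1))
  idx <- unique(idx)
  must <- unique(c(1L, n, if (!is.null(path$energy)) which.max(path$energy)))
  idx <- sort(unique(c(idx, must)))
  # restore the requested count after de-duplication / forced inclusions
  while (length(idx) > n_windows) {
    drop_ok <- setdiff(idx, must)
    gaps <- diff(path$s[idx])
    # drop the removable anchor in the tightest spot
    cand <- drop_ok[which.min(vapply(drop_ok, function(i) {
      k <- match(i, idx)
      min(gaps[max(1, k - 1)], gaps[min(length(gaps), k)])
    }, numeric(1)))]
    idx <- setdiff(idx, cand)
  }
  while (length(idx) < n_windows) {
    free <- setdiff(seq_len(n), idx)
    if (length(free) == 0L) break
    k <- which.max(diff(path$s[idx]))          # widest gap in s
    mid <- (path$s[idx[k]] + path$s[idx[k + 1]]) / 2
    idx <- sort(c(idx, free[which.min(abs(path$s[free] - mid))]))
  }
  idx
}

## ---- I/O ---------------------------------------------------------------

#' Read / write FEP windows as CSV
#'
#' Long format with columns \code{window}, \code{sample_id}, \code{dE_int};
#' optional \code{s} column carried through when present.
#'
#' @param windows list of \code{\link{ensemble_window}}s.
#' @param file CSV path.
#' @param temperature temperature assigned to windows on reading.
#' @return \code{read_windows} returns a list of \code{ensemble_window}s.
#' @export
write_windows <- function(windows, file) {
  tab <- do.call(rbind, lapply(windows, function(w)
    data.frame(window = w$index, s = w$s, sample_id = seq_along(w$samples),
               dE_int = w$samples)))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_windows
#' @export
read_windows <- function(file, temperature = 298) {
  tab <- utils::read.csv(file)
  lapply(split(tab, tab$window)[order(unique(tab$window))], function(d)
    ensemble_window(d$dE_int, index = d$window[1],
                    s = if ("s" %in% names(d)) d$s[1] else NA_real_,
                    temperature = temperature))
}

#' Write a free-energy profile as CSV plus a summary block
#'
#' The CSV has one row per state (\code{s}, \code{dG}, per-step components
#' shifted onto the arriving state); the summary is a small key: value text
#' block with the barriers and reaction free energy.
#'
#' @param profile a \code{"free_energy_profile"}.
#' @param file CSV path.
#' @param summary_file optional text path for the barrier summary.
#' @export
write_profile <- function(profile, file, summary_file = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  comp <- profile$components
  pad <- function(v) if (is.null(comp)) NA_real_ else c(NA, v)
  tab <- data.frame(s = profile$s, dG = profile$dG,
                    d_eqm0 = pad(comp$d_eqm0), d_zpe = pad(comp$d_zpe),
                    d_ensemble = pad(comp$d_ensemble))
  utils::write.csv(tab, file, row.names = FALSE)
  if (!is.null(summary_file)) {
    writeLines(c(
      sprintf("forward_barrier: %.6f", profile$forward_barrier),
      sprintf("reverse_barrier: %.6f", profile$reverse_barrier),
      sprintf("reaction_free_energy: %.6f", profile$reaction_free_energy),
      sprintf("temperature: %.2f", profile$temperature)
    ), summary_file)
  }
  invisible(file)
}
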