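#' Toy QM/MM model system: a reactive potential coupled to a harmonic bath
#'
#' A low-dimensional surrogate for a QM/MM Hamiltonian: the "QM" part is a
#' quartic double well in the first reactive coordinate (optionally tilted,
#' optionally with a harmonic transverse reactive coordinate), and the "MM"
#' part is a set of harmonic bath oscillators bilinearly coupled to the first
#' reactive coordinate,
#' \deqn{V(q, x) = a (q_1^2 - q_0^2)^2 + b q_1 + \sum_{r \ge 2}
#'   \tfrac{1}{2} k_\perp q_r^2 + \sum_b \tfrac{1}{2} k_b (x_b - c_b q_1)^2.}
#' Because the coupling is bilinear with coordinate-independent force
#' constants, the bath integrates out to an additive constant: free-energy
#' differences along \eqn{q_1} equal differences of the gas-phase ("QM")
#' potential, which makes every path/FEP operation in the package testable
#' against an analytic oracle.
#'
#' The transverse force constant is fixed at \eqn{k_\perp = 2 a q_0^2}, the
#' geometric mean scale of the well curvatures, so the two-coordinate variant
#' has a genuine index-1 saddle at the origin.
#'
#' @param n_reactive number of reactive ("QM") coordinates, 1 or 2.
#' @param a quartic well parameter (kcal mol^-1 A^-4), > 0.
#' @param q0 half well separation (A), > 0; minima near q1 = +/- q0.
#' @param b linear tilt (kcal mol^-1 A^-1); 0 gives a symmetric double well.
#' @param k_bath bath force constants (kcal mol^-1 A^-2), all > 0; the bath
#'   size is \code{length(k_bath)} and may be zero.
#' @param c_bath dimensionless bilinear coupling coefficients, same length as
#'   \code{k_bath}.
#' @param masses per-coordinate masses (amu) for the reactive coordinates
#'   followed by the bath coordinates; defaults to 1 amu each.
#'
#' @return An object of class \code{"surface_spec"}.
#' @examples
#' spec <- model_surface_spec()            # defaults: saddle height a*q0^4 = 1
#' evaluate_total_energy(spec, q = 1, x = c(0.5, -0.3))
#' @export
model_surface_spec <- function(n_reactive = 1L, a = 1, q0 = 1, b = 0,
                               k_bath = c(2, 4), c_bath = c(0.5, -0.3),
                               masses = NULL) {
  n_reactive <- as.integer(n_reactive)
  if (!n_reactive %in% c(1L, 2L)) stop("n_reactive must be 1 or 2")
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("a must be a positive scalar")
  if (!is.numeric(q0) || length(q0) != 1L || q0 <= 0) stop("q0 must be a positive scalar")
  if (!is.numeric(b) || length(b) != 1L) stop("b must be a scalar")
  if (length(k_bath) != length(c_bath))
    stop("k_bath and c_bath must have equal length")
  if (length(k_bath) > 0 && any(k_bath <= 0)) stop("all bath force constants must be > 0")
  n_dim <- n_reactive + length(k_bath)
  if (is.null(masses)) masses <- rep(1, n_dim)
  if (length(masses) != n_dim || any(masses <= 0))
    stop("masses must be ", n_dim, " positive values")
  structure(list(
    n_reactive = n_reactive, a = a, q0 = q0, b = b,
    k_bath = as.numeric(k_bath), c_bath = as.numeric(c_bath),
    masses = as.numeric(masses), n_bath = length(k_bath)
  ), class = "surface_spec")
}

#' @export
print.surface_spec <- function(x, ...) {
  cat("Toy QM/MM surface:", x$n_reactive, "reactive coordinate(s),",
      x$n_bath, "bath oscillator(s)\n")
  cat(sprintf("  V_QM = %g (q^2 - %g^2)^2 %+g q   (saddle height %g kcal/mol at b = 0)\n",
              x$a, x$q0, x$b, x$a * x$q0^4))
  if (x$n_bath > 0)
    cat("  bath k =", paste(format(x$k_bath), collapse = ", "),
        " coupling c =", paste(format(x$c_bath), collapse = ", "), "\n")
  invisible(x)
}

# transverse harmonic force constant for the second reactive coordinate
k_perp <- function(spec) 2 * spec$a * spec$q0^2

# gas-phase ("QM") potential; q is a numeric vector of length n_reactive
qm_energy <- function(spec, q) {
  q <- as.numeric(q)
  if (length(q) != spec$n_reactive)
    stop("q must have length ", spec$n_reactive)
  e <- spec$a * (q[1]^2 - spec$q0^2)^2 + spec$b * q[1]
  if (spec$n_reactive == 2L) e <- e + 0.5 * k_perp(spec) * q[2]^2
  e
}

# bath + coupling term at fixed reactive coordinates
bath_energy <- function(spec, q, x) {
  if (spec$n_bath == 0L) return(0)
  sum(0.5 * spec$k_bath * (x - spec$c_bath * q[1])^2)
}

#' Total energy of the toy QM/MM system
#'
#' \eqn{V(q, x) = V_{QM}(q) + \sum_b \tfrac{1}{2} k_b (x_b - c_b q_1)^2}.
#'
#' @param spec a \code{\link{model_surface_spec}}.
#' @param q reactive coordinates (length \code{n_reactive}).
#' @param x bath coordinates (length \code{n_bath}); may be omitted when the
#'   bath is empty.
#' @return Energy in kcal mol^-1.
#' @export
evaluate_total_energy <- function(spec, q, x = numeric(0)) {
  stopifnot(inherits(spec, "surface_spec"))
  if (length(x) != spec$n_bath)
    stop("x must have length ", spec$n_bath, " (got ", length(x), ")")
  qm_energy(spec, q) + bath_energy(spec, q, x)
}

#' Full-dimensional energy function of a model surface
#'
#' Packs reactive and bath coordinates into a single vector
#' \code{z = c(q, x)} and returns \code{function(z)} suitable for the
#' stationary-point and IRC machinery in \code{\link{optimize_saddle}} /
#' \code{\link{trace_irc}}.
#'
#' @param spec a \code{\link{model_surface_spec}}.
#' @return A function mapping a numeric vector of length
#'   \code{n_reactive + n_bath} to an energy; carries the coordinate masses
#'   as attribute \code{"masses"}.
#' @export
model_energy_fn <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  nr <- spec$n_reactive
  f <- function(z) evaluate_total_energy(spec, z[seq_len(nr)], z[-seq_len(nr)])
  attr(f, "masses") <- spec$masses
  f
}

#' Exact free-energy profile with the bath integrated out
#'
#' For bilinear coupling with coordinate-independent bath force constants the
#' bath partition function does not depend on the reactive coordinate, so
#' \deqn{A(q) = V_{QM}(q) - k_B T \sum_b \tfrac{1}{2}
#'   \ln\!\left(2 \pi k_B T / k_b\right),}
#' and free-energy differences equal gas-phase potential differences at any
#' temperature. This is the analytic oracle against which the FEP estimator
#' is validated.
#'
#' @param spec a \code{\link{model_surface_spec}}.
#' @param q_grid numeric vector of values of the first reactive coordinate
#'   (the transverse coordinate, if present, is held at 0), or a matrix with
#'   \code{n_reactive} columns.
#' @param temperature temperature in kelvin, > 0.
#' @return Numeric vector of free energies (kcal mol^-1), one per grid point,
#'   including the additive bath constant.
#' @export
analytic_free_profile <- function(spec, q_grid, temperature = 298) {
  stopifnot(inherits(spec, "surface_spec"))
  if (temperature <= 0) stop("temperature must be > 0")
  kT <- fepkin_constants$kB * temperature
  qmat <- if (is.matrix(q_grid)) q_grid else {
    m <- matrix(0, nrow = length(q_grid), ncol = spec$n_reactive)
    m[, 1] <- q_grid
    m
  }
  if (ncol(qmat) != spec$n_reactive)
    stop("q_grid must have ", spec$n_reactive, " columns")
  bath_const <- if (spec$n_bath > 0)
    -kT * sum(0.5 * log(2 * pi * kT / spec$k_bath)) else 0
  apply(qmat, 1L, function(q) qm_energy(spec, q)) + bath_const
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw equilibrium bath configurations at fixed reactive coordinates
#'
#' The bath is harmonic, so equilibrium sampling is exact: each bath
#' coordinate is Gaussian with mean \eqn{c_b q_1} and variance
#' \eqn{k_B T / k_b}. At \eqn{T = 0} all samples sit at the bath minimum.
#' This plays the role of the per-window MM molecular dynamics with the QM
#' atoms held fixed; exact draws remove integrator error from downstream
#' estimator tests.
#'
#' @param spec a \code{\link{model_surface_spec}}.
#' @param q_fixed reactive coordinates held fixed during sampling.
#' @param temperature kelvin, >= 0.
#' @param n number of samples, >= 1.
#' @param seed integer seed; identical seeds reproduce identical samples. The
#'   caller's RNG state is left untouched.
#' @param window optional window index carried along for bookkeeping.
#' @return An object of class \code{"bath_sample"}: a list with the sample
#'   matrix \code{x} (n rows, one column per bath coordinate), the per-sample
#'   bath/coupling \code{energy}, and the sampling metadata.
#' @export
sample_bath <- function(spec, q_fixed, temperature = 298, n = 1000L,
                        seed = 1L, window = NA_integer_) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (temperature < 0) stop("temperature must be >= 0")
  q_fixed <- as.numeric(q_fixed)
  if (length(q_fixed) != spec$n_reactive)
    stop("q_fixed must have length ", spec$n_reactive)
  mu <- spec$c_bath * q_fixed[1]
  sdv <- if (temperature > 0)
    sqrt(fepkin_constants$kB * temperature / spec$k_bath) else rep(0, spec$n_bath)
  x <- with_seed(seed, {
    if (spec$n_bath == 0L) matrix(numeric(0), nrow = n, ncol = 0)
    else matrix(stats::rnorm(n * spec$n_bath, mean = rep(mu, each = n),
                             sd = rep(sdv, each = n)),
                nrow = n, ncol = spec$n_bath)
  })
  energy <- if (spec$n_bath == 0L) rep(0, n)
  else colSums(0.5 * spec$k_bath * (t(x) - mu)^2)
  structure(list(window = window, q = q_fixed, x = x, energy = energy,
                 temperature = temperature, seed = seed),
            class = "bath_sample")
}

#' @export
print.bath_sample <- function(x, ...) {
  cat(sprintf("Bath sample: %d draws, %d bath coordinate(s), T = %g K, seed %s\n",
              nrow(x$x), ncol(x$x), x$temperature, format(x$seed)))
  invisible(x)
}

#' Serialize / restore a model surface specification
#'
#' The specification round-trips through YAML with keys matching the
#' constructor arguments.
#'
#' @param spec a \code{\link{model_surface_spec}}.
#' @param file path to a YAML file.
#' @return \code{read_surface_spec} returns a \code{"surface_spec"};
#'   \code{write_surface_spec} returns \code{file} invisibly.
#' @export
write_surface_spec <- function(spec, file) {
  stopifnot(inherits(spec, "surface_spec"))
  yaml::write_yaml(list(n_reactive = spec$n_reactive, a = spec$a, q0 = spec$q0,
                        b = spec$b, k_bath = spec$k_bath, c_bath = spec$c_bath,
                        masses = spec$masses), file)
  invisible(file)
}

#' @rdname write_surface_spec
#' @export
read_surface_spec <- function(file) {
  y <- yaml::read_yaml(file)
  model_surface_spec(n_reactive = y$n_reactive, a = y$a, q0 = y$q0, b = y$b,
                     k_bath = unlist(y$k_bath), c_bath = unlist(y$c_bath),
                     masses = unlist(y$masses))
}

#' Write bath samples as CSV
#'
#' One row per draw with columns \code{window}, \code{sample}, \code{energy}.
#'
#' @param samples a \code{"bath_sample"} or a list of them.
#' @param file output CSV path.
#' @export
write_bath_samples <- function(samples, file) {
  if (inherits(samples, "bath_sample")) samples <- list(samples)
  tab <- do.call(rbind, lapply(samples, function(s)
    data.frame(window = s$window, sample = seq_along(s$energy),
               energy = s$energy)))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
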