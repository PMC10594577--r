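## Two-step irreversible (covalent) inhibition kinetics:
##   E + I <-> E:I -> E-I      (reversible binding K_i, inactivation k_inact)
## Progress curves follow the classical exponential-approach form, the
## observed rate is hyperbolic in [I], and rates interconvert with activation
## free energies through the Eyring relation.

#' Construct a progress curve
#'
#' A fluorometric progress curve: product-proportional signal versus time at
#' one inhibitor concentration.
#'
#' @param time time points in seconds, strictly increasing.
#' @param signal signal values (arbitrary units), non-negative.
#' @param inhibitor inhibitor concentration in molar.
#' @param substrate optional substrate concentration (molar).
#' @param km optional Michaelis constant (molar) for substrate competition.
#' @return An object of class \code{"progress_curve"}.
#' @export
progress_curve <- function(time, signal, inhibitor,
                           substrate = NA_real_, km = NA_real_) {
  if (length(time) != length(signal))
    stop_fepkin("fepkin_input_error", "time and signal must have equal length")
  if (any(diff(time) <= 0))
    stop_fepkin("fepkin_input_error", "time must be strictly increasing")
  if (any(signal < 0))
    stop_fepkin("fepkin_input_error", "signal must be non-negative")
  if (inhibitor < 0)
    stop_fepkin("fepkin_input_error", "inhibitor concentration must be >= 0")
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 inhibitor = inhibitor, substrate = substrate, km = km),
            class = "progress_curve")
}

#' Simulated progress curve for time-dependent inhibition
#'
#' \deqn{P(t) = v_0 \left(1 - e^{-k_{obs} t}\right) / k_{obs},}
#' the product signal when the instantaneous rate decays exponentially from
#' \eqn{v_0} as the enzyme is inactivated with observed rate \eqn{k_{obs}}.
#' The \eqn{k_{obs} = 0} limit is the uninhibited straight line \eqn{v_0 t};
#' the implementation (via \code{expm1}) is continuous through that limit.
#'
#' @param v0 initial rate (signal s^-1), >= 0.
#' @param k_obs observed inactivation rate (s^-1), >= 0.
#' @param times time points (s).
#' @return Signal values at \code{times}.
#' @export
simulate_progress <- function(v0, k_obs, times) {
  if (v0 < 0 || k_obs < 0)
    stop_fepkin("fepkin_input_error", "v0 and k_obs must be >= 0")
  if (k_obs == 0) return(v0 * times)
  v0 * (-expm1(-k_obs * times)) / k_obs
}

#' Fit the observed inactivation rate of one progress curve
#'
#' Nonlinear least-squares fit of \code{\link{simulate_progress}} to a
#' progress curve, returning \eqn{v_0} and \eqn{k_{obs}} with standard
#' errors and residual diagnostics. Starting values come from the early
#' slope and the curvature of the trace.
#'
#' @param curve a \code{\link{progress_curve}} with at least 5 points.
#' @return A list with \code{v0}, \code{k_obs}, \code{se} (named vector),
#'   \code{residual_sd}, \code{fit} (the \code{nls} object) and the curve's
#'   inhibitor concentration.
#' @export
fit_kobs <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$time; y <- curve$signal
  if (length(t) < 5L)
    stop_fepkin("fepkin_input_error", "need at least 5 time points")
  if (stats::sd(y) == 0 || stats::coef(stats::lm(y ~ t))[2] <= 0)
    stop_fepkin("fepkin_fit_error",
                "signal has no usable slope; k_obs is unidentifiable")
  n_head <- max(3L, ceiling(length(t) / 10))
  v0_start <- max(stats::coef(stats::lm(y[1:n_head] ~ t[1:n_head]))[2], 1e-12)
  # curvature-based k_obs guess: final rate / initial rate = exp(-k T)
  v_end <- stats::coef(stats::lm(utils::tail(y, n_head) ~ utils::tail(t, n_head)))[2]
  ratio <- min(max(v_end / v0_start, 1e-6), 1)
  k_start <- max(-log(ratio) / (max(t) - min(t)), 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ simulate_progress(v0, k, t),
                      start = list(v0 = v0_start, k = k_start),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_fepkin("fepkin_fit_error",
                                    "k_obs fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(v0 = NA_real_, k = NA_real_))
  list(v0 = unname(cf["v0"]), k_obs = unname(cf["k"]),
       se = c(v0 = unname(se[1]), k_obs = unname(se[2])),
       residual_sd = stats::sigma(fit), fit = fit,
       inhibitor = curve$inhibitor)
}

#' Fit the two-step inhibition constants from a set of progress curves
#'
#' Two-stage procedure: each curve is fitted for its \eqn{k_{obs}}
#' (\code{\link{fit_kobs}}), then the hyperbola
#' \deqn{k_{obs}([I]) = k_{inact} [I] / (K_i^{app} + [I])}
#' is fitted across concentrations by weighted nonlinear least squares
#' (weights \eqn{1/SE^2} from stage one). With substrate competition
#' enabled and \eqn{[S]}, \eqn{K_m} supplied on the curves,
#' \eqn{K_i^{app} = K_i (1 + [S]/K_m)}; otherwise \eqn{K_i^{app} = K_i}.
#' When the design never approaches saturation (all \eqn{[I]} far below
#' \eqn{K_i}) the hyperbola degenerates to a line through the origin: the
#' fit then warns, reports the second-order efficiency from the slope, and
#' flags \eqn{K_i} and \eqn{k_{inact}} as unidentifiable.
#'
#' @param curves list of \code{\link{progress_curve}}s at >= 4 distinct
#'   inhibitor concentrations (a zero-inhibitor control is used for \eqn{v_0}
#'   context but not the hyperbola).
#' @param competition apply the substrate-competition correction (default
#'   off; the correction needs \code{substrate} and \code{km} on the curves).
#' @return An object of class \code{"inhibition_fit"} with \code{K_i} (M),
#'   \code{k_inact} (s^-1), standard errors, per-curve \code{k_obs} table,
#'   \code{efficiency} (= k_inact/K_i, M^-1 s^-1) and its delta-method SE.
#' @export
fit_two_step <- function(curves, competition = FALSE) {
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "progress_curve")))
    stop_fepkin("fepkin_input_error", "curves must be progress_curve objects")
  conc <- vapply(curves, `[[`, numeric(1), "inhibitor")
  if (length(unique(conc[conc > 0])) < 4L)
    stop_fepkin("fepkin_input_error", "need >= 4 distinct nonzero [I] values")
  stage1 <- lapply(curves[conc > 0], fit_kobs)
  kobs_tab <- data.frame(
    inhibitor = vapply(stage1, `[[`, numeric(1), "inhibitor"),
    k_obs = vapply(stage1, `[[`, numeric(1), "k_obs"),
    se = vapply(stage1, function(f) f$se["k_obs"], numeric(1)),
    v0 = vapply(stage1, `[[`, numeric(1), "v0"))
  comp_factor <- 1
  if (competition) {
    s_over_km <- vapply(curves[conc > 0],
                        function(cv) cv$substrate / cv$km, numeric(1))
    if (any(!is.finite(s_over_km)))
      stop_fepkin("fepkin_input_error",
                  "competition correction needs substrate and km on every curve")
    if (length(unique(round(s_over_km, 10))) != 1L)
      stop_fepkin("fepkin_input_error", "[S]/Km must be shared across curves")
    comp_factor <- 1 + s_over_km[1]
  }
  w <- ifelse(is.finite(kobs_tab$se) & kobs_tab$se > 0, 1 / kobs_tab$se^2, 1)
  ki_start <- stats::median(kobs_tab$inhibitor)
  kin_start <- max(kobs_tab$k_obs)
  hyp <- tryCatch(
    minpack.lm::nlsLM(k_obs ~ kinact * inhibitor / (kiapp + inhibitor),
                      data = kobs_tab, weights = w,
                      start = list(kinact = kin_start, kiapp = ki_start),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  cf <- if (!is.null(hyp)) stats::coef(hyp)
  se <- if (!is.null(hyp))
    tryCatch(sqrt(diag(stats::vcov(hyp))), error = function(e) rep(NA_real_, 2))
  # linear regime: hyperbola unresolved when the fitted Ki dwarfs the ladder
  # or its uncertainty swamps the estimate
  unidentifiable <- is.null(hyp) ||
    cf[["kiapp"]] > 50 * max(kobs_tab$inhibitor) ||
    (is.finite(se[2]) && se[2] > 5 * cf[["kiapp"]])
  if (unidentifiable) {
    warning("[I] ladder never approaches K_i: only k_inact/K_i is identifiable",
            call. = FALSE)
    lin <- stats::lm(k_obs ~ 0 + inhibitor, data = kobs_tab, weights = w)
    eff <- unname(stats::coef(lin)[1]) / comp_factor
    eff_se <- unname(sqrt(diag(stats::vcov(lin)))[1]) / comp_factor
    out <- list(K_i = NA_real_, k_inact = NA_real_,
                se = c(K_i = NA_real_, k_inact = NA_real_),
                efficiency = eff, efficiency_se = eff_se,
                kobs_table = kobs_tab, competition = competition,
                comp_factor = comp_factor, identifiable = FALSE, fit = NULL)
    class(out) <- "inhibition_fit"
    return(out)
  }
  ki <- unname(cf["kiapp"]) / comp_factor
  kinact <- unname(cf["kinact"])
  ki_se <- unname(se[2]) / comp_factor
  kin_se <- unname(se[1])
  eff <- kinact / ki
  corr <- tryCatch(stats::vcov(hyp)[1, 2], error = function(e) 0)
  eff_se <- eff * sqrt((kin_se / kinact)^2 + (ki_se / ki)^2 -
                         2 * corr / (kinact * unname(cf["kiapp"])))
  out <- list(K_i = ki, k_inact = kinact,
              se = c(K_i = ki_se, k_inact = kin_se),
              efficiency = eff, efficiency_se = eff_se,
              kobs_table = kobs_tab, competition = competition,
              comp_factor = comp_factor, identifiable = TRUE, fit = hyp)
  class(out) <- "inhibition_fit"
  out
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Two-step irreversible inhibition fit\n")
  if (x$identifiable) {
    cat(sprintf("  K_i      = %.4g M  (%.3g nM)  +/- %.3g nM\n",
                x$K_i, x$K_i * 1e9, x$se["K_i"] * 1e9))
    cat(sprintf("  k_inact  = %.4g s^-1  +/- %.3g\n", x$k_inact, x$se["k_inact"]))
  } else {
    cat("  K_i, k_inact: unidentifiable (linear regime)\n")
  }
  cat(sprintf("  k_inact/K_i = %.4g M^-1 s^-1\n", x$efficiency))
  if (x$competition)
    cat(sprintf("  substrate competition applied, 1 + [S]/Km = %.4g\n",
                x$comp_factor))
  invisible(x)
}

#' Eyring conversion: rate constant to activation free energy
#'
#' Transition-state theory with unit transmission coefficient:
#' \deqn{\Delta G^\ddagger = R T \ln\!\left(\frac{k_B T}{h\,k}\right),}
#' using \eqn{k_B T / h = 6.2093 \times 10^{12}} s^-1 at 298 K.
#'
#' @param k first-order rate constant (s^-1), > 0.
#' @param temperature kelvin, > 0 (default 298).
#' @return An object of class \code{"tst_result"} with the rate, the barrier
#'   (kcal mol^-1) and the temperature.
#' @export
eyring_barrier <- function(k, temperature = 298) {
  if (!is.numeric(k) || k <= 0)
    stop_fepkin("fepkin_input_error", "rate constant must be > 0")
  if (temperature <= 0) stop_fepkin("fepkin_input_error", "temperature must be > 0")
  prefactor <- fepkin_constants$kB_over_h * temperature
  dg <- fepkin_constants$R * temperature * log(prefactor / k)
  structure(list(k = k, barrier = dg, temperature = temperature),
            class = "tst_result")
}

#' Eyring conversion: activation free energy to rate constant
#'
#' \deqn{k = \frac{k_B T}{h} e^{-\Delta G^\ddagger / R T}.} Round-trips with
#' \code{\link{eyring_barrier}} to 1e-10 relative.
#'
#' @param barrier activation free energy (kcal mol^-1).
#' @param temperature kelvin, > 0.
#' @return Rate constant in s^-1.
#' @export
eyring_rate <- function(barrier, temperature = 298) {
  if (temperature <= 0) stop_fepkin("fepkin_input_error", "temperature must be > 0")
  prefactor <- fepkin_constants$kB_over_h * temperature
  prefactor * exp(-barrier / (fepkin_constants$R * temperature))
}

#' @export
print.tst_result <- function(x, ...) {
  cat(sprintf("TST: k = %.4g s^-1  <->  dG++ = %.4g kcal/mol at %g K\n",
              x$k, x$barrier, x$temperature))
  invisible(x)
}

#' Second-order inactivation efficiency k_inact / K_i
#'
#' @param k_inact inactivation rate constant (s^-1), > 0.
#' @param K_i inhibition constant (molar), > 0.
#' @return Efficiency in M^-1 s^-1.
#' @export
efficiency <- function(k_inact, K_i) {
  if (!is.numeric(k_inact) || k_inact <= 0)
    stop_fepkin("fepkin_input_error", "k_inact must be > 0")
  if (!is.numeric(K_i) || K_i <= 0)
    stop_fepkin("fepkin_input_error", "K_i must be > 0")
  k_inact / K_i
}

## ---- I/O ---------------------------------------------------------------

#' Read / write progress curves as CSV
#'
#' Long format with columns \code{time_s}, \code{signal},
#' \code{inhibitor_nM} and optionally \code{substrate_uM}, \code{Km_uM}.
#' Concentrations are stored in the assay-friendly units named in the
#' header and converted to molar on reading.
#'
#' @param curves list of \code{\link{progress_curve}}s.
#' @param file CSV path.
#' @return \code{read_progress_curves} returns a list of
#'   \code{progress_curve}s, one per distinct inhibitor concentration.
#' @export
write_progress_curves <- function(curves, file) {
  tab <- do.call(rbind, lapply(curves, function(cv) {
    d <- data.frame(time_s = cv$time, signal = cv$signal,
                    inhibitor_nM = cv$inhibitor * 1e9)
    if (!is.na(cv$substrate)) d$substrate_uM <- cv$substrate * 1e6
    if (!is.na(cv$km)) d$Km_uM <- cv$km * 1e6
    d
  }))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_progress_curves
#' @export
read_progress_curves <- function(file) {
  tab <- utils::read.csv(file)
  lapply(split(tab, tab$inhibitor_nM), function(d)
    progress_curve(d$time_s, d$signal, d$inhibitor_nM[1] * 1e-9,
                   substrate = if ("substrate_uM" %in% names(d))
                     d$substrate_uM[1] * 1e-6 else NA_real_,
                   km = if ("Km_uM" %in% names(d))
                     d$Km_uM[1] * 1e-6 else NA_real_))
}
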