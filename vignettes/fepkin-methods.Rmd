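---
title: "Methods: free-energy perturbation along reaction paths and covalent inhibition kinetics"
author: "fepkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy perturbation along reaction paths and covalent inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepkin)
```

# Scope

`fepkin` implements the desk-scale computational chain used to characterize
covalent inhibition of a cysteine protease such as cathepsin L by Michael
acceptor warheads: (i) location and verification of transition states and
intrinsic reaction coordinates (IRC) on an energy surface, with the
mass-weighted path coordinate *s*; (ii) a free-energy-perturbation (FEP)
estimator that assembles a free-energy profile along the path from gas-phase
energies, zero-point corrections and ensemble averages of interaction-energy
differences; (iii) trajectory analyses (hydrogen-bond occupancy, distance
populations, RMSD, per-residue interaction-energy decomposition); and
(iv) two-step irreversible inhibition kinetics with Eyring interconversion
of rates and activation free energies. Because the electronic-structure and
enzyme-scale MD layers of such a study cannot run at desk scale, every
path/FEP operation is exercised on an analytically solvable model system,
and every analysis stage has a seeded generator that closes the loop on
known truth.

# The model system

The surrogate for a QM/MM Hamiltonian is a quartic double well bilinearly
coupled to a harmonic bath:

$$V(q, x) = a\,(q_1^2 - q_0^2)^2 + b\,q_1 + \sum_{r \ge 2} \tfrac12 k_\perp q_r^2
 + \sum_b \tfrac12 k_b\,(x_b - c_b\,q_1)^2 .$$

The defaults ($a = 1$ kcal mol^-1^ Å^-4^, $q_0 = 1$ Å, $b = 0$, two bath
oscillators with $k_b = (2, 4)$ kcal mol^-1^ Å^-2^ and $c_b = (0.5, -0.3)$,
unit masses) give a symmetric barrier of exactly $a\,q_0^4 = 1$ kcal
mol^-1^, so all tests are scale-free. Two properties make this the right
oracle:

* **Exact bath integration.** With coordinate-independent $k_b$, the bath
  partition function does not depend on $q_1$, so free-energy differences
  along the reactive coordinate equal differences of the bare reactive
  potential at any temperature (`analytic_free_profile`).
* **Exact sampling.** The conditional bath distribution at fixed $q$ is
  Gaussian with mean $c_b q_1$ and variance $k_B T / k_b$, so equilibrium
  "MM" configurations are drawn exactly (`sample_bath`) instead of by MD.
  This removes integrator error from every estimator test; what is lost is
  any test of MD-specific artefacts (autocorrelation, thermostat bias),
  which the package does not attempt to model.

Units are kcal mol^-1^, Å, amu and kelvin throughout, with
$k_B = 1.987204 \times 10^{-3}$ kcal mol^-1^ K^-1^.

# Stationary points and the IRC

`optimize_saddle` / `optimize_minimum` are eigenvector-following Newton
searches: the finite-difference Hessian (central differences, step
$10^{-4}$ Å — the usual accuracy/stability compromise for smooth analytic
surfaces) is diagonalized at each iterate and the step ascends along the
softest mode (saddle search) or descends along all modes, with a 0.3 Å
trust-radius cap. Convergence is a gradient-norm criterion whose default,
1.2 kJ mol^-1^ Å^-1^ = 0.28680 kcal mol^-1^ Å^-1^, is the customary
criterion for QM/MM transition-state refinement. `verify_stationary`
recomputes and diagonalizes the Hessian and accepts a point only if the
count of negative eigenvalues matches its claimed character — exactly one
for a transition state, none for a minimum — with a scale-aware zero
tolerance so numerically flat modes are not miscounted.

One practical consequence of the loose default criterion is worth stating:
on a surface whose curvature scale is of order 1 kcal mol^-1^ Å^-2^, a
point converged only to 0.287 kcal mol^-1^ Å^-1^ can sit several hundredths
of an Å off the true saddle, which is enough to tip both IRC branches into
the same well. IRC tracing therefore starts from a tightly converged saddle
(thresholds of 10^-8^-10^-9^ are cheap on the model system); the default
threshold is kept for the verification contract, not for path tracing.

`trace_irc` displaces $\pm$ a small step along the transition vector (the
Hessian eigenvector of the negative eigenvalue, in mass-weighted
coordinates) and follows damped steepest descent in mass-weighted
coordinates — fixed step, halved whenever a trial step would raise the
energy — until the gradient norm drops below `min_threshold`. Descent in
mass-weighted rather than plain coordinates is a documented choice: the two
coincide for the unit-mass defaults, and for smooth model surfaces either
converges to the same minima.

## The path coordinate *s*

For a structure sequence, the adopted increment is the
total-mass-normalized mass-weighted displacement

$$\Delta s_i = \Big[\sum_j m_j\,(\Delta x_{j,i}^2 + \Delta y_{j,i}^2 +
\Delta z_{j,i}^2)\,/\,m_i\Big]^{1/2}, \qquad m_i = \sum_j m_j,$$

accumulated from $s = 0$ at the first structure. Two algebraic readings of
a mass-weighted path length are defensible (per-atom mass weighting with or
without total-mass normalization); the normalized form was adopted because
it keeps *s* in Å — a rigid translation of the whole region by $d$ gives
$\Delta s = d$, and a single atom of mass $m$ moved by $d$ gives
$d\sqrt{m/M}$ — and the un-normalized amu^1/2^ Å form remains selectable
(`normalization = "none"`). Consecutive structures are *not* superposed
before differencing: IRC output from a fixed-frame optimizer is already
aligned, and silently removing rotations would corrupt genuinely rotating
paths; callers feeding externally aligned trajectories must align first.

# The FEP estimator

The free energy accumulates along the path as

$$\Delta G(s_{i+1}) = \Delta G(s_i) + \Delta E^0_{QM} + \Delta ZPE +
\delta G^{ens}_i,$$

where the ensemble term is, by default, the exponential (Zwanzig) average

$$\delta G^{ens}_i = -k_B T \ln\big\langle e^{-\Delta E_{int}/k_B T}
\big\rangle_i ,$$

computed through a log-sum-exp so any finite sample set yields a finite
increment. The prose description of such estimators — "an average of the
interaction-energy difference" — is ambiguous between exponential and
arithmetic averaging; the exponential form is the default because the
method *is* free-energy perturbation, and the arithmetic mean
(`estimator = "mean"`) is exposed for comparison rather than guessed at
silently. For Gaussian samples the two differ by $\sigma^2 / 2 k_B T$,
which the test suite checks against the closed-form cumulant. Each
increment carries a delta-method standard error
($k_B T\,\mathrm{sd}(w)/(\sqrt{n}\,\bar w)$ on the Boltzmann weights $w$,
computed in shifted space), accumulated in quadrature along the profile;
this is the "3 SE" yardstick of the closure tests. Error bars beyond this
(block bootstrap) are deliberately out of scope.

Zero-point energies enter as supplied per-structure scalars; no frequency
calculation is performed. Temperature defaults to 298 K. Profiles are
anchored at the first (reactant-side) state, and the barrier fields obey
*forward − reverse = ΔG~rxn~* bitwise, not merely algebraically — the
reaction free energy is stored as that difference.

**Window semantics.** `partition_windows` selects `n_windows` *anchor
states* evenly spaced in *s*, always retaining the first and last
structures and the structure of maximal energy (the barrier top must
survive coarsening). "Window" here means a sampled state, matching the
usage "20 ps of sampling for each window extracted from the IRC";
increments live between consecutive anchors, so `n_windows` anchors yield
`n_windows − 1` increments.

# Trajectory analyses

* **Hydrogen bonds.** A contact is satisfied in a frame when the
  donor–acceptor distance is ≤ 3.0 Å *and* the donor–hydrogen–acceptor
  angle, measured at the hydrogen, is ≥ 135°; both cutoffs are arguments.
  Occupancies are reported per block (e.g. frames spanning 50 ns); a
  trailing partial block is reported with its own frame count rather than
  dropped, so no data disappears silently.
* **Distance populations.** Histograms are density-normalized; modes are
  local maxima with topographic prominence ≥ 5% of the highest bin. This
  reproduces a "most frequently visited conformations" reading (a reactive
  ≈ 2.2 Å and a nonreactive ≈ 4.3 Å population, in the motivating system)
  without committing to a mixture fit.
* **RMSD.** Optional least-squares rigid-body superposition by the Kabsch
  algorithm (with the reflection guard on the SVD determinant) precedes the
  deviation; the test suite cross-checks against `bio3d::fit.xyz` as an
  independent oracle.
* **Interaction decomposition.** Per inhibitor site group (P1′, P1, P2,
  P3) and protein residue, $E_{elec} = \sum f q_i q_j / r_{ij}$ with
  $f = 332.0636$ kcal Å mol^-1^ e^-2^ and
  $E_{LJ} = \sum 4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$
  under Lorentz–Berthelot mixing (arithmetic σ, geometric ε). These
  conventions must be stated because published figures rarely print them.
  No cutoff is applied by default — switching radii belong to MD
  propagation, not to the analysis of a finite complex — but a cutoff
  option exists for parity experiments. Means and variances are over all
  analysed frames, and group totals equal the sum of their residue records
  to machine precision (pairwise additivity is a test invariant).

# Kinetics

The two-step irreversible scheme E + I ⇌ E:I → E–I is fitted with the
canonical progress-curve model

$$P(t) = \frac{v_0}{k_{obs}} \big(1 - e^{-k_{obs} t}\big), \qquad
k_{obs}([I]) = \frac{k_{inact} [I]}{K_i^{app} + [I]},$$

the standard form for saturating time-dependent inhibition; assay papers
typically cite protocol references rather than printing these equations, so
the adopted model is documented here. Fitting is two-stage — per-curve
$k_{obs}$ by nonlinear least squares (`minpack.lm::nlsLM`, starts from the
early slope and the initial/final slope ratio), then a weighted hyperbola
across concentrations (weights $1/SE^2$) — which matches common assay
practice and keeps the diagnostics interpretable. When the concentration
ladder never approaches $K_i$ the hyperbola degenerates to a line; the fit
then warns, reports only the second-order efficiency $k_{inact}/K_i$ from
the slope, and flags the individual constants unidentifiable.

Substrate competition ($K_i^{app} = K_i(1 + [S]/K_m)$) is available but
**off** by default: published $K_i$ values often omit whether the
correction was applied, and silently rescaling a reported quantity is
worse than exposing both conventions.

Eyring conversions use $\Delta G^\ddagger = RT \ln(k_B T / h k)$ with unit
transmission coefficient and $k_B T/h = 6.2093 \times 10^{12}$ s^-1^ at
298 K. The default temperature is 298 K rather than 298.15 K: both printed
barrier checks (0.040 s^-1^ → 19.3, 0.00629 s^-1^ → 20.4 kcal mol^-1^)
reproduce at 298 K, and 298.15 K shifts the second by ~0.05. Both are
selectable.

# Synthetic data

The generators define the study conditions the tests run under:

* **Assays.** Eight two-fold dilutions anchored at the top concentration,
  1000 nM down to 7.8 nM, 30 min of monitoring at one reading per 10 s.
  (An assay window quoted as "0.78–1000 nM" cannot be a single two-fold
  series containing 1000; the generator keeps the two-fold ladder anchored
  at 1000 nM as its default design.) Noise is additive Gaussian with
  sd = 2% of the curve's maximum by default (proportional noise is an
  option), and negative readings are clipped at zero. Initial rates are
  attenuated as $v_0/(1 + [I]/K_i)$, the instantaneous-binding limit.
* **Trajectories.** A minimal five-atom fixture — donor/hydrogen/acceptor
  switched between a bonded (2.8 Å, 180°) and broken (4.5 Å) pose, plus a
  probe pair with mixture-distributed distance (defaults 2.2/4.3 Å,
  σ = 0.15 Å, equal weights). Occupancy placement is quota-exact per block
  by default — exact closed-loop tests beat flaky statistical ones — with
  Bernoulli placement as an option. No attempt is made to emulate a real
  protein: the analyses are geometry- and parameter-driven, and realism
  would add no test power. Correspondingly, passing tests demonstrate
  correctness of the analysis operators, not robustness to force-field or
  sampling artefacts of real trajectories.
* **FEP windows.** Bath configurations drawn exactly at each anchor state,
  with interaction-energy differences to the next state; a reverse-sampled
  variant supports Crooks-style consistency checks. All randomness flows
  through explicit integer seeds (window $w$ uses seed + $w$), and the
  generators save and restore the caller's RNG state.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2000 bath samples per
window over 21 anchors for FEP closure; 10^4^ draws for sampling-moment
checks; 10^5^ samples for the Gaussian cumulant check; 200 replicate
assays at 2% noise (8 concentrations × 180 points each) for parameter
recovery; 5000 frames for the bimodal distance fixture. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances while keeping
the whole suite interactive. Ties in mode detection resolve to the
lower-distance bin (the first encountered); degenerate inputs (empty
windows, flat signals, non-stationary points submitted for verification)
raise typed errors rather than returning silently wrong numbers.

# Known limitations

* The model system's bilinear, $q$-independent coupling is exactly what
  makes the analytic oracle available; estimator behaviour under strongly
  anharmonic or $q$-dependent coupling is untested.
* The IRC tracer is a damped steepest-descent follower adequate for smooth
  low-dimensional surfaces; it is not a production Hessian-following
  integrator for rugged landscapes.
* Kinetic fits assume product-proportional signal with no depletion,
  photobleaching or inner-filter effects over the assay window.
* Interaction decomposition is gas-phase pairwise additive: no
  polarization, no reaction-field or lattice-sum electrostatics.
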