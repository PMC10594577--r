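## Stationary-point location, IRC tracing and the mass-weighted path
## coordinate s. The energy function contract throughout: a plain R function
## z -> energy on a flat coordinate vector; derivatives are taken by central
## finite differences (step 1e-4) unless the function is cheap enough not to
## care. Masses may ride along as attr(fn, "masses").

stop_fepkin <- function(class, ...) {
  stop(structure(class = c(class, "fepkin_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# central-difference gradient, default step 1e-4 length units
fd_gradient <- function(f, z, h = 1e-4) {
  vapply(seq_along(z), function(i) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + h; zm[i] <- zm[i] - h
    (f(zp) - f(zm)) / (2 * h)
  }, numeric(1))
}

# central-difference Hessian (symmetric), step 1e-4
fd_hessian <- function(f, z, h = 1e-4) {
  n <- length(z)
  H <- matrix(0, n, n)
  f0 <- f(z)
  for (i in seq_len(n)) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + h; zm[i] <- zm[i] - h
    H[i, i] <- (f(zp) + f(zm) - 2 * f0) / h^2
    if (i < n) for (j in seq((i + 1), n)) {
      zpp <- z; zpm <- z; zmp <- z; zmm <- z
      zpp[c(i, j)] <- zpp[c(i, j)] + h
      zmm[c(i, j)] <- zmm[c(i, j)] - h
      zpm[i] <- zpm[i] + h; zpm[j] <- zpm[j] - h
      zmp[i] <- zmp[i] - h; zmp[j] <- zmp[j] + h
      H[i, j] <- H[j, i] <- (f(zpp) - f(zpm) - f(zmp) + f(zmm)) / (4 * h^2)
    }
  }
  H
}

# count of negative Hessian eigenvalues, with a scale-aware tolerance so that
# numerically-zero modes are not miscounted
count_negative <- function(eig, tol = NULL) {
  if (is.null(tol)) tol <- 1e-6 * max(1, max(abs(eig)))
  sum(eig < -tol)
}

new_stationary_point <- function(coords, energy, gradient_norm, eigenvalues, kind) {
  structure(list(coords = coords, energy = energy,
                 gradient_norm = gradient_norm,
                 eigenvalues = eigenvalues, kind = kind),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("Stationary point (%s): E = %.6g, |grad| = %.3g, %d negative eigenvalue(s)\n",
              x$kind, x$energy, x$gradient_norm,
              count_negative(x$eigenvalues)))
  cat("  coords:", paste(format(x$coords, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

# One eigenvector-following Newton step. mode = "saddle" forces exactly one
# uphill direction (the softest mode); mode = "minimum" forces all-downhill.
ef_step <- function(g, H, mode, max_step) {
  e <- eigen(H, symmetric = TRUE)
  gq <- drop(crossprod(e$vectors, g))
  lam <- e$values
  eff <- lam
  shift <- 0.1 * max(1, max(abs(lam)))
  if (mode == "saddle") {
    soft <- which.min(lam)
    # uphill along the softest mode, downhill along the rest
    eff[soft] <- if (lam[soft] < 0) lam[soft] else -abs(lam[soft]) - shift
    rest <- setdiff(seq_along(lam), soft)
    eff[rest] <- ifelse(lam[rest] > 0, lam[rest], abs(lam[rest]) + shift)
  } else {
    eff <- ifelse(lam > 0, lam, abs(lam) + shift)
  }
  step <- -e$vectors %*% (gq / eff)
  nrm <- sqrt(sum(step^2))
  if (nrm > max_step) step <- step * (max_step / nrm)
  drop(step)
}

optimize_stationary <- function(f, guess, mode, threshold, max_iter, fd_step, max_step) {
  z <- as.numeric(guess)
  for (it in seq_len(max_iter)) {
    g <- fd_gradient(f, z, fd_step)
    if (sqrt(sum(g^2)) <= threshold) {
      H <- fd_hessian(f, z, fd_step)
      eig <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      return(list(coords = z, energy = f(z), gradient_norm = sqrt(sum(g^2)),
                  eigenvalues = eig, iterations = it))
    }
    H <- fd_hessian(f, z, fd_step)
    z <- z + ef_step(g, H, mode, max_step)
  }
  stop_fepkin("fepkin_search_error",
              "stationary-point search did not converge in ", max_iter,
              " iterations (|grad| = ",
              format(sqrt(sum(fd_gradient(f, z, fd_step)^2)), digits = 4), ")")
}

#' Locate a first-order saddle point (transition state)
#'
#' Eigenvector-following Newton search: at each iterate the finite-difference
#' Hessian is diagonalized and the step ascends along the softest mode while
#' descending along all others, so the walk is drawn to an index-1 saddle.
#' Convergence is declared when the gradient norm falls below
#' \code{threshold}; the converged Hessian is then diagonalized and the point
#' is accepted only if it has exactly one negative eigenvalue.
#'
#' @param f energy function (numeric vector -> energy, kcal mol^-1).
#' @param guess starting coordinates.
#' @param threshold gradient-norm convergence criterion in kcal mol^-1 A^-1;
#'   default 1.2 kJ mol^-1 A^-1 converted to kcal units (0.28680).
#' @param max_iter iteration cap; exceeding it raises a search error.
#' @param fd_step finite-difference step (A), central differences.
#' @param max_step trust-radius cap on the Newton step length (A).
#' @return A \code{"stationary_point"} with \code{kind = "saddle"}.
#' @seealso \code{\link{verify_stationary}}, \code{\link{trace_irc}}
#' @export
optimize_saddle <- function(f, guess, threshold = default_gradient_threshold(),
                            max_iter = 200L, fd_step = 1e-4, max_step = 0.3) {
  if (threshold <= 0) stop_fepkin("fepkin_input_error", "threshold must be > 0")
  res <- optimize_stationary(f, guess, "saddle", threshold, max_iter, fd_step, max_step)
  n_neg <- count_negative(res$eigenvalues)
  if (n_neg != 1L)
    stop_fepkin("fepkin_verification_error",
                "converged point has ", n_neg,
                " negative Hessian eigenvalue(s); expected 1")
  new_stationary_point(res$coords, res$energy, res$gradient_norm,
                       res$eigenvalues, "saddle")
}

#' Locate a local minimum
#'
#' All-downhill eigenvector-following Newton search with the same convergence
#' contract as \code{\link{optimize_saddle}}; the converged point must have no
#' negative Hessian eigenvalue.
#'
#' @inheritParams optimize_saddle
#' @return A \code{"stationary_point"} with \code{kind = "minimum"}.
#' @export
optimize_minimum <- function(f, guess, threshold = default_gradient_threshold(),
                             max_iter = 200L, fd_step = 1e-4, max_step = 0.3) {
  if (threshold <= 0) stop_fepkin("fepkin_input_error", "threshold must be > 0")
  res <- optimize_stationary(f, guess, "minimum", threshold, max_iter, fd_step, max_step)
  n_neg <- count_negative(res$eigenvalues)
  if (n_neg != 0L)
    stop_fepkin("fepkin_verification_error",
                "converged point has ", n_neg,
                " negative Hessian eigenvalue(s); expected 0")
  new_stationary_point(res$coords, res$energy, res$gradient_norm,
                       res$eigenvalues, "minimum")
}

#' Verify the character of a stationary point by Hessian diagonalization
#'
#' Computes and diagonalizes the finite-difference Hessian at the supplied
#' point and accepts it only if the number of negative eigenvalues matches
#' the claimed kind: exactly one for a saddle, none for a minimum.
#'
#' @param f energy function.
#' @param point a \code{"stationary_point"} or a bare coordinate vector.
#' @param kind \code{"saddle"} or \code{"minimum"}.
#' @param threshold maximum admissible gradient norm at the point.
#' @param fd_step finite-difference step.
#' @return The verified \code{"stationary_point"} with eigenvalues filled.
#' @export
verify_stationary <- function(f, point, kind = c("saddle", "minimum"),
                              threshold = default_gradient_threshold(),
                              fd_step = 1e-4) {
  kind <- match.arg(kind)
  z <- if (inherits(point, "stationary_point")) point$coords else as.numeric(point)
  g <- fd_gradient(f, z, fd_step)
  gn <- sqrt(sum(g^2))
  if (gn > threshold)
    stop_fepkin("fepkin_input_error",
                "point is not stationary: |grad| = ", format(gn, digits = 4),
                " exceeds threshold ", format(threshold, digits = 4))
  eig <- eigen(fd_hessian(f, z, fd_step), symmetric = TRUE, only.values = TRUE)$values
  n_neg <- count_negative(eig)
  expected <- if (kind == "saddle") 1L else 0L
  if (n_neg != expected)
    stop_fepkin("fepkin_verification_error",
                "found ", n_neg, " negative eigenvalue(s); a ", kind,
                " requires ", expected)
  new_stationary_point(z, f(z), gn, eig, kind)
}

## ---- reaction path container ------------------------------------------

#' Construct a reaction-path structure sequence
#'
#' A path is an ordered sequence of structures. Coordinates are either a
#' matrix with one row per structure (generalized coordinates, one mass per
#' coordinate) or a 3-D array \code{[atom, xyz, structure]} (Cartesian
#' coordinates, one mass per atom). Gas-phase energies and zero-point
#' energies may be attached per structure; the path coordinate \code{s} is
#' filled by \code{\link{compute_s}}.
#'
#' @param coords structure coordinates (matrix \code{n_struct x n_coord} or
#'   array \code{n_atom x 3 x n_struct}).
#' @param masses per-coordinate (matrix form) or per-atom (array form)
#'   masses in amu; all positive.
#' @param energy optional total energies along the path.
#' @param e_qm0 optional gas-phase ("QM") energies per structure.
#' @param zpe optional zero-point energies per structure.
#' @return An object of class \code{"reaction_path"}.
#' @export
reaction_path <- function(coords, masses, energy = NULL, e_qm0 = NULL, zpe = NULL) {
  if (is.array(coords) && length(dim(coords)) == 3L) {
    if (dim(coords)[2] != 3L) stop_fepkin("fepkin_input_error",
                                          "array coordinates must be n_atom x 3 x n_struct")
    n_struct <- dim(coords)[3]
    if (length(masses) != dim(coords)[1])
      stop_fepkin("fepkin_input_error", "need one mass per atom")
  } else {
    coords <- as.matrix(coords)
    n_struct <- nrow(coords)
    if (length(masses) != ncol(coords))
      stop_fepkin("fepkin_input_error", "need one mass per coordinate")
  }
  if (any(masses <= 0)) stop_fepkin("fepkin_input_error", "masses must be positive")
  chk <- function(v, what) {
    if (!is.null(v) && length(v) != n_struct)
      stop_fepkin("fepkin_input_error", what, " must have one value per structure")
    v
  }
  structure(list(coords = coords, masses = as.numeric(masses),
                 energy = chk(energy, "energy"), e_qm0 = chk(e_qm0, "e_qm0"),
                 zpe = chk(zpe, "zpe"), s = NULL, n_struct = n_struct),
            class = "reaction_path")
}

n_structures <- function(path) path$n_struct

# coordinates of structure i as a flat numeric vector
path_coords <- function(path, i) {
  if (is.matrix(path$coords)) path$coords[i, ] else as.numeric(path$coords[, , i])
}

#' @export
print.reaction_path <- function(x, ...) {
  cat("Reaction path:", x$n_struct, "structures,",
      if (is.matrix(x$coords)) ncol(x$coords) else dim(x$coords)[1],
      if (is.matrix(x$coords)) "generalized coordinate(s)\n" else "atom(s)\n")
  if (!is.null(x$s))
    cat(sprintf("  s range [0, %.4g], total mass %.4g amu\n",
                max(x$s), sum(x$masses)))
  if (!is.null(x$energy))
    cat(sprintf("  energy range [%.4g, %.4g] kcal/mol\n",
                min(x$energy), max(x$energy)))
  invisible(x)
}

#' Trace the intrinsic reaction coordinate from a saddle point
#'
#' Starting from a verified saddle, the path is displaced a small amount
#' along +/- the Hessian eigenvector of the negative eigenvalue and then
#' followed downhill by damped steepest descent in mass-weighted coordinates
#' (fixed step, halved whenever a step would raise the energy) until the
#' gradient norm falls below \code{min_threshold}. The two branches are
#' joined into one ordered sequence running minimum -> saddle -> minimum.
#'
#' @param f energy function; per-coordinate masses are taken from
#'   \code{attr(f, "masses")} or the \code{masses} argument (default: unit
#'   masses).
#' @param saddle a \code{"stationary_point"} of kind \code{"saddle"}.
#' @param step steepest-descent step length in mass-weighted coordinates.
#' @param max_steps cap per descending branch; exceeding it without reaching
#'   a minimum raises a tracing error.
#' @param min_threshold gradient norm below which a branch endpoint counts
#'   as a minimum.
#' @param masses optional per-coordinate masses overriding the attribute.
#' @param fd_step finite-difference step for gradients.
#' @return A \code{"reaction_path"} with energies and the \code{s} coordinate
#'   filled (see \code{\link{compute_s}}).
#' @export
trace_irc <- function(f, saddle, step = 0.01, max_steps = 20000L,
                      min_threshold = 1e-5, masses = NULL, fd_step = 1e-4) {
  if (!inherits(saddle, "stationary_point") || saddle$kind != "saddle")
    stop_fepkin("fepkin_input_error", "saddle must be a verified saddle point")
  if (step <= 0) stop_fepkin("fepkin_input_error", "step must be > 0")
  if (is.null(masses)) masses <- attr(f, "masses")
  z0 <- saddle$coords
  if (is.null(masses)) masses <- rep(1, length(z0))
  sqm <- sqrt(masses)

  H <- fd_hessian(f, z0, fd_step)
  # transition vector in mass-weighted coordinates
  Hmw <- H / outer(sqm, sqm)
  e <- eigen(Hmw, symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]

  descend <- function(direction) {
    y <- z0 * sqm + direction * step * v     # mass-weighted coordinates
    branch <- list(y / sqm)
    h <- step
    e_prev <- f(y / sqm)
    for (k in seq_len(max_steps)) {
      z <- y / sqm
      g <- fd_gradient(f, z, fd_step)
      if (sqrt(sum(g^2)) <= min_threshold) return(do.call(rbind, branch))
      gy <- g / sqm
      repeat {
        y_try <- y - h * gy / sqrt(sum(gy^2))
        e_try <- f(y_try / sqm)
        if (e_try <= e_prev || h < 1e-12) break
        h <- h / 2
      }
      y <- y_try
      e_prev <- e_try
      branch[[length(branch) + 1L]] <- y / sqm
      if (h < step) h <- min(step, h * 2)
    }
    stop_fepkin("fepkin_tracing_error",
                "IRC branch did not reach a minimum within ", max_steps, " steps")
  }

  fwd <- descend(+1)
  bwd <- descend(-1)
  coords <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                  matrix(z0, nrow = 1), fwd)
  path <- reaction_path(coords, masses,
                        energy = apply(coords, 1L, f),
                        e_qm0 = apply(coords, 1L, f),
                        zpe = rep(0, nrow(coords)))
  compute_s(path)
}

#' Mass-weighted path coordinate s along a structure sequence
#'
#' The increment between consecutive structures is the total-mass-normalized
#' mass-weighted displacement
#' \deqn{\Delta s_i = \left[\sum_j m_j \left(\Delta x_{j,i}^2 +
#'   \Delta y_{j,i}^2 + \Delta z_{j,i}^2\right) / m_i\right]^{1/2},}
#' where \eqn{m_i = \sum_j m_j} is the total mass of the region, and
#' \eqn{s} is the cumulative sum anchored at 0 for the first structure. With
#' the total-mass normalization \eqn{s} carries length units (Angstrom): a
#' rigid translation of all atoms by \eqn{d} gives \eqn{\Delta s = d}, and a
#' single atom of mass \eqn{m} displaced by \eqn{d} gives
#' \eqn{\Delta s = d\sqrt{m/M}}. The un-normalized mass-weighted form
#' (amu^1/2 Angstrom) is selectable. Structures are used as supplied:
#' consecutive frames are not superposed first, so paths must already share a
#' frame (IRC output from a fixed-frame optimizer does).
#'
#' @param path a \code{"reaction_path"} with at least 2 structures.
#' @param normalization \code{"total_mass"} (default; units of length) or
#'   \code{"none"} (plain mass-weighted length, amu^1/2 Angstrom).
#' @return The path with \code{$s} filled (non-decreasing, \code{s[1] = 0}).
#' @export
compute_s <- function(path, normalization = c("total_mass", "none")) {
  stopifnot(inherits(path, "reaction_path"))
  normalization <- match.arg(normalization)
  n <- path$n_struct
  if (n < 2L) stop_fepkin("fepkin_input_error", "need at least 2 structures")
  total_mass <- sum(if (is.matrix(path$coords)) path$masses else path$masses)
  ds <- vapply(seq_len(n - 1L), function(i) {
    if (is.matrix(path$coords)) {
      d2 <- (path$coords[i + 1L, ] - path$coords[i, ])^2
      w <- sum(path$masses * d2)
    } else {
      d2 <- (path$coords[, , i + 1L] - path$coords[, , i])^2
      w <- sum(path$masses * rowSums(d2))
    }
    if (normalization == "total_mass") sqrt(w / total_mass) else sqrt(w)
  }, numeric(1))
  path$s <- c(0, cumsum(ds))
  path
}

## ---- path I/O ----------------------------------------------------------

#' Read / write reaction paths as multi-model PDB plus a CSV sidecar
#'
#' Cartesian (atomistic) paths are written as a multi-model PDB file via
#' \pkg{bio3d}, one MODEL per structure, with a sidecar CSV holding per
#' structure \code{index}, \code{e_qm0}, \code{zpe} and \code{s}. Masses are
#' not stored in the PDB and must be supplied on reading (topology table).
#'
#' @param path a \code{"reaction_path"} with array (atomistic) coordinates.
#' @param pdb_file multi-model PDB path.
#' @param sidecar_file CSV path for energies and s.
#' @param masses per-atom masses (amu), required by \code{read_path}.
#' @return \code{read_path} returns a \code{"reaction_path"}.
#' @export
write_path <- function(path, pdb_file, sidecar_file) {
  stopifnot(inherits(path, "reaction_path"))
  if (is.matrix(path$coords))
    stop_fepkin("fepkin_input_error",
                "PDB output needs atomistic (n_atom x 3 x n_struct) coordinates")
  n_atom <- dim(path$coords)[1]
  xyz <- t(apply(path$coords, 3L, function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = pdb_file, xyz = xyz,
                   resno = rep(1L, n_atom), resid = rep("QMR", n_atom),
                   elety = paste0("A", seq_len(n_atom)))
  side <- data.frame(index = seq_len(path$n_struct),
                     e_qm0 = if (is.null(path$e_qm0)) NA_real_ else path$e_qm0,
                     zpe = if (is.null(path$zpe)) NA_real_ else path$zpe,
                     s = if (is.null(path$s)) NA_real_ else path$s)
  utils::write.csv(side, sidecar_file, row.names = FALSE)
  invisible(pdb_file)
}

#' @rdname write_path
#' @export
read_path <- function(pdb_file, sidecar_file, masses) {
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE)
  xyz <- pdb$xyz
  n_struct <- nrow(xyz)
  n_atom <- ncol(xyz) / 3L
  coords <- array(0, dim = c(n_atom, 3L, n_struct))
  for (i in seq_len(n_struct))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  side <- utils::read.csv(sidecar_file)
  p <- reaction_path(coords, masses,
                     e_qm0 = side$e_qm0, zpe = side$zpe)
  p$s <- side$s
  p
}
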