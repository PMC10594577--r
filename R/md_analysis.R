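## Trajectory analyses: block-wise hydrogen-bond occupancy, distance
## histograms with mode detection, RMSD with optimal (Kabsch) superposition,
## and per-residue Coulomb + Lennard-Jones interaction-energy decomposition.

#' Bundle trajectory frames with a topology table
#'
#' @param frames coordinate array \code{n_atom x 3 x n_frames} (Angstrom).
#' @param topology data frame with one row per atom and columns \code{name},
#'   \code{resid}, \code{resname}, \code{group} (inhibitor site label such as
#'   "P1", "P1p", "P2", "P3", or "protein"), \code{charge} (e), \code{sigma}
#'   (A), \code{epsilon} (kcal mol^-1).
#' @param frame_dt time spacing between frames (ns); used only for labeling.
#' @return An object of class \code{"trajectory_bundle"}.
#' @export
trajectory_bundle <- function(frames, topology, frame_dt = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[2] != 3L)
    stop_fepkin("fepkin_input_error", "frames must be an n_atom x 3 x n_frames array")
  need <- c("name", "resid", "group")
  if (!all(need %in% names(topology)))
    stop_fepkin("fepkin_input_error", "topology needs columns: ",
                paste(need, collapse = ", "))
  if (dim(frames)[1] != nrow(topology))
    stop_fepkin("fepkin_input_error", "frame atom count (", dim(frames)[1],
                ") must match topology rows (", nrow(topology), ")")
  structure(list(frames = frames, topology = topology, frame_dt = frame_dt,
                 n_atoms = dim(frames)[1], n_frames = dim(frames)[3]),
            class = "trajectory_bundle")
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms,",
      "dt =", x$frame_dt, "ns\n")
  cat("  groups:", paste(unique(x$topology$group), collapse = ", "), "\n")
  invisible(x)
}

# resolve an atom reference (index or topology name) to an index
atom_index <- function(traj, ref) {
  if (is.numeric(ref)) {
    if (ref < 1 || ref > traj$n_atoms)
      stop_fepkin("fepkin_input_error", "atom index ", ref, " out of range")
    return(as.integer(ref))
  }
  i <- which(traj$topology$name == ref)
  if (length(i) != 1L)
    stop_fepkin("fepkin_input_error", "atom '", ref,
                "' matches ", length(i), " topology entries")
  i
}

#' Hydrogen-bond acceptance criteria
#'
#' A frame satisfies a donor-hydrogen-acceptor contact when the
#' donor-acceptor distance is at most \code{dist_cutoff} and the
#' donor-hydrogen-acceptor angle, measured at the hydrogen, is at least
#' \code{angle_cutoff}.
#'
#' @param dist_cutoff donor-acceptor distance cutoff (A), default 3.0.
#' @param angle_cutoff angle cutoff at the hydrogen (degrees), default 135.
#' @param block_size frames per occupancy block (e.g. frames spanning 50 ns);
#'   \code{NULL} treats the whole trajectory as one block.
#' @return An object of class \code{"hbond_criteria"}.
#' @export
hbond_criteria <- function(dist_cutoff = 3.0, angle_cutoff = 135,
                           block_size = NULL) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0 || angle_cutoff > 180)
    stop_fepkin("fepkin_input_error",
                "cutoffs must be positive and the angle at most 180 degrees")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff,
                 block_size = block_size), class = "hbond_criteria")
}

#' Block-wise hydrogen-bond occupancy
#'
#' For every contact and trajectory block, the fraction of frames satisfying
#' both hydrogen-bond criteria. Blocks tile the trajectory in order; a final
#' partial block is reported with its own (smaller) frame count rather than
#' dropped.
#'
#' @param traj a \code{\link{trajectory_bundle}}.
#' @param contacts data frame with columns \code{donor}, \code{hydrogen},
#'   \code{acceptor} (atom indices or topology names) and optionally
#'   \code{id}.
#' @param criteria a \code{\link{hbond_criteria}}.
#' @return Data frame with one row per contact x block: \code{contact},
#'   \code{block}, \code{occupancy} in [0, 1], \code{n_frames}.
#' @export
hbond_occupancy <- function(traj, contacts, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory_bundle"),
            inherits(criteria, "hbond_criteria"))
  bs <- if (is.null(criteria$block_size)) traj$n_frames else criteria$block_size
  block_of <- ceiling(seq_len(traj$n_frames) / bs)
  out <- lapply(seq_len(nrow(contacts)), function(ci) {
    d <- atom_index(traj, contacts$donor[ci])
    h <- atom_index(traj, contacts$hydrogen[ci])
    a <- atom_index(traj, contacts$acceptor[ci])
    ok <- vapply(seq_len(traj$n_frames), function(f) {
      xyz <- traj$frames[, , f]
      rda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      rda <= criteria$dist_cutoff && ang >= criteria$angle_cutoff
    }, logical(1))
    occ <- tapply(ok, block_of, mean)
    nfr <- tapply(ok, block_of, length)
    id <- if ("id" %in% names(contacts)) contacts$id[ci]
    else paste(contacts$donor[ci], contacts$hydrogen[ci],
               contacts$acceptor[ci], sep = "-")
    data.frame(contact = id, block = as.integer(names(occ)),
               occupancy = as.numeric(occ), n_frames = as.integer(nfr))
  })
  do.call(rbind, out)
}

#' Reshape occupancy results into a contact x block heat-map table
#'
#' @param occupancy output of \code{\link{hbond_occupancy}}.
#' @param file optional CSV path; written when supplied.
#' @return Wide data frame, contacts as rows, blocks as columns.
#' @export
occupancy_table <- function(occupancy, file = NULL) {
  wide <- stats::reshape(occupancy[, c("contact", "block", "occupancy")],
                         idvar = "contact", timevar = "block",
                         direction = "wide")
  names(wide) <- sub("^occupancy\\.", "block_", names(wide))
  rownames(wide) <- NULL
  if (!is.null(file)) utils::write.csv(wide, file, row.names = FALSE)
  wide
}

# peak prominence on a density vector: height above the highest saddle
# separating the peak from higher terrain
peak_prominence <- function(dens, i) {
  h <- dens[i]
  side_min <- function(idx) {
    if (!length(idx)) return(NA_real_)   # no terrain on this side
    m <- Inf; best <- NA_real_
    for (j in idx) {
      m <- min(m, dens[j])
      if (dens[j] > h) { best <- m; break }
    }
    best                                  # NA when no higher peak that side
  }
  l <- side_min(rev(seq_len(i - 1)))
  r <- side_min(seq(i + 1, length.out = length(dens) - i))
  saddles <- c(l, r)
  if (all(is.na(saddles))) h               # no higher peak anywhere
  else h - max(saddles, na.rm = TRUE)
}

#' Distance distribution between an atom pair, with mode detection
#'
#' Normalized histogram of the pairwise distance over all frames. Modes are
#' local maxima of the histogram whose prominence exceeds 5% of the global
#' maximum, which picks out the most frequently visited conformations (e.g.
#' a reactive ~2.2 A and a nonreactive ~4.3 A population) without curve
#' fitting.
#'
#' @param traj a \code{\link{trajectory_bundle}} with >= 1 frame.
#' @param pair length-2 vector of atom indices or names.
#' @param bin_width histogram bin width (A).
#' @param min_prominence mode prominence threshold as a fraction of the
#'   highest bin (default 0.05).
#' @return An object of class \code{"distance_histogram"}: \code{breaks},
#'   \code{mids}, \code{density} (integrates to 1), \code{counts},
#'   \code{modes} (distances at modal bins) and the raw \code{distances}.
#' @export
distance_histogram <- function(traj, pair, bin_width = 0.1,
                               min_prominence = 0.05) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  if (traj$n_frames < 1L) stop_fepkin("fepkin_input_error", "no frames")
  if (bin_width <= 0) stop_fepkin("fepkin_input_error", "bin width must be > 0")
  i <- atom_index(traj, pair[[1]]); j <- atom_index(traj, pair[[2]])
  d <- vapply(seq_len(traj$n_frames), function(f)
    sqrt(sum((traj$frames[i, , f] - traj$frames[j, , f])^2)), numeric(1))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- max(ceiling(max(d) / bin_width) * bin_width, lo + bin_width)
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  dens <- h$density
  is_max <- vapply(seq_along(dens), function(k) {
    left <- if (k == 1) -Inf else dens[k - 1]
    right <- if (k == length(dens)) -Inf else dens[k + 1]
    dens[k] > 0 && dens[k] >= left && dens[k] >= right &&
      (dens[k] > left || dens[k] > right || length(dens) == 1L)
  }, logical(1))
  peaks <- which(is_max)
  keep <- peaks[vapply(peaks, function(k)
    peak_prominence(dens, k) >= min_prominence * max(dens), logical(1))]
  structure(list(breaks = h$breaks, mids = h$mids, density = dens,
                 counts = h$counts, modes = h$mids[keep],
                 bin_width = bin_width, distances = d),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("Distance histogram: %d frames, bin %.3g A, modes at %s A\n",
              length(x$distances), x$bin_width,
              paste(format(x$modes, digits = 3), collapse = ", ")))
  invisible(x)
}

# Kabsch: optimal rotation (and translation) of moving onto target
kabsch_superpose <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(A %*% R, 2, ct, FUN = "+")
}

#' RMSD time series against a reference frame
#'
#' Root-mean-square deviation of a selection, frame by frame, against a
#' reference frame, with optional least-squares rigid-body superposition
#' (Kabsch algorithm) before each comparison.
#'
#' @param traj a \code{\link{trajectory_bundle}}.
#' @param selection atom indices or names (default: all atoms).
#' @param reference reference frame index (default 1).
#' @param superpose remove the optimal rigid-body motion first (default
#'   TRUE).
#' @return Numeric vector of per-frame RMSD values (A).
#' @export
rmsd_series <- function(traj, selection = NULL, reference = 1L,
                        superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  sel <- if (is.null(selection)) seq_len(traj$n_atoms)
  else vapply(selection, function(a) atom_index(traj, a), integer(1))
  if (length(sel) == 0L) stop_fepkin("fepkin_input_error", "empty selection")
  ref <- traj$frames[sel, , reference, drop = FALSE][, , 1]
  if (length(sel) == 1L) ref <- matrix(ref, ncol = 3)
  vapply(seq_len(traj$n_frames), function(f) {
    cur <- traj$frames[sel, , f, drop = FALSE][, , 1]
    if (length(sel) == 1L) cur <- matrix(cur, ncol = 3)
    if (superpose && length(sel) >= 3L) cur <- kabsch_superpose(cur, ref)
    sqrt(mean(rowSums((cur - ref)^2)))
  }, numeric(1))
}

#' Per-residue Coulomb + Lennard-Jones interaction-energy decomposition
#'
#' For each inhibitor site group and each protein residue, the pairwise
#' nonbonded energy summed over all atom pairs and averaged over frames:
#' \deqn{E_{elec} = \sum f\, q_i q_j / r_{ij}, \qquad
#'   E_{LJ} = \sum 4\epsilon_{ij}\left[(\sigma_{ij}/r)^{12} -
#'   (\sigma_{ij}/r)^{6}\right],}
#' with \eqn{f = 332.0636} kcal A mol^-1 e^-2 and Lorentz-Berthelot mixing
#' (arithmetic \eqn{\sigma}, geometric \eqn{\epsilon}). No cutoff is applied
#' by default (finite analysis system); an optional cutoff is available for
#' parity experiments.
#'
#' @param traj a \code{\link{trajectory_bundle}} whose topology carries
#'   \code{charge}, \code{sigma}, \code{epsilon} for every involved atom.
#' @param groups inhibitor group labels to analyse (default: every
#'   non-"protein" group present).
#' @param residues protein residue ids (default: all residues whose atoms
#'   are labeled "protein").
#' @param cutoff optional pair-distance cutoff (A); pairs beyond it
#'   contribute zero.
#' @return Data frame with one row per residue x group: \code{residue},
#'   \code{group}, \code{e_elec}, \code{e_lj}, \code{mean}
#'   (= e_elec + e_lj), \code{variance} of the per-frame totals.
#' @export
interaction_decomposition <- function(traj, groups = NULL, residues = NULL,
                                      cutoff = NULL) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  top <- traj$topology
  need <- c("charge", "sigma", "epsilon")
  if (!all(need %in% names(top)))
    stop_fepkin("fepkin_input_error", "topology lacks columns: ",
                paste(setdiff(need, names(top)), collapse = ", "))
  if (is.null(groups))
    groups <- setdiff(unique(top$group), "protein")
  if (is.null(residues))
    residues <- unique(top$resid[top$group == "protein"])
  bad <- which(!stats::complete.cases(top[, need]))
  out <- list()
  for (g in groups) {
    gi <- which(top$group == g)
    if (!length(gi)) stop_fepkin("fepkin_input_error", "no atoms in group ", g)
    for (r in residues) {
      ri <- which(top$resid == r & top$group == "protein")
      if (!length(ri)) stop_fepkin("fepkin_input_error", "no atoms in residue ", r)
      inv <- intersect(c(gi, ri), bad)
      if (length(inv))
        stop_fepkin("fepkin_input_error", "missing charge/LJ parameters for atom(s): ",
                    paste(top$name[inv], collapse = ", "))
      qq <- outer(top$charge[gi], top$charge[ri]) * fepkin_constants$f_elec
      sij <- outer(top$sigma[gi], top$sigma[ri], `+`) / 2
      eij <- sqrt(outer(top$epsilon[gi], top$epsilon[ri]))
      per_frame <- vapply(seq_len(traj$n_frames), function(f) {
        dx <- outer(traj$frames[gi, 1, f], traj$frames[ri, 1, f], `-`)
        dy <- outer(traj$frames[gi, 2, f], traj$frames[ri, 2, f], `-`)
        dz <- outer(traj$frames[gi, 3, f], traj$frames[ri, 3, f], `-`)
        rij <- sqrt(dx^2 + dy^2 + dz^2)
        mask <- if (is.null(cutoff)) 1 else (rij <= cutoff) * 1
        sr6 <- (sij / rij)^6
        c(sum(qq / rij * mask), sum(4 * eij * (sr6^2 - sr6) * mask))
      }, numeric(2))
      tot <- colSums(per_frame)  # per-frame elec + LJ
      out[[length(out) + 1L]] <- data.frame(
        residue = r, group = g,
        e_elec = mean(per_frame[1, ]), e_lj = mean(per_frame[2, ]),
        mean = mean(tot), variance = if (traj$n_frames > 1) stats::var(tot) else 0)
    }
  }
  do.call(rbind, out)
}

## ---- trajectory I/O ----------------------------------------------------

#' Read / write a trajectory bundle (multi-model PDB + topology CSV)
#'
#' Frames go to a multi-model PDB file (one MODEL per frame, via
#' \pkg{bio3d}); the topology travels as a CSV sidecar with columns
#' \code{name}, \code{resid}, \code{resname}, \code{group}, \code{charge},
#' \code{sigma}, \code{epsilon}.
#'
#' @param traj a \code{\link{trajectory_bundle}}.
#' @param pdb_file multi-model PDB path.
#' @param topology_file CSV sidecar path.
#' @param frame_dt frame spacing (ns) assigned on reading.
#' @return \code{read_trajectory} returns a \code{trajectory_bundle}.
#' @export
write_trajectory <- function(traj, pdb_file, topology_file) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  xyz <- t(apply(traj$frames, 3L, function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = pdb_file, xyz = xyz,
                   resno = traj$topology$resid,
                   resid = if ("resname" %in% names(traj$topology))
                     traj$topology$resname else rep("MOL", traj$n_atoms),
                   elety = traj$topology$name)
  utils::write.csv(traj$topology, topology_file, row.names = FALSE)
  invisible(pdb_file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(pdb_file, topology_file, frame_dt = 1) {
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  n_atom <- ncol(xyz) / 3L
  frames <- array(0, dim = c(n_atom, 3L, n_frames))
  for (f in seq_len(n_frames))
    frames[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory_bundle(frames, utils::read.csv(topology_file), frame_dt)
}
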