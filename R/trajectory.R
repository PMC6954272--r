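#' Trajectory container
#'
#' A fixed-topology series of coordinate frames with an (informational)
#' frame interval.
#'
#' @param topology a `Structure`.
#' @param frames list of N x 3 coordinate matrices.
#' @param frame_interval time per frame (arbitrary units, metadata only).
#' @export
new_trajectory <- function(topology, frames, frame_interval = 1) {
  stopifnot(inherits(topology, "Structure"), is.list(frames),
            length(frames) >= 1L)
  na <- n_atoms(topology)
  for (f in frames) stopifnot(is.matrix(f), nrow(f) == na, ncol(f) == 3L)
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames over %d atoms\n",
              length(x$frames), n_atoms(x$topology)))
  invisible(x)
}

#' Read a multi-model PDB file as a Trajectory
#' @param path path to a multi-model PDB file.
#' @param frame_interval time per frame (metadata).
#' @export
read_trajectory_pdb <- function(path, frame_interval = 1) {
  s <- read_pdb(path)
  topo <- new_structure(s$atoms, s$models[1L])
  new_trajectory(topo, s$models, frame_interval)
}

#' Salt-bridge persistence parameters
#'
#' A contact is counted in a frame when the distance between the
#' designated outermost side-chain carbon atoms of an acidic and a basic
#' residue is strictly below `distance_cutoff`; the pair is persistent
#' when its occupancy strictly exceeds `occupancy_fraction` of the
#' frames.
#'
#' @param distance_cutoff contact distance in angstrom (default 7.0).
#' @param occupancy_fraction persistence threshold as a fraction of
#'   frames, in (0, 1); default 1/3, compared strictly.
#' @param outer_atom named character vector mapping residue names to
#'   their designated outermost side-chain carbon.
#' @export
salt_bridge_params <- function(distance_cutoff = 7.0,
                               occupancy_fraction = 1 / 3,
                               outer_atom = c(ASP = "CG", GLU = "CD",
                                              ARG = "CZ", LYS = "CE",
                                              HIS = "CE1")) {
  stopifnot(distance_cutoff > 0, occupancy_fraction > 0,
            occupancy_fraction < 1)
  structure(list(distance_cutoff = distance_cutoff,
                 occupancy_fraction = occupancy_fraction,
                 outer_atom = outer_atom,
                 acidic = c("ASP", "GLU"),
                 basic = c("ARG", "LYS", "HIS")),
            class = "SaltBridgeParams")
}

#' Salt-bridge occupancy over a trajectory
#'
#' For every acidic x basic residue pair across the two groups, computes
#' the fraction of frames in which the designated outermost side-chain
#' carbon atoms are closer than the cutoff, and flags pairs whose
#' occupancy strictly exceeds the persistence fraction.
#'
#' @param t a `Trajectory`.
#' @param p a [salt_bridge_params()] object.
#' @param group_a,group_b residue selections (`SelectionSpec`); acidic
#'   residues are taken from either group and paired with basic residues
#'   of the other.  Defaults pair all acidic with all basic residues.
#' @return a `ContactReport` data frame with columns `acidic_resno`,
#'   `acidic_chain`, `basic_resno`, `basic_chain`, `occupancy`,
#'   `mean_distance`, `persistent`.
#' @export
salt_bridge_occupancy <- function(t, p = salt_bridge_params(),
                                  group_a = selection(),
                                  group_b = selection()) {
  a <- t$topology$atoms
  ia <- select_atoms(t$topology, group_a)
  ib <- select_atoms(t$topology, group_b)
  resat <- function(idx, classes) {
    keep <- idx[a$resname[idx] %in% classes]
    res <- unique(data.frame(chain = a$chain[keep], resno = a$resno[keep],
                             resname = a$resname[keep]))
    if (!nrow(res)) return(res)
    res$atom <- NA_integer_
    for (i in seq_len(nrow(res))) {
      want <- p$outer_atom[[res$resname[i]]]
      j <- which(a$chain == res$chain[i] & a$resno == res$resno[i] &
                   a$name == want)
      if (length(j) == 1L) res$atom[i] <- j
      else warning(sprintf("residue %s%d %s: designated atom %s %s; skipped",
                           res$chain[i], res$resno[i], res$resname[i], want,
                           if (length(j)) "duplicated" else "missing"))
    }
    res[!is.na(res$atom), , drop = FALSE]
  }
  acidic <- unique(rbind(resat(ia, p$acidic), resat(ib, p$acidic)))
  basic <- unique(rbind(resat(ia, p$basic), resat(ib, p$basic)))
  if (!nrow(acidic) || !nrow(basic))
    stop("need at least one acidic and one basic residue with the ",
         "designated atoms present")
  nf <- length(t$frames)
  rows <- list()
  for (i in seq_len(nrow(acidic))) {
    for (j in seq_len(nrow(basic))) {
      d <- vapply(t$frames, function(x)
        sqrt(sum((x[acidic$atom[i], ] - x[basic$atom[j], ])^2)),
        numeric(1))
      occ <- sum(d < p$distance_cutoff) / nf
      rows[[length(rows) + 1L]] <- data.frame(
        acidic_resno = acidic$resno[i], acidic_chain = acidic$chain[i],
        basic_resno = basic$resno[j], basic_chain = basic$chain[j],
        occupancy = occ, mean_distance = mean(d),
        persistent = occ > p$occupancy_fraction)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ContactReport", "data.frame")
  out
}

#' Center-of-mass drift of a selection along a trajectory
#'
#' Superposes each frame onto the first frame on the alignment selection
#' (Kabsch, proper rotations), then reports the mass-weighted centroid
#' displacement of the analysis selection relative to frame 1, optionally
#' projected on an asymmetry axis.
#'
#' @param t a `Trajectory`.
#' @param sel analysis selection.
#' @param align_to alignment selection (>= 3 atoms).
#' @param axis optional length-3 vector; adds a `projection` column with
#'   the signed displacement along the normalized axis.
#' @return data frame with columns `frame`, `dx`, `dy`, `dz`,
#'   `displacement` and optionally `projection` (angstrom).
#' @export
com_drift <- function(t, sel, align_to, axis = NULL) {
  isel <- select_atoms(t$topology, sel)
  iali <- select_atoms(t$topology, align_to)
  if (!length(isel) || !length(iali)) stop("empty selection")
  mass <- atomic_masses[t$topology$atoms$element[isel]]
  mass[is.na(mass)] <- 12.011
  ref <- t$frames[[1L]][iali, , drop = FALSE]
  com <- function(x) colSums(x[isel, , drop = FALSE] * mass) / sum(mass)
  com0 <- com(t$frames[[1L]])
  disp <- t(vapply(t$frames, function(x) {
    tr <- kabsch_transform(ref, x[iali, , drop = FALSE])
    com(apply_transform(x, tr)) - com0
  }, numeric(3)))
  out <- data.frame(frame = seq_along(t$frames), dx = disp[, 1],
                    dy = disp[, 2], dz = disp[, 3],
                    displacement = sqrt(rowSums(disp^2)))
  if (!is.null(axis)) {
    u <- axis / sqrt(sum(axis^2))
    out$projection <- as.vector(disp %*% u)
  }
  out
}

#' Distance between two site centroids
#'
#' @param s a `Structure`.
#' @param site_a,site_b non-empty atom selections.
#' @param model model index.
#' @return Euclidean distance between the selection centroids (angstrom).
#' @export
site_separation <- function(s, site_a, site_b, model = 1L) {
  sqrt(sum((centroid(s, site_a, model) - centroid(s, site_b, model))^2))
}

#' Hexagonal lattice constant from the intra-unit trimer separation
#'
#' Trimers-of-dimers occupy the vertices of a honeycomb whose edge length
#' is the separation between the two trimers of one core unit; the
#' hexagonal lattice constant (vertex-lattice spacing) is then
#' `sqrt(3)` times that edge.
#'
#' @param tod_separation trimer-trimer separation (any length unit).
#' @return lattice constant in the same unit.
#' @export
hex_lattice_constant <- function(tod_separation) {
  if (any(tod_separation <= 0)) stop("separation must be positive")
  sqrt(3) * tod_separation
}
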