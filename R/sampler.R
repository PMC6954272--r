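#' Conformational ensemble container
#'
#' An `Ensemble` is an ordered collection of coordinate frames sharing one
#' topology, with per-frame metadata (annealing step, energy, accepted flag,
#' closure distance once filtered) and, when produced by the hinge sampler,
#' the dihedral increments that generated each frame.
#'
#' @param topology a `Structure` (single model used as reference).
#' @param frames list of N x 3 coordinate matrices.
#' @param meta data frame with one row per frame (columns `frame`, `step`,
#'   `energy`, `accepted`, `closure_distance`).
#' @param dihedrals optional frames x k matrix of dihedral increments
#'   (degrees) relative to the topology.
#' @return an object of class `Ensemble`.
#' @export
new_ensemble <- function(topology, frames, meta = NULL, dihedrals = NULL) {
  stopifnot(inherits(topology, "Structure"), is.list(frames))
  n <- length(frames)
  na <- n_atoms(topology)
  for (f in frames)
    stopifnot(is.matrix(f), nrow(f) == na, ncol(f) == 3L)
  if (is.null(meta))
    meta <- data.frame(frame = seq_len(n), step = NA_integer_,
                       energy = NA_real_, accepted = NA,
                       closure_distance = NA_real_)
  if (nrow(meta) != n)
    stop("metadata row count (", nrow(meta),
         ") does not match frame count (", n, ")")
  meta$frame <- seq_len(n)
  if (!is.null(dihedrals)) stopifnot(nrow(dihedrals) == n)
  structure(list(topology = topology, frames = frames, meta = meta,
                 dihedrals = dihedrals), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d frames over %d atoms\n",
              n_frames(x), n_atoms(x$topology)))
  invisible(x)
}

#' @rdname new_ensemble
#' @param e an `Ensemble`.
#' @export
n_frames <- function(e) length(e$frames)

#' Subset an Ensemble by frame index
#' @param e an `Ensemble`.
#' @param idx frame indices to keep.
#' @export
subset_ensemble <- function(e, idx) {
  new_ensemble(e$topology, e$frames[idx], e$meta[idx, , drop = FALSE],
               if (!is.null(e$dihedrals)) e$dihedrals[idx, , drop = FALSE])
}

#' Convert an Ensemble to a multi-model Structure
#' @param e an `Ensemble`.
#' @export
ensemble_to_structure <- function(e) {
  new_structure(e$topology$atoms, e$frames)
}

# default van der Waals radii (angstrom) by element
default_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80)

#' Soft-sphere clash parameters
#'
#' Purely repulsive steric energy used during hinge sampling: each
#' cross-pair closer than the sum of its van der Waals radii contributes
#' `scale * (1 - d / (r_i + r_j))^exponent`; pairs at or beyond contact
#' contribute nothing.  Pairs of atoms from residues within
#' `exclude_window` sequence positions on the same chain are excluded
#' (covers bonded and 1-3 neighbours across the segment boundary).
#'
#' @param vdw named numeric vector of per-element radii in angstrom.
#' @param exponent softness exponent (>= 1).
#' @param scale energy scale per pair.
#' @param exclude_window sequence-separation exclusion window (residues).
#' @export
clash_params <- function(vdw = default_vdw, exponent = 2, scale = 1,
                         exclude_window = 1L) {
  stopifnot(all(vdw > 0), exponent >= 1, scale > 0)
  structure(list(vdw = vdw, exponent = exponent, scale = scale,
                 exclude_window = as.integer(exclude_window)),
            class = "ClashParams")
}

#' Soft-sphere clash energy between two selections
#'
#' @param s a `Structure`.
#' @param mobile,static disjoint atom selections (`SelectionSpec` or index
#'   vectors).
#' @param p a [clash_params()] object.
#' @param model model index.
#' @param xyz optional coordinate matrix overriding the stored model
#'   (fast path for samplers).
#' @return total repulsive energy (>= 0); 0 with a warning when either
#'   selection is empty.
#' @export
clash_energy <- function(s, mobile, static, p = clash_params(),
                         model = 1L, xyz = NULL) {
  mi <- select_atoms(s, mobile)
  si <- select_atoms(s, static)
  if (!length(mi) || !length(si)) {
    warning("empty selection; clash energy is 0")
    return(0)
  }
  if (length(intersect(mi, si))) stop("selections are not disjoint")
  if (is.null(xyz)) xyz <- get_xyz(s, model)
  a <- s$atoms
  rm_ <- p$vdw[a$element[mi]]
  rs_ <- p$vdw[a$element[si]]
  rm_[is.na(rm_)] <- 1.7
  rs_[is.na(rs_)] <- 1.7
  xm <- xyz[mi, , drop = FALSE]
  xs <- xyz[si, , drop = FALSE]
  # pairwise distances: |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(xm^2), rowSums(xs^2), "+") - 2 * tcrossprod(xm, xs)
  d <- sqrt(pmax(d2, 0))
  rsum <- outer(rm_, rs_, "+")
  # sequence-neighbour exclusion on the same chain
  if (p$exclude_window >= 0L) {
    same_chain <- outer(a$chain[mi], a$chain[si], "==")
    close_seq <- abs(outer(a$resno[mi], a$resno[si], "-")) <= p$exclude_window
    rsum[same_chain & close_seq] <- 0
  }
  overlap <- pmax(1 - d / rsum, 0)
  overlap[rsum == 0] <- 0
  p$scale * sum(overlap^p$exponent)
}

#' Annealed hinge-sampler parameters
#'
#' @param n_steps number of Monte Carlo steps (>= 1).
#' @param initial_temperature,final_temperature temperatures in energy
#'   units (> 0).
#' @param schedule `"geometric"` (default) or `"gsa-visiting"`, a
#'   Tsallis-style generalized-annealing temperature law.
#' @param proposal_width standard deviation (degrees) of the per-step
#'   Gaussian perturbation applied independently to every sampled dihedral.
#' @param visiting_shape,acceptance_shape dimensionless shape parameters of
#'   the generalized schedule (ignored by `"geometric"`); defaults follow
#'   common biomolecular generalized-annealing practice.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param initial_deltas optional starting dihedral increments (degrees).
#' @export
sampler_params <- function(n_steps = 2000L, initial_temperature = 2,
                           final_temperature = 0.01,
                           schedule = c("geometric", "gsa-visiting"),
                           proposal_width = 8,
                           visiting_shape = 2.62, acceptance_shape = -5,
                           seed = 1L, initial_deltas = NULL) {
  schedule <- match.arg(schedule)
  if (n_steps < 1L) stop("parameter error: n_steps must be >= 1")
  stopifnot(initial_temperature > 0, final_temperature > 0,
            proposal_width > 0)
  structure(list(n_steps = as.integer(n_steps),
                 initial_temperature = initial_temperature,
                 final_temperature = final_temperature,
                 schedule = schedule, proposal_width = proposal_width,
                 visiting_shape = visiting_shape,
                 acceptance_shape = acceptance_shape,
                 seed = as.integer(seed),
                 initial_deltas = initial_deltas),
            class = "SamplerParams")
}

# temperature at step t (1-based) of n
schedule_temperature <- function(sp, t, n) {
  if (sp$schedule == "geometric") {
    if (n == 1L) return(sp$initial_temperature)
    sp$initial_temperature *
      (sp$final_temperature / sp$initial_temperature)^((t - 1) / (n - 1))
  } else {
    qv <- sp$visiting_shape
    # Tsallis visiting-temperature law, floored at final_temperature
    tv <- sp$initial_temperature * (2^(qv - 1) - 1) /
      ((1 + t)^(qv - 1) - 1)
    max(tv, sp$final_temperature)
  }
}

# acceptance probability for an energy increase dE > 0 at temperature T
acceptance_prob <- function(sp, dE, temp) {
  if (dE <= 0) return(1)
  if (sp$schedule == "geometric" || sp$acceptance_shape == 1) {
    exp(-dE / temp)
  } else {
    qa <- sp$acceptance_shape
    base <- 1 - (1 - qa) * dE / temp
    if (base <= 0) 0 else base^(1 / (1 - qa))
  }
}

#' Annealed Monte Carlo sampling of hinge dihedrals
#'
#' Runs a Metropolis-style annealing chain in the space of sampled hinge
#' dihedral increments.  At each step all sampled dihedrals are perturbed
#' by independent Gaussian noise (wrapped to (-180, 180] degrees), the
#' structure is rebuilt by rigid-body rotation from the starting model, and
#' the move is accepted by the configured annealing rule applied to the
#' soft-sphere clash energy between the mobile domain and the static
#' scaffold.  Hinge residues are excluded from the energy, mirroring
#' side-chain removal at the hinge during sampling.  Every accepted state
#' (including the initial state, step 0) is recorded.
#'
#' @param s a `Structure` (model 1 is the starting conformation).
#' @param h a `HingeSpec`.
#' @param sp a [sampler_params()] object.
#' @param cp a [clash_params()] object.
#' @return an `Ensemble` of accepted states, with an `acceptance_rate`
#'   attribute.
#' @export
sample_hinge <- function(s, h, sp = sampler_params(), cp = clash_params()) {
  stopifnot(inherits(s, "Structure"), inherits(h, "HingeSpec"),
            inherits(sp, "SamplerParams"))
  a <- s$atoms
  in_chain <- a$chain == h$chain
  mobile_idx <- which(in_chain & a$resno %in% h$mobile_residues)
  hinge_idx <- which(in_chain & a$resno %in% h$hinge_residues)
  static_idx <- setdiff(seq_len(n_atoms(s)), c(mobile_idx, hinge_idx))
  k <- nrow(h$sampled_dihedrals)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(sp$seed)

  energy_of <- function(delta) {
    st <- apply_hinge_rotation(s, h, delta)
    list(xyz = get_xyz(st),
         e = clash_energy(s, mobile_idx, static_idx, cp,
                          xyz = get_xyz(st)))
  }

  delta <- if (is.null(sp$initial_deltas)) rep(0, k) else
    wrap_angle(sp$initial_deltas)
  cur <- energy_of(delta)
  frames <- vector("list", sp$n_steps + 1L)
  deltas_rec <- matrix(NA_real_, sp$n_steps + 1L, k)
  steps <- integer(sp$n_steps + 1L)
  energies <- numeric(sp$n_steps + 1L)
  frames[[1L]] <- cur$xyz
  deltas_rec[1L, ] <- delta
  energies[1L] <- cur$e
  nrec <- 1L
  n_acc <- 0L

  for (t in seq_len(sp$n_steps)) {
    temp <- schedule_temperature(sp, t, sp$n_steps)
    prop <- wrap_angle(delta + stats::rnorm(k, 0, sp$proposal_width))
    cand <- energy_of(prop)
    if (stats::runif(1) < acceptance_prob(sp, cand$e - cur$e, temp)) {
      delta <- prop
      cur <- cand
      n_acc <- n_acc + 1L
      nrec <- nrec + 1L
      frames[[nrec]] <- cur$xyz
      deltas_rec[nrec, ] <- delta
      steps[nrec] <- t
      energies[nrec] <- cur$e
    }
  }
  meta <- data.frame(frame = seq_len(nrec), step = steps[seq_len(nrec)],
                     energy = energies[seq_len(nrec)], accepted = TRUE,
                     closure_distance = NA_real_)
  e <- new_ensemble(s, frames[seq_len(nrec)], meta,
                    deltas_rec[seq_len(nrec), , drop = FALSE])
  attr(e, "acceptance_rate") <- n_acc / sp$n_steps
  attr(e, "static_idx") <- static_idx
  attr(e, "mobile_idx") <- mobile_idx
  e
}

#' Loop-closure filter parameters
#'
#' @param anchor_a,anchor_b atom selections flanking the severed linker
#'   (e.g. the mobile domain's C-terminal attachment and the static
#'   scaffold's N-terminal attachment).
#' @param max_distance maximum allowed distance (angstrom) between anchor
#'   centroids; default 18, the span of the four removed loop residues.
#' @export
closure_filter_params <- function(anchor_a, anchor_b, max_distance = 18) {
  stopifnot(max_distance > 0)
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 max_distance = max_distance),
            class = "ClosureFilterParams")
}

#' Closure filter: reject frames whose anchor gap is unbridgeable
#'
#' Retains exactly the frames whose anchor-centroid distance is less than
#' or equal to `max_distance`; the surviving frames' metadata records the
#' measured distance.
#'
#' @param e an `Ensemble`.
#' @param f a [closure_filter_params()] object.
#' @return the filtered `Ensemble`, with attribute `n_rejected`.
#' @export
closure_filter <- function(e, f) {
  ia <- select_atoms(e$topology, f$anchor_a)
  ib <- select_atoms(e$topology, f$anchor_b)
  if (!length(ia) || !length(ib))
    stop("selection error: closure anchor resolves to no atoms")
  d <- vapply(e$frames, function(x) {
    ca <- colMeans(x[ia, , drop = FALSE])
    cb <- colMeans(x[ib, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  keep <- which(d <= f$max_distance)
  e$meta$closure_distance <- d
  out <- subset_ensemble(e, keep)
  attr(out, "n_rejected") <- n_frames(e) - length(keep)
  out
}

#' Two-round seeded hinge sampling
#'
#' Reproduces the seed-and-expand annealing protocol: an initial chain is
#' run, `n_seeds` well-separated conformations are chosen from it by greedy
#' maximin selection on pairwise mobile-domain C-alpha RMSD (starting from
#' the lowest-energy frame), and a second chain is started from each seed.
#' The resulting frames are concatenated and deduplicated by exact
#' coordinate equality.
#'
#' @inheritParams sample_hinge
#' @param n_seeds number of second-round starting conformations (>= 1).
#' @return the combined `Ensemble`; attribute `round_sizes` records the
#'   per-chain recorded frame counts before deduplication.
#' @export
two_round_sampling <- function(s, h, sp = sampler_params(),
                               cp = clash_params(), n_seeds = 3L) {
  if (n_seeds < 1L) stop("n_seeds must be >= 1")
  round1 <- sample_hinge(s, h, sp, cp)
  # all C-alphas: the static scaffold anchors the superposition, so the
  # RMSD reflects mobile-domain displacement (mobile-only RMSD would be
  # identically zero for a rigid body)
  ca_idx <- which(s$atoms$name == "CA")
  seeds <- maximin_frames(round1, ca_idx, n_seeds)

  chains <- vector("list", n_seeds)
  for (j in seq_len(n_seeds)) {
    spj <- sp
    spj$seed <- (sp$seed + j) %% .Machine$integer.max
    spj$initial_deltas <- round1$dihedrals[seeds[j], ]
    chains[[j]] <- sample_hinge(s, h, spj, cp)
  }
  all_frames <- c(round1$frames, unlist(lapply(chains, `[[`, "frames"),
                                        recursive = FALSE))
  all_meta <- rbind(round1$meta, do.call(rbind, lapply(chains, `[[`, "meta")))
  all_dih <- rbind(round1$dihedrals,
                   do.call(rbind, lapply(chains, `[[`, "dihedrals")))
  sig <- vapply(all_frames, function(x) paste(x, collapse = ","),
                character(1))
  keep <- !duplicated(sig)
  out <- new_ensemble(s, all_frames[keep], all_meta[keep, , drop = FALSE],
                      all_dih[keep, , drop = FALSE])
  attr(out, "round_sizes") <- c(n_frames(round1),
                                vapply(chains, n_frames, integer(1)))
  attr(out, "static_idx") <- attr(round1, "static_idx")
  attr(out, "mobile_idx") <- attr(round1, "mobile_idx")
  out
}

# greedy maximin (farthest-point) frame selection on mobile-domain RMSD
maximin_frames <- function(e, atom_idx, n_seeds) {
  n <- n_frames(e)
  if (n_seeds >= n) return(seq_len(n))
  coords <- lapply(e$frames, function(x) x[atom_idx, , drop = FALSE])
  chosen <- which.min(e$meta$energy)
  mind <- vapply(coords, function(c2) qcp_rmsd(coords[[chosen]], c2),
                 numeric(1))
  while (length(chosen) < n_seeds) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    dn <- vapply(coords, function(c2) qcp_rmsd(coords[[nxt]], c2),
                 numeric(1))
    mind <- pmin(mind, dn)
  }
  chosen
}

#' Write an Ensemble as multi-model PDB plus CSV metadata sidecar
#'
#' @param e an `Ensemble`.
#' @param pdb_path,csv_path output paths.
#' @export
write_ensemble <- function(e, pdb_path, csv_path = NULL) {
  write_pdb(ensemble_to_structure(e), pdb_path)
  if (!is.null(csv_path))
    utils::write.csv(e$meta, csv_path, row.names = FALSE)
  invisible(pdb_path)
}
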