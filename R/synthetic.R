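# Ideal-helix backbone generator used by the toy builders.  Parametric
# curve: CA(t) on a helix of given radius (A), rise (A/residue) and twist
# (degrees/residue); N and C are placed on the same curve at t -/+ 0.35,
# O and CB stick out radially.  direction = +1 builds N->C up the axis,
# -1 down.
helix_residues <- function(resno, axis_xy, z_start, phase, rise = 1.5,
                           radius = 2.3, twist = 100, direction = 1) {
  point <- function(t) {
    th <- (phase + t * twist) * pi / 180
    c(axis_xy[1] + radius * cos(th), axis_xy[2] + radius * sin(th),
      z_start + direction * rise * t)
  }
  radial <- function(t) {
    th <- (phase + t * twist) * pi / 180
    c(cos(th), sin(th), 0)
  }
  atoms <- list()
  xyz <- list()
  for (k in seq_along(resno)) {
    t0 <- k
    ca <- point(t0); nn <- point(t0 - 0.35); cc <- point(t0 + 0.35)
    oo <- cc + 1.23 * radial(t0 + 0.35)
    cb <- ca + 1.53 * radial(t0)
    nm <- c("N", "CA", "C", "O", "CB")
    el <- c("N", "C", "C", "O", "C")
    for (q in 1:5) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = nm[q], element = el[q], resno = resno[k], resname = "ALA",
        stringsAsFactors = FALSE)
    }
    xyz <- c(xyz, list(nn, ca, cc, oo, cb))
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

#' Generate a toy two-domain hinge protein
#'
#' Builds an idealized alpha-helical stand-in for the mobile-kinase-domain
#' problem: a static scaffold helix, a 3-residue hinge, a rigid mobile
#' domain helix continuing the same axis, and a second static scaffold
#' helix placed alongside the far end of the mobile domain.  The linker
#' that would join the mobile domain's C-terminus to the second scaffold
#' is not modelled; its two attachment atoms serve as closure anchors,
#' placed `anchor_gap` angstrom apart in the starting conformation.
#' Backbone is N, CA, C, O, CB; the construction is deterministic.
#'
#' @param n_static,n_mobile,n_scaffold2 residue counts of the static base
#'   helix, the mobile helix and the flanking static helix (each >= 4).
#' @param rise,radius,twist ideal-helix parameters (1.5 A/residue,
#'   2.3 A, 100 degrees/residue).
#' @param anchor_gap starting closure-anchor distance in angstrom.
#' @param chain chain identifier.
#' @return list with `structure` (a `Structure`), `hinge` (a `HingeSpec`
#'   over the 3 hinge residues, all six phi/psi sampled), `closure` (a
#'   [closure_filter_params()] with the default 18 A limit), and the
#'   residue ranges `static_residues`, `hinge_residues`,
#'   `mobile_residues`, `scaffold2_residues`.
#' @export
make_toy_hinge_protein <- function(n_static = 12L, n_mobile = 12L,
                                   n_scaffold2 = 8L, rise = 1.5,
                                   radius = 2.3, twist = 100,
                                   anchor_gap = 6, chain = "A") {
  if (n_static < 4L || n_mobile < 4L || n_scaffold2 < 4L)
    stop("each domain needs at least 4 residues")
  if (rise <= 0 || radius <= 0 || anchor_gap <= 0)
    stop("infeasible geometry parameters")
  ns <- as.integer(n_static); nm <- as.integer(n_mobile)
  np <- as.integer(n_scaffold2)
  static_res <- 1:ns
  hinge_res <- (ns + 1L):(ns + 3L)
  mobile_res <- (ns + 4L):(ns + 3L + nm)
  scaf2_res <- (ns + nm + 4L):(ns + nm + 3L + np)

  main <- helix_residues(c(static_res, hinge_res, mobile_res),
                         axis_xy = c(0, 0), z_start = 0, phase = 0,
                         rise = rise, radius = radius, twist = twist)
  # provisional flanking helix, then shift it so that its first N sits
  # anchor_gap from the mobile domain's last C along +x
  z_top <- rise * (ns + 3L + nm + 1L)
  # anchor the scaffold's first N exactly anchor_gap from the mobile
  # domain's last C, radially outward from the main helix axis, with the
  # scaffold phased so its body points away from the mobile helix
  c_idx <- which(main$atoms$resno == max(mobile_res) & main$atoms$name == "C")
  c_pos <- main$xyz[c_idx, ]
  u <- c(c_pos[1], c_pos[2], 0)
  u <- u / sqrt(sum(u^2))
  target <- c_pos + anchor_gap * u
  theta_n <- atan2(-u[2], -u[1]) * 180 / pi   # N points back toward C
  scaf <- helix_residues(scaf2_res, axis_xy = c(0, 0),
                         z_start = z_top, phase = theta_n - 0.65 * twist,
                         rise = rise, radius = radius, twist = twist,
                         direction = -1)
  n_idx <- which(scaf$atoms$resno == min(scaf2_res) & scaf$atoms$name == "N")
  shift <- target - scaf$xyz[n_idx, ]
  scaf$xyz <- sweep(scaf$xyz, 2L, shift, "+")

  atoms <- rbind(main$atoms, scaf$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- chain
  atoms$occupancy <- 1
  atoms$b <- 0
  s <- new_structure(atoms, list(rbind(main$xyz, scaf$xyz)))
  h <- hinge_spec(s, chain, hinge_res, mobile_res)
  f <- closure_filter_params(
    anchor_a = selection(chain = chain, resno = max(mobile_res),
                         name = "C"),
    anchor_b = selection(chain = chain, resno = min(scaf2_res),
                         name = "N"),
    max_distance = 18)
  list(structure = s, hinge = h, closure = f,
       static_residues = static_res, hinge_residues = hinge_res,
       mobile_residues = mobile_res, scaffold2_residues = scaf2_res)
}

#' Generate a toy dimer with a planted active-site separation
#'
#' Two copies of the toy hinge protein as chains A and B, chain B
#' translated so that the marker atoms (CB of the central mobile-domain
#' residue of each chain) sit exactly `separation` angstrom apart.
#'
#' @param separation planted active-site separation (angstrom).
#' @param ... passed to [make_toy_hinge_protein()].
#' @return list with `structure`, `site_a`, `site_b` (marker
#'   `SelectionSpec`s) and `separation`.
#' @export
make_toy_dimer <- function(separation = 55, ...) {
  stopifnot(separation > 0)
  mono <- make_toy_hinge_protein(chain = "A", ...)
  sa <- mono$structure
  mid <- mono$mobile_residues[ceiling(length(mono$mobile_residues) / 2)]
  atoms_b <- sa$atoms
  atoms_b$chain <- "B"
  atoms_b$serial <- atoms_b$serial + nrow(sa$atoms)
  xyz_b <- sweep(get_xyz(sa), 2L, c(separation, 0, 0), "+")
  atoms <- rbind(sa$atoms, atoms_b)
  s <- new_structure(atoms, list(rbind(get_xyz(sa), xyz_b)))
  list(structure = s,
       site_a = selection(chain = "A", resno = mid, name = "CB"),
       site_b = selection(chain = "B", resno = mid, name = "CB"),
       separation = separation)
}

#' Generate a small peptide of charged residues
#'
#' A row of residues carrying the side-chain atoms needed by the
#' salt-bridge machinery (designated outermost carbons included),
#' spaced `spacing` angstrom apart along x.
#'
#' @param resnames residue names in order (from ASP, GLU, ARG, LYS, HIS,
#'   ALA).
#' @param spacing inter-residue spacing along x (angstrom).
#' @param chain chain identifier.
#' @return a `Structure`.
#' @export
make_charged_peptide <- function(resnames = c("GLU", "ASP", "ALA",
                                              "ARG", "LYS"),
                                 spacing = 12, chain = "A") {
  side <- list(ASP = c("CG"), GLU = c("CG", "CD"),
               ARG = c("CG", "CD", "NE", "CZ"),
               LYS = c("CG", "CD", "CE"), HIS = c("CG", "CE1"),
               ALA = character(0))
  elem_of <- function(nm) if (startsWith(nm, "N")) "N" else
    if (startsWith(nm, "O")) "O" else "C"
  atoms <- list(); xyz <- list()
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    if (!rn %in% names(side)) stop("unsupported residue name: ", rn)
    base <- c((i - 1) * spacing, 0, 0)
    nm <- c("N", "CA", "C", "O", "CB", side[[rn]])
    off <- list(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.2, 0.8, 0),
                c(1.2, 2.0, 0), c(0, -1.5, 0))
    for (k in seq_along(side[[rn]]))
      off[[5L + k]] <- c(0, -1.5 - 1.4 * k, 0)
    for (q in seq_along(nm)) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = nm[q], element = elem_of(nm[q]), resno = i, resname = rn,
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- base + off[[q]]
    }
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a)); a$chain <- chain
  a$occupancy <- 1; a$b <- 0
  new_structure(a, list(do.call(rbind, xyz)))
}

#' Generate a trajectory with planted charged contacts
#'
#' Produces frames in which each planted acidic-basic contact is inside
#' its target distance in exactly the requested fraction of frames: the
#' basic residue is rigidly translated along the pair axis onto the
#' target distance for the in-contact frames and left at its (distant)
#' base position otherwise, then isotropic Gaussian jitter is added to
#' every atom.
#'
#' @param base a `Structure` (e.g. from [make_charged_peptide()]).
#' @param contacts data frame with columns `resno_a` (acidic), `resno_b`
#'   (basic), `target_distance` (angstrom), `fraction` (of frames;
#'   `fraction * n_frames` must be a whole number).  `resno_b` values
#'   must be distinct across rows.
#' @param n_frames number of frames.
#' @param noise_sd Gaussian positional noise sigma (angstrom), applied
#'   after contact placement.
#' @param seed RNG seed.
#' @param params a [salt_bridge_params()] supplying the designated-atom
#'   table.
#' @return a `Trajectory`; attribute `planted` records the in-contact
#'   frame sets.
#' @export
make_planted_trajectory <- function(base, contacts, n_frames = 30L,
                                    noise_sd = 0, seed = 1L,
                                    params = salt_bridge_params()) {
  stopifnot(inherits(base, "Structure"), is.data.frame(contacts))
  if (anyDuplicated(contacts$resno_b))
    stop("each basic residue may appear in only one planted contact")
  a <- base$atoms
  find_outer <- function(rn) {
    res <- a$resname[a$resno == rn][1]
    if (is.na(res)) stop("contact references missing residue ", rn)
    j <- which(a$resno == rn & a$name == params$outer_atom[[res]])
    if (length(j) != 1L) stop("designated atom missing for residue ", rn)
    j
  }
  counts <- contacts$fraction * n_frames
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("unrealizable fraction: fraction x n_frames must be integral")
  counts <- as.integer(round(counts))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  xyz0 <- get_xyz(base)
  planted <- vector("list", nrow(contacts))
  shifts <- vector("list", nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    ia <- find_outer(contacts$resno_a[k])
    ib <- find_outer(contacts$resno_b[k])
    v <- xyz0[ib, ] - xyz0[ia, ]
    d0 <- sqrt(sum(v^2))
    if (d0 <= contacts$target_distance[k])
      stop("base structure already places pair ", k, " inside the target")
    u <- v / d0
    planted[[k]] <- sort(sample.int(n_frames, counts[k]))
    shifts[[k]] <- list(
      atoms = which(a$resno == contacts$resno_b[k]),
      shift = (contacts$target_distance[k] - d0) * u)
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    x <- xyz0
    for (k in seq_len(nrow(contacts))) {
      if (f %in% planted[[k]]) {
        idx <- shifts[[k]]$atoms
        x[idx, ] <- sweep(x[idx, , drop = FALSE], 2L, shifts[[k]]$shift,
                          "+")
      }
    }
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), 3L)
    frames[[f]] <- x
  }
  tr <- new_trajectory(base, frames)
  attr(tr, "planted") <- planted
  tr
}

#' Generate a half-map pair with planted anisotropic resolution
#'
#' Simulates a density map from a structure, degrades it with an extra
#' per-axis Gaussian blur (planting resolution anisotropy, e.g. worse
#' resolution along z), and adds two independent Gaussian noise
#' realizations to produce the half-map pair.
#'
#' @param s a `Structure`.
#' @param resolution base map resolution (angstrom).
#' @param voxel_size voxel edge (angstrom).
#' @param blur_sigma length-3 per-axis extra real-space blur sigma
#'   (angstrom); `c(0, 0, z)` plants worse resolution along z.
#' @param snr signal-to-noise ratio (sd of blurred signal over noise
#'   sd); must be > 0, `Inf` for noise-free maps.
#' @param seed RNG seed (two independent noise streams derived from it).
#' @param dim optional cubic grid size (voxels); the simulated map is
#'   cropped/padded symmetrically to this size.
#' @return list with `half1`, `half2` (`DensityMap`s) and `truth` (the
#'   planted per-axis effective blur sigma and resolution).
#' @export
make_half_maps <- function(s, resolution = 10, voxel_size = 2,
                           blur_sigma = c(0, 0, 0), snr = 5, seed = 1L,
                           dim = NULL) {
  if (!is.infinite(snr) && snr <= 0) stop("SNR must be positive")
  stopifnot(length(blur_sigma) == 3L, all(blur_sigma >= 0))
  signal <- simulate_map(s, resolution, voxel_size)
  if (!is.null(dim)) signal <- crop_pad_map(signal, rep(dim, 3L))
  if (any(blur_sigma > 0)) signal <- gaussian_blur(signal, blur_sigma)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  noise_sd <- if (is.infinite(snr)) 0 else stats::sd(signal$data) / snr
  mk <- function(sub_seed) {
    set.seed(sub_seed)
    d <- signal$data
    if (noise_sd > 0)
      d <- d + array(stats::rnorm(length(d), 0, noise_sd), dim(d))
    new_density_map(d, voxel_size, signal$origin)
  }
  half1 <- mk(seed)
  half2 <- mk((seed + 77777L) %% .Machine$integer.max)
  sigma0 <- resolution * sqrt(log(2)) / (sqrt(2) * pi)
  sig_eff <- sqrt(sigma0^2 + blur_sigma^2)
  list(half1 = half1, half2 = half2,
       truth = list(blur_sigma = blur_sigma,
                    effective_sigma = sig_eff,
                    effective_resolution = sig_eff * sqrt(2) * pi /
                      sqrt(log(2)),
                    noise_sd = noise_sd))
}

# separable Gaussian blur with per-axis real-space sigma (angstrom),
# applied in Fourier space
gaussian_blur <- function(m, sigma) {
  dims <- dim(m$data)
  fx <- fft_freq(dims[1]) / m$voxel_size
  fy <- fft_freq(dims[2]) / m$voxel_size
  fz <- fft_freq(dims[3]) / m$voxel_size
  gx <- exp(-2 * pi^2 * sigma[1]^2 * fx^2)
  gy <- exp(-2 * pi^2 * sigma[2]^2 * fy^2)
  gz <- exp(-2 * pi^2 * sigma[3]^2 * fz^2)
  G <- gx %o% gy %o% gz
  out <- Re(stats::fft(stats::fft(m$data) * G, inverse = TRUE)) /
    length(m$data)
  new_density_map(out, m$voxel_size, m$origin)
}

# center-crop or zero-pad a map to the requested dimensions
crop_pad_map <- function(m, dims) {
  old <- dim(m$data)
  out <- array(0, dims)
  src <- dst <- vector("list", 3L)
  shift <- numeric(3L)
  for (k in 1:3) {
    n <- min(old[k], dims[k])
    s0 <- (old[k] - n) %/% 2L
    d0 <- (dims[k] - n) %/% 2L
    src[[k]] <- (s0 + 1L):(s0 + n)
    dst[[k]] <- (d0 + 1L):(d0 + n)
    shift[k] <- (s0 - d0) * m$voxel_size
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m$data[src[[1]], src[[2]], src[[3]]]
  new_density_map(out, m$voxel_size, m$origin + shift)
}
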