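#' Density map container
#'
#' A 3-D scalar grid with isotropic voxel size (angstrom/voxel) and an
#' origin giving the Cartesian position (angstrom) of the center of voxel
#' (1,1,1).  Axis order is x (fastest), y, z, matching the MRC2014 default.
#'
#' @param data 3-D numeric array of finite values, >= 2 voxels per axis.
#' @param voxel_size voxel edge length in angstrom (> 0).
#' @param origin length-3 numeric, angstrom.
#' @export
new_density_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) >= 2L),
            all(is.finite(data)), voxel_size > 0, length(origin) == 3L)
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)), class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap: %s voxels @ %.3f A/voxel\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size))
  invisible(x)
}

# default atomic masses (u) for map simulation
atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

#' Simulate a density map from an atomic model
#'
#' Places a mass-weighted isotropic Gaussian at every atom.  The Gaussian
#' width is tied to the nominal resolution so that the Fourier amplitude
#' of a single atom falls to one half at spatial frequency 1/resolution
#' (`sigma = resolution * sqrt(ln 2) / (sqrt(2) * pi)`).  Each atom's
#' density integrates to its mass, so the map integral (sum x voxel
#' volume) is proportional to the total mass.
#'
#' @param s a `Structure` (must contain at least one atom).
#' @param resolution nominal resolution in angstrom (>= 2 x voxel_size).
#' @param voxel_size voxel edge in angstrom.
#' @param model model index.
#' @param pad padding (angstrom) beyond the atomic bounding box.
#' @return a `DensityMap`.
#' @export
simulate_map <- function(s, resolution, voxel_size, model = 1L, pad = 6) {
  stopifnot(inherits(s, "Structure"))
  if (n_atoms(s) == 0L) stop("cannot simulate a map from an empty structure")
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 x voxel_size (Nyquist)")
  xyz <- get_xyz(s, model)
  sigma <- resolution * sqrt(log(2)) / (sqrt(2) * pi)
  lo <- apply(xyz, 2L, min) - pad
  hi <- apply(xyz, 2L, max) + pad
  dims <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 2L)
  origin <- lo
  mass <- atomic_masses[s$atoms$element]
  mass[is.na(mass)] <- 12.011
  grid <- array(0, dims)
  amp <- mass / (2 * pi * sigma^2)^1.5 * voxel_size^3
  cut <- ceiling(4.5 * sigma / voxel_size)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1L) *
                 voxel_size)
  for (i in seq_len(nrow(xyz))) {
    cv <- round((xyz[i, ] - origin) / voxel_size) + 1L
    rng <- lapply(1:3, function(k)
      max(1L, cv[k] - cut):min(dims[k], cv[k] + cut))
    gx <- exp(-(ax[[1]][rng[[1]]] - xyz[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - xyz[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - xyz[i, 3])^2 / (2 * sigma^2))
    grid[rng[[1]], rng[[2]], rng[[3]]] <-
      grid[rng[[1]], rng[[2]], rng[[3]]] +
      amp[i] * (gx %o% gy %o% gz)
  }
  new_density_map(grid, voxel_size, origin)
}

#' Thresholded, locally masked cross-correlation between two maps
#'
#' Pearson correlation between an experimental and a simulated map over
#' the voxels that (a) exceed a solvent-removal threshold in the
#' experimental map and (b) lie within a given radius of the atoms of a
#' region of interest.
#'
#' @param map_exp,map_sim `DensityMap`s on the same grid.
#' @param threshold density threshold applied to `map_exp`; default
#'   `NULL` uses mean + 1 SD of `map_exp`.
#' @param region optional `Structure` or N x 3 coordinate matrix defining
#'   the region of interest; `NULL` disables the region mask.
#' @param radius dilation radius (angstrom) around the region atoms.
#' @return the cross-correlation coefficient in [-1, 1].
#' @export
local_ccc <- function(map_exp, map_sim, threshold = NULL, region = NULL,
                      radius = 5) {
  if (!identical(dim(map_exp$data), dim(map_sim$data)) ||
      !isTRUE(all.equal(map_exp$voxel_size, map_sim$voxel_size)))
    stop("resample error: maps are not on the same grid")
  if (is.null(threshold))
    threshold <- mean(map_exp$data) + stats::sd(map_exp$data)
  mask <- map_exp$data > threshold
  if (!is.null(region)) {
    xyz <- if (inherits(region, "Structure")) get_xyz(region) else region
    mask <- mask & region_mask(map_exp, xyz, radius)
  }
  if (!any(mask))
    stop("undefined-CCC error: empty mask after thresholding")
  stats::cor(map_exp$data[mask], map_sim$data[mask])
}

# logical mask of voxels within `radius` angstrom of any of the points
region_mask <- function(m, xyz, radius) {
  dims <- dim(m$data)
  mask <- array(FALSE, dims)
  rv <- ceiling(radius / m$voxel_size)
  ax <- lapply(1:3, function(k) m$origin[k] + (seq_len(dims[k]) - 1L) *
                 m$voxel_size)
  r2 <- radius^2
  for (i in seq_len(nrow(xyz))) {
    cv <- round((xyz[i, ] - m$origin) / m$voxel_size) + 1L
    rng <- lapply(1:3, function(k)
      max(1L, cv[k] - rv):min(dims[k], cv[k] + rv))
    dx2 <- (ax[[1]][rng[[1]]] - xyz[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - xyz[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - xyz[i, 3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]]] | within
  }
  mask
}

#' The 13-axis conical-FSC direction set
#'
#' The three principal axes plus the ten axes bisecting them: the six
#' face-diagonal directions and the four body-diagonal directions (axes
#' are unsigned, so antipodes are not repeated).  With a 42 degree
#' half-angle these cones cover every direction in reciprocal space.
#'
#' @return a 13 x 3 matrix of unit vectors.
#' @export
cone_axes_13 <- function() {
  ax <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(1, 1, 0), c(1, -1, 0), c(0, 1, 1), c(0, 1, -1),
              c(1, 0, 1), c(1, 0, -1),
              c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  ax / sqrt(rowSums(ax^2))
}

#' Cone specification for conical FSC
#'
#' @param axes m x 3 matrix of cone axes (normalized internally); default
#'   the 13-axis set of [cone_axes_13()].
#' @param half_angle cone half-angle in degrees, in (0, 90); default 42.
#' @export
cone_spec <- function(axes = cone_axes_13(), half_angle = 42) {
  stopifnot(is.matrix(axes), ncol(axes) == 3L,
            half_angle > 0, half_angle < 90)
  axes <- axes / sqrt(rowSums(axes^2))
  structure(list(axes = axes, half_angle = half_angle), class = "ConeSpec")
}

# signed FFT frequencies (cycles per sample) along an axis of length n
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# per-voxel Fourier geometry for a map: frequency magnitude (1/A), unit
# direction cosines against each cone axis, and shell index
fourier_geometry <- function(m, axes) {
  dims <- dim(m$data)
  fx <- fft_freq(dims[1]) / m$voxel_size
  fy <- fft_freq(dims[2]) / m$voxel_size
  fz <- fft_freq(dims[3]) / m$voxel_size
  FX <- array(fx, dims)
  FY <- array(rep(fy, each = dims[1]), dims)
  FZ <- array(rep(fz, each = dims[1] * dims[2]), dims)
  R <- sqrt(FX^2 + FY^2 + FZ^2)
  nyq <- 1 / (2 * m$voxel_size)
  shell_width <- 1 / (min(dims) * m$voxel_size)
  shell <- as.integer(round(R / shell_width))
  n_shells <- as.integer(floor(nyq / shell_width + 1e-9))
  cosang <- vector("list", nrow(axes))
  Rsafe <- R; Rsafe[1, 1, 1] <- 1
  for (a in seq_len(nrow(axes))) {
    u <- axes[a, ]
    cosang[[a]] <- abs(FX * u[1] + FY * u[2] + FZ * u[3]) / Rsafe
  }
  list(R = R, shell = shell, n_shells = n_shells,
       shell_width = shell_width, nyquist = nyq, cosang = cosang)
}

#' Conical Fourier shell correlation between two half-maps
#'
#' For every cone (axis plus antipode, given half-angle) and every
#' spatial-frequency shell, computes
#' `FSC = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` over the
#' Fourier voxels inside that cone and shell, and estimates a per-cone
#' resolution as the first downward crossing of the criterion.
#'
#' @param half1,half2 `DensityMap`s on identical grids.
#' @param cones a [cone_spec()]; default 13 axes at 42 degrees.
#' @param criterion FSC resolution criterion (default 0.143).
#' @return an `FSCResult`: list with `shells` (1/angstrom centers),
#'   `fsc` (shells x cones matrix, NA for empty bins), `resolution`
#'   (angstrom per cone), `flags`, `cones`, `criterion`, `voxel_size`.
#' @export
conical_fsc <- function(half1, half2, cones = cone_spec(),
                        criterion = 0.143) {
  if (!identical(dim(half1$data), dim(half2$data)) ||
      !isTRUE(all.equal(half1$voxel_size, half2$voxel_size)))
    stop("grid mismatch between half-maps")
  geom <- fourier_geometry(half1, cones$axes)
  F1 <- stats::fft(half1$data)
  F2 <- stats::fft(half2$data)
  cross_re <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  cos_min <- cos(cones$half_angle * pi / 180)
  n_cones <- nrow(cones$axes)
  ns <- geom$n_shells
  fsc <- matrix(NA_real_, ns, n_cones)
  shells <- seq_len(ns) * geom$shell_width
  in_range <- geom$shell >= 1L & geom$shell <= ns
  for (a in seq_len(n_cones)) {
    inc <- in_range & geom$cosang[[a]] >= cos_min
    if (!any(inc)) next
    sh <- geom$shell[inc]
    num <- vapply(split(cross_re[inc], sh), sum, numeric(1))
    d1 <- vapply(split(p1[inc], sh), sum, numeric(1))
    d2 <- vapply(split(p2[inc], sh), sum, numeric(1))
    ids <- as.integer(names(num))
    ok <- d1 > 0 & d2 > 0
    fsc[ids[ok], a] <- num[ok] / sqrt(d1[ok] * d2[ok])
  }
  res <- numeric(n_cones)
  flags <- character(n_cones)
  for (a in seq_len(n_cones)) {
    curve <- fsc[, a]
    keep <- !is.na(curve)  # empty bins interpolated over by omission
    r <- fsc_resolution(shells[keep], curve[keep], criterion,
                        voxel_size = half1$voxel_size)
    res[a] <- r$resolution
    flags[a] <- r$flag
  }
  structure(list(shells = shells, fsc = fsc, resolution = res,
                 flags = flags, cones = cones, criterion = criterion,
                 voxel_size = half1$voxel_size),
            class = "FSCResult")
}

#' Resolution from an FSC curve
#'
#' Linear interpolation of the first downward crossing of the criterion;
#' the estimate is never better (smaller) than the Nyquist resolution
#' `2 * voxel_size`.
#'
#' @param shells spatial-frequency shell centers (1/angstrom, increasing).
#' @param fsc correlation values at the shells.
#' @param criterion crossing criterion.
#' @param voxel_size voxel size (angstrom), for the Nyquist floor.
#' @return list with `resolution` (angstrom) and `flag` (`"ok"`,
#'   `"above-criterion"` when the curve never drops below the criterion,
#'   `"below-criterion"` when it starts below it).
#' @export
fsc_resolution <- function(shells, fsc, criterion = 0.143,
                           voxel_size = NULL) {
  stopifnot(length(shells) == length(fsc), length(shells) >= 1L)
  nyq_res <- if (is.null(voxel_size)) 1 / max(shells) else 2 * voxel_size
  below <- which(fsc < criterion)
  if (!length(below))
    return(list(resolution = nyq_res, flag = "above-criterion"))
  i <- below[1L]
  if (i == 1L)
    return(list(resolution = 1 / shells[length(shells)],
                flag = "below-criterion"))
  f_cross <- shells[i - 1L] + (shells[i] - shells[i - 1L]) *
    (fsc[i - 1L] - criterion) / (fsc[i - 1L] - fsc[i])
  list(resolution = max(1 / f_cross, nyq_res), flag = "ok")
}

#' Anisotropic low-pass filter driven by conical FSC resolutions
#'
#' Attenuates each Fourier voxel according to the per-cone resolution
#' estimates: inside one cone the filter is a low-pass with cutoff at
#' that cone's resolution (optionally with a soft cosine edge); voxels
#' inside several overlapping cones take the average of the overlapping
#' cones' filter values.  A cutoff at or beyond Nyquist passes all
#' frequencies.  The output is real.
#'
#' @param m a `DensityMap`.
#' @param f an `FSCResult` computed on the same grid geometry (per-cone
#'   `resolution` must be present and finite).
#' @param edge_width soft cosine edge width in 1/angstrom; 0 gives a hard
#'   cutoff.
#' @return the filtered `DensityMap`.
#' @export
anisotropic_lowpass <- function(m, f, edge_width = 0.01) {
  if (is.null(f$resolution) || any(!is.finite(f$resolution)))
    stop("FSC resolution estimates missing for one or more cones")
  if (!isTRUE(all.equal(m$voxel_size, f$voxel_size)))
    stop("FSCResult was computed on a different grid geometry")
  geom <- fourier_geometry(m, f$cones$axes)
  cos_min <- cos(f$cones$half_angle * pi / 180)
  cutoffs <- 1 / f$resolution
  filt_sum <- array(0, dim(m$data))
  filt_n <- array(0, dim(m$data))
  for (a in seq_along(cutoffs)) {
    inc <- geom$cosang[[a]] >= cos_min
    fa <- lowpass_response(geom$R, cutoffs[a], edge_width, geom$nyquist)
    filt_sum[inc] <- filt_sum[inc] + fa[inc]
    filt_n[inc] <- filt_n[inc] + 1
  }
  filt <- filt_sum / pmax(filt_n, 1)
  filt[filt_n == 0] <- 1  # outside every cone (only possible at DC)
  filt[1, 1, 1] <- 1      # DC has no direction; always passes
  out <- Re(stats::fft(stats::fft(m$data) * filt, inverse = TRUE)) /
    length(m$data)
  new_density_map(out, m$voxel_size, m$origin)
}

# radial low-pass response; cutoff at/above Nyquist passes everything
lowpass_response <- function(R, cutoff, edge_width, nyquist) {
  if (cutoff >= nyquist - 1e-12) return(array(1, dim(R)))
  if (edge_width <= 0) return((R <= cutoff) * 1)
  lo <- cutoff - edge_width / 2
  hi <- cutoff + edge_width / 2
  resp <- 0.5 * (1 + cos(pi * (R - lo) / edge_width))
  resp[R <= lo] <- 1
  resp[R >= hi] <- 0
  resp
}

#' Isotropic low-pass filter (reference)
#'
#' Plain radial low-pass at a single cutoff, same edge model as
#' [anisotropic_lowpass()].
#'
#' @param m a `DensityMap`.
#' @param cutoff cutoff spatial frequency (1/angstrom).
#' @param edge_width cosine edge width (1/angstrom); 0 for hard.
#' @export
isotropic_lowpass <- function(m, cutoff, edge_width = 0) {
  geom <- fourier_geometry(m, matrix(c(1, 0, 0), 1))
  filt <- lowpass_response(geom$R, cutoff, edge_width, geom$nyquist)
  filt[1, 1, 1] <- 1
  out <- Re(stats::fft(stats::fft(m$data) * filt, inverse = TRUE)) /
    length(m$data)
  new_density_map(out, m$voxel_size, m$origin)
}

#' Export FSC curves to CSV
#' @param f an `FSCResult`.
#' @param path output CSV path.
#' @export
write_fsc_csv <- function(f, path) {
  n_cones <- ncol(f$fsc)
  df <- data.frame(
    cone_id = rep(seq_len(n_cones), each = length(f$shells)),
    shell_center_invA = rep(f$shells, n_cones),
    fsc = as.vector(f$fsc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
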