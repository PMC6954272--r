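single_atom <- function(pos, element = "C") {
  new_structure(
    data.frame(serial = 1, name = "CA", element = element, resno = 1,
               resname = "ALA", chain = "A"),
    list(matrix(pos, 1, 3)))
}

test_that("simulate_map places density at atoms, integrates to mass, and is linear", {
  a1 <- single_atom(c(3.2, 4.1, 5.7))
  m <- simulate_map(a1, 6, 1)
  ix <- which(m$data == max(m$data), arr.ind = TRUE)[1, ]
  expect_equal(m$origin + (ix - 1) * m$voxel_size, c(3.2, 4.1, 5.7),
               tolerance = 1e-9, ignore_attr = TRUE)
  # integral proportional to mass within 1%
  expect_equal(sum(m$data), 12.011, tolerance = 0.01)
  # two coincident atoms double the map (linearity in mass)
  two <- new_structure(
    data.frame(serial = 1:2, name = c("CA", "CB"), element = "C",
               resno = 1:2, resname = "ALA", chain = c("A", "B")),
    list(matrix(rep(c(3.2, 4.1, 5.7), 2), 2, 3, byrow = TRUE)))
  m2 <- simulate_map(two, 6, 1)
  expect_equal(m2$data, 2 * m$data, tolerance = 1e-9)
  expect_error(simulate_map(a1, 1.5, 1), "Nyquist")
})

test_that("simulate_map matches the analytic Gaussian sum for two atoms 20 A apart", {
  s <- new_structure(
    data.frame(serial = 1:2, name = "CA", element = "C", resno = 1:2,
               resname = "ALA", chain = c("A", "B")),
    list(matrix(c(0, 0, 0, 20, 0, 0), 2, 3, byrow = TRUE)))
  m <- simulate_map(s, 5, 1)
  # two local maxima at the atom positions (within one voxel)
  peaks <- which(m$data == max(m$data), arr.ind = TRUE)
  near <- function(p, atom) all(abs(m$origin + (p - 1) * m$voxel_size -
                                      atom) <= m$voxel_size + 1e-9)
  halves <- list(m$data[m$origin[1] + seq_len(dim(m$data)[1]) - 1 < 10, , ],
                 m$data[m$origin[1] + seq_len(dim(m$data)[1]) - 1 >= 10, , ])
  expect_equal(max(halves[[1]]), max(halves[[2]]), tolerance = 1e-6)
  # oracle: direct evaluation of the Gaussian sum on the same grid
  sigma <- 5 * sqrt(log(2)) / (sqrt(2) * pi)
  dims <- dim(m$data)
  ax <- lapply(1:3, function(k) m$origin[k] + (seq_len(dims[k]) - 1))
  g <- array(0, dims)
  for (atom in list(c(0, 0, 0), c(20, 0, 0))) {
    gx <- exp(-(ax[[1]] - atom[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]] - atom[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]] - atom[3])^2 / (2 * sigma^2))
    g <- g + 12.011 / (2 * pi * sigma^2)^1.5 * (gx %o% gy %o% gz)
  }
  expect_equal(m$data, g, tolerance = 1e-3)
})

test_that("local CCC is a thresholded masked Pearson correlation", {
  toy <- toy_system()
  m <- simulate_map(toy$structure, 8, 1.5)
  expect_equal(local_ccc(m, m), 1, tolerance = 1e-12)
  neg <- new_density_map(-m$data, m$voxel_size, m$origin)
  expect_equal(local_ccc(m, neg), -1, tolerance = 1e-12)
  aff <- new_density_map(3.7 * m$data + 1.2, m$voxel_size, m$origin)
  expect_equal(local_ccc(m, aff), 1, tolerance = 1e-9)
  # region restriction changes the voxel set but self-CCC stays 1
  expect_equal(local_ccc(m, m, region = get_xyz(toy$structure)[1:10, ],
                         radius = 4), 1, tolerance = 1e-12)
  expect_error(local_ccc(m, m, threshold = max(m$data) + 1),
               "undefined-CCC")
  other <- simulate_map(toy$structure, 8, 2)
  expect_error(local_ccc(m, other), "resample error")
})

test_that("the 13-axis 42-degree cone set covers every Fourier direction", {
  ax <- cone_axes_13()
  expect_equal(nrow(ax), 13L)
  expect_equal(rowSums(ax^2), rep(1, 13), tolerance = 1e-12)
  n <- 64
  fr <- csutools:::fft_freq(n)
  g <- as.matrix(expand.grid(x = fr, y = fr, z = fr))
  g <- g[rowSums(g^2) > 0, ]
  u <- g / sqrt(rowSums(g^2))
  best <- apply(abs(u %*% t(ax)), 1, max)
  expect_true(all(best >= cos(42 * pi / 180)))
})

test_that("conical FSC is 1 for identical halves and -1 for negated halves", {
  toy <- toy_system()
  hm <- make_half_maps(toy$structure, resolution = 10, voxel_size = 2,
                       snr = Inf, seed = 1, dim = 48)
  f <- conical_fsc(hm$half1, hm$half2)
  vals <- f$fsc[!is.na(f$fsc)]
  expect_true(all(abs(vals - 1) < 1e-9))
  neg <- new_density_map(-hm$half2$data, 2, hm$half2$origin)
  fneg <- conical_fsc(hm$half1, neg)
  expect_true(all(abs(fneg$fsc[!is.na(fneg$fsc)] + 1) < 1e-9))
  small <- new_density_map(array(0.0, c(8, 8, 8)) + 1e-9, 2)
  expect_error(conical_fsc(hm$half1, small), "grid mismatch")
})

test_that("FSC of independent white noise stays inside the null band", {
  set.seed(21)
  n <- 64
  m1 <- new_density_map(array(rnorm(n^3), c(n, n, n)), 2)
  m2 <- new_density_map(array(rnorm(n^3), c(n, n, n)), 2)
  f <- conical_fsc(m1, m2)
  # null fluctuation scale 3/sqrt(n_independent); Fourier voxels of a
  # real map come in Hermitian-conjugate pairs, so the independent count
  # per bin is half the voxel count
  geom <- csutools:::fourier_geometry(m1, f$cones$axes)
  cmin <- cos(f$cones$half_angle * pi / 180)
  for (a in seq_len(ncol(f$fsc))) {
    inc <- geom$shell >= 1 & geom$shell <= length(f$shells) &
      geom$cosang[[a]] >= cmin
    counts <- tabulate(geom$shell[inc], nbins = length(f$shells))
    for (sh in 2:length(f$shells)) {
      if (counts[sh] < 10 || is.na(f$fsc[sh, a])) next
      expect_lt(abs(f$fsc[sh, a]), 3 / sqrt(counts[sh] / 2))
    }
  }
})

test_that("planted z-blur makes the z cone resolve worse than x and y", {
  toy <- toy_system()
  hm <- make_half_maps(toy$structure, resolution = 10, voxel_size = 2,
                       blur_sigma = c(0, 0, 4), snr = 3, seed = 31,
                       dim = 48)
  f <- conical_fsc(hm$half1, hm$half2)
  expect_gt(f$resolution[3], f$resolution[1])
  expect_gt(f$resolution[3], f$resolution[2])
})

test_that("fsc_resolution interpolates the first downward crossing", {
  # step curve: crossing between the 3rd and 4th shells
  shells <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  curve <- c(1, 1, 1, 0, 0)
  r <- fsc_resolution(shells, curve, criterion = 0.143)
  f_cross <- 0.03 + 0.01 * (1 - 0.143) / 1
  expect_equal(r$resolution, 1 / f_cross, tolerance = 1e-12)
  expect_equal(r$flag, "ok")
  # curve above the criterion everywhere -> Nyquist, flagged
  r1 <- fsc_resolution(shells, rep(1, 5), criterion = 0.143,
                       voxel_size = 2)
  expect_equal(r1$resolution, 4)
  expect_equal(r1$flag, "above-criterion")
  # criterion 0 with a positive curve -> Nyquist, flagged
  r0 <- fsc_resolution(shells, c(0.9, 0.8, 0.7, 0.6, 0.5), criterion = 0,
                       voxel_size = 2)
  expect_equal(r0$flag, "above-criterion")
  # curve entirely below -> worst shell, flagged
  rb <- fsc_resolution(shells, rep(0, 5), criterion = 0.143)
  expect_equal(rb$resolution, 1 / 0.05)
  expect_equal(rb$flag, "below-criterion")
})

test_that("anisotropic low-pass reduces to known limits", {
  toy <- toy_system()
  hm <- make_half_maps(toy$structure, resolution = 10, voxel_size = 2,
                       snr = Inf, seed = 1, dim = 32)
  m <- hm$half1
  f <- conical_fsc(m, m)
  # cutoffs at Nyquist pass the map through unchanged
  fny <- f; fny$resolution <- rep(2 * m$voxel_size, 13)
  out <- anisotropic_lowpass(m, fny, edge_width = 0)
  expect_lt(max(abs(out$data - m$data)) / max(abs(m$data)), 1e-6)
  # cutoffs below the first shell leave only the DC component
  fdc <- f; fdc$resolution <- rep(1 / (0.5 * f$shells[1]), 13)
  dc <- anisotropic_lowpass(m, fdc, edge_width = 0)
  expect_lt(max(abs(dc$data - mean(m$data))), 1e-9 * max(abs(m$data)))
  # isotropic cutoffs match the direct isotropic filter
  fiso <- f; fiso$resolution <- rep(7, 13)
  a <- anisotropic_lowpass(m, fiso, edge_width = 0)
  b <- isotropic_lowpass(m, 1 / 7, edge_width = 0)
  expect_lt(max(abs(a$data - b$data)) / max(abs(b$data)), 1e-6)
  # hard isotropic filtering is idempotent
  a2 <- anisotropic_lowpass(a, fiso, edge_width = 0)
  expect_lt(max(abs(a2$data - a$data)) / max(abs(a$data)), 1e-6)
  # missing resolutions are rejected
  fbad <- f; fbad$resolution[4] <- NA
  expect_error(anisotropic_lowpass(m, fbad), "missing")
})

test_that("MRC round trip preserves grid, voxel size and origin", {
  toy <- toy_system()
  m <- simulate_map(toy$structure, 8, 1.5)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  back <- read_mrc(f)
  expect_identical(dim(back$data), dim(m$data))
  expect_equal(back$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(back$origin, m$origin, tolerance = 1e-5)
  expect_lt(max(abs(back$data - m$data)), 1e-5 * max(abs(m$data)))
})

test_that("MRC output is readable by an independent parser", {
  tf <- withr::local_tempfile(fileext = ".mrc")
  toy <- toy_system()
  m <- simulate_map(toy$structure, 10, 2)
  write_mrc(m, tf)
  # header sanity via direct binary inspection
  con <- file(tf, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  expect_identical(hdr[1:3], dim(m$data))
  expect_identical(hdr[4], 2L)
  seek(con, 208)
  expect_identical(readChar(con, 4), "MAP ")
})
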