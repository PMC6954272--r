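# Independent oracles and fixture builders used across the suite.

# Kabsch minimum RMSD via SVD with the proper-rotation determinant
# correction -- independent of the package's QCP path.
kabsch_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  sv <- svd(crossprod(a, b))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(sum((a %*% R - b)^2) / nrow(a))
}

# Rodrigues rotation matrix about a unit axis (right-handed, +theta)
rodrigues_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(theta) * diag(3) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(u)
}

# random rigid transform applied to an N x 3 coordinate set
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- rodrigues_matrix(ax, runif(1, 0, 2 * pi))
  sweep(xyz %*% t(R), 2, rnorm(3, sd = 20), "+")
}

# toy system shared by many tests
toy_system <- function(...) make_toy_hinge_protein(...)

# ensemble of two conformational blobs around hinge rotations `centers`
# (degrees on the first phi), each blob = exact center plus symmetric
# +/- offsets, so the planted center is the within-blob medoid
blob_ensemble <- function(toy, centers = c(0, 90),
                          offsets = c(0.5, 1, 1.5, 2)) {
  s <- toy$structure
  h <- toy$hinge
  angs <- unlist(lapply(centers, function(c0)
    c(c0, c0 + offsets, c0 - offsets)))
  frames <- lapply(angs, function(a)
    get_xyz(apply_hinge_rotation(s, h, c(a, 0, 0, 0, 0, 0))))
  labels <- rep(seq_along(centers), each = 1 + 2 * length(offsets))
  centers_idx <- 1 + (seq_along(centers) - 1) * (1 + 2 * length(offsets))
  list(ensemble = new_ensemble(s, frames), labels = labels,
       center_frames = centers_idx)
}

# ensemble with two planted rotational modes of given amplitude ratio.
# The planted ground truth must be identifiable for PCA to recover it:
# the second mode's displacement field is orthogonalized against the
# first (Gram-Schmidt on the linearized fields), and the two amplitude
# series are empirically decorrelated, so the modes are independent by
# construction rather than only in expectation.
planted_mode_ensemble <- function(toy, n = 80, amp = c(3, 1), seed = 1) {
  set.seed(seed)
  s <- toy$structure
  h <- toy$hinge
  idx <- select_atoms(s, selection(resno = toy$mobile_residues,
                                   name = "CA"))
  x0 <- get_xyz(s)[idx, ]
  field <- function(d)
    as.vector(get_xyz(apply_hinge_rotation(s, h, d))[idx, ] - x0)
  f1 <- field(c(0, 0, 1, 0, 0, 0))   # phi of the middle hinge residue
  f2 <- field(c(0, 0, 0, 0, 1, 0))   # phi of the last hinge residue
  beta <- sum(f1 * f2) / sum(f1 * f1)
  m1 <- c(0, 0, 1, 0, 0, 0)
  m2 <- c(0, 0, -beta, 0, 1, 0)
  a1 <- runif(n, -amp[1], amp[1])
  a2 <- runif(n, -amp[2], amp[2])
  a1 <- a1 - mean(a1)
  a2 <- a2 - mean(a2)
  a2 <- a2 - a1 * sum(a1 * a2) / sum(a1^2)
  frames <- lapply(seq_len(n), function(i)
    get_xyz(apply_hinge_rotation(s, h, a1[i] * m1 + a2[i] * m2)))
  list(ensemble = new_ensemble(s, frames), a1 = a1, a2 = a2)
}

# ensemble whose closure-anchor distances are exactly `dists`, built by
# sliding the flanking scaffold along the anchor axis
anchored_distance_ensemble <- function(toy, dists) {
  s <- toy$structure
  ia <- select_atoms(s, toy$closure$anchor_a)
  ib <- select_atoms(s, toy$closure$anchor_b)
  scaf <- select_atoms(s, selection(resno = toy$scaffold2_residues))
  xyz <- get_xyz(s)
  u <- xyz[ib, ] - xyz[ia, ]
  d0 <- sqrt(sum(u^2))
  u <- u / d0
  frames <- lapply(dists, function(d) {
    x <- xyz
    x[scaf, ] <- sweep(x[scaf, , drop = FALSE], 2, (d - d0) * u, "+")
    x
  })
  new_ensemble(s, frames)
}
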