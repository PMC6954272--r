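#' Minimum RMSD by the quaternion characteristic polynomial (QCP) method
#'
#' Computes the least root-mean-square deviation between two point sets
#' over all proper rotations and translations, without constructing the
#' rotation: the largest eigenvalue of the quaternion key matrix is found
#' by Newton iteration on its quartic characteristic polynomial
#' (Theobald's method), and the RMSD follows from
#' `sqrt((Ga + Gb - 2*lambda_max) / N)`.  Reflections are never
#' considered, so mirror-image sets retain a non-zero RMSD.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (angstrom) with the
#'   same N.
#' @return the minimum RMSD in angstrom.
#' @export
qcp_rmsd <- function(coords_a, coords_b) {
  if (!is.matrix(coords_a) || !is.matrix(coords_b) ||
      ncol(coords_a) != 3L || ncol(coords_b) != 3L)
    stop("coordinates must be N x 3 matrices")
  n <- nrow(coords_a)
  if (nrow(coords_b) != n)
    stop("shape error: point counts differ (", n, " vs ", nrow(coords_b), ")")
  a <- sweep(coords_a, 2L, colMeans(coords_a))
  b <- sweep(coords_b, 2L, colMeans(coords_b))
  if (n < 3L) {
    warning("fewer than 3 points: rotation is degenerate, ",
            "translation-only minimum returned")
    return(sqrt(sum((a - b)^2) / n))
  }
  ga <- sum(a^2); gb <- sum(b^2)
  M <- crossprod(a, b)           # 3x3 inner-product matrix
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]

  Sxx2 <- Sxx^2; Syy2 <- Syy^2; Szz2 <- Szz^2
  Sxy2 <- Sxy^2; Syz2 <- Syz^2; Sxz2 <- Sxz^2
  Syx2 <- Syx^2; Szy2 <- Szy^2; Szx2 <- Szx^2

  SyzSzymSyySzz2 <- 2 * (Syz * Szy - Syy * Szz)
  Sxx2Syy2Szz2Syz2Szy2 <- Syy2 + Szz2 - Sxx2 + Syz2 + Szy2

  C2 <- -2 * (Sxx2 + Syy2 + Szz2 + Sxy2 + Syx2 + Sxz2 + Szx2 + Syz2 + Szy2)
  C1 <- 8 * (Sxx * Syz * Szy + Syy * Szx * Sxz + Szz * Sxy * Syx -
               Sxx * Syy * Szz - Syz * Szx * Sxy - Szy * Syx * Sxz)

  SxzpSzx <- Sxz + Szx; SyzpSzy <- Syz + Szy; SxypSyx <- Sxy + Syx
  SyzmSzy <- Syz - Szy; SxzmSzx <- Sxz - Szx; SxymSyx <- Sxy - Syx
  SxxpSyy <- Sxx + Syy; SxxmSyy <- Sxx - Syy

  C0 <- (Sxy2 + Sxz2 - Syx2 - Szx2)^2 +
    (Sxx2Syy2Szz2Syz2Szy2 + SyzSzymSyySzz2) *
    (Sxx2Syy2Szz2Syz2Szy2 - SyzSzymSyySzz2) +
    (-SxzpSzx * SyzmSzy + SxymSyx * (SxxmSyy - Szz)) *
    (-SxzmSzx * SyzpSzy + SxymSyx * (SxxmSyy + Szz)) +
    (-SxzpSzx * SyzpSzy - SxypSyx * (SxxpSyy - Szz)) *
    (-SxzmSzx * SyzmSzy - SxypSyx * (SxxpSyy + Szz)) +
    (SxypSyx * SyzpSzy + SxzpSzx * (SxxmSyy + Szz)) *
    (-SxymSyx * SyzmSzy + SxzpSzx * (SxxpSyy + Szz)) +
    (SxypSyx * SyzmSzy + SxzmSzx * (SxxmSyy - Szz)) *
    (-SxymSyx * SyzpSzy + SxzmSzx * (SxxpSyy - Szz))

  # Newton iteration from the upper bound lambda <= (Ga + Gb) / 2
  lambda <- (ga + gb) / 2
  for (i in 1:60) {
    l2 <- lambda * lambda
    p <- l2 * l2 + C2 * l2 + C1 * lambda + C0
    dp <- 4 * l2 * lambda + 2 * C2 * lambda + C1
    if (dp == 0) break
    step <- p / dp
    lambda <- lambda - step
    if (abs(step) < 1e-11 * abs(lambda) + 1e-14) break
  }
  sqrt(max(0, (ga + gb - 2 * lambda) / n))
}

#' Pairwise minimum-RMSD dissimilarity matrix
#'
#' Builds the symmetric n x n matrix of pairwise QCP RMSD values over a
#' selected atom subset (default: C-alpha atoms of the whole topology).
#'
#' @param e an `Ensemble`.
#' @param sel atom selection (`SelectionSpec` or index vector); default
#'   all C-alpha atoms.
#' @return a `DistanceMatrix`: the matrix with attribute `frame_index`.
#' @export
pairwise_rmsd_matrix <- function(e, sel = selection(name = "CA")) {
  idx <- select_atoms(e$topology, sel)
  if (!length(idx)) stop("selection error: empty atom selection")
  n <- n_frames(e)
  coords <- lapply(e$frames, function(x) x[idx, , drop = FALSE])
  d <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      ci <- coords[[i]]
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- qcp_rmsd(ci, coords[[j]])
      }
    }
  }
  structure(d, frame_index = e$meta$frame, class = c("DistanceMatrix",
                                                     "matrix", "array"))
}

# Kabsch superposition: rotation + translation mapping mov onto ref
# (proper rotation enforced via the SVD determinant correction).
kabsch_transform <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  H <- crossprod(sweep(mov, 2L, cm), sweep(ref, 2L, cr))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, ref_center = cr, mov_center = cm)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2L, tr$mov_center) %*% t(tr$R), 2L, tr$ref_center, "+")
}

#' Principal component analysis of a conformational ensemble
#'
#' Each frame is first rigidly superposed onto the topology on the
#' static-region selection, so that the decomposition sees internal
#' (mobile-domain) motion only; PCA is then performed on the flattened
#' Cartesian coordinates of the analysis selection.
#'
#' @param e an `Ensemble`.
#' @param sel analysis selection (default C-alpha atoms).
#' @param align_to static-region selection used for superposition; `NULL`
#'   skips alignment (frames already share a fixed scaffold).
#' @return a `PCAResult`: list with `components` (orthonormal columns),
#'   `variance_fraction`, `projections` (frames x components, centered)
#'   and `sdev`.
#' @export
ensemble_pca <- function(e, sel = selection(name = "CA"), align_to = NULL) {
  if (n_frames(e) < 2L) stop("rank error: need at least 2 frames for PCA")
  idx <- select_atoms(e$topology, sel)
  if (!length(idx)) stop("selection error: empty atom selection")
  frames <- e$frames
  if (!is.null(align_to)) {
    aidx <- select_atoms(e$topology, align_to)
    if (length(aidx) < 3L) stop("alignment selection needs >= 3 atoms")
    ref <- get_xyz(e$topology)[aidx, , drop = FALSE]
    frames <- lapply(frames, function(x) {
      tr <- kabsch_transform(ref, x[aidx, , drop = FALSE])
      apply_transform(x, tr)
    })
  }
  X <- t(vapply(frames, function(x) as.vector(t(x[idx, , drop = FALSE])),
                numeric(3L * length(idx))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(components = pc$rotation, variance_fraction = vf,
                 projections = pc$x, sdev = pc$sdev),
            class = "PCAResult")
}

#' Centroid-linkage (UPGMC) clustering of a dissimilarity matrix
#'
#' Agglomerative hierarchical clustering with the centroid linkage
#' criterion, cut at a fraction of the maximum merge distance.  Centroid
#' linkage is run on squared dissimilarities (the standard formulation);
#' merge heights are reported back on the RMSD scale.  Each flat cluster's
#' medoid (k-medoids with k = 1) is identified.
#'
#' @param d a `DistanceMatrix` (or plain symmetric matrix).
#' @param cutoff_fraction cut height as a fraction of the maximum merge
#'   distance, in (0, 1]; default 0.3.
#' @return a `ClusterResult`: list with `labels` (contiguous from 1, in
#'   order of first appearance), `medoids` (frame index per cluster),
#'   `cutoff` (absolute, RMSD scale), `cutoff_fraction`, `merge_heights`
#'   and the `hclust` object.
#' @export
cluster_upgmc <- function(d, cutoff_fraction = 0.3) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (cutoff_fraction <= 0 || cutoff_fraction > 1)
    stop("cutoff_fraction must be in (0, 1]")
  n <- nrow(d)
  if (n == 1L) {
    return(structure(list(labels = 1L, medoids = 1L, cutoff = 0,
                          cutoff_fraction = cutoff_fraction,
                          merge_heights = numeric(0), hclust = NULL),
                     class = "ClusterResult"))
  }
  hc <- stats::hclust(stats::as.dist(d^2), method = "centroid")
  heights <- sqrt(pmax(hc$height, 0))
  # centroid linkage can produce inversions; cut on the subtree-maximum
  # height so the flat clustering is well defined (distance criterion)
  eff <- heights
  for (i in seq_along(eff)) {
    ch <- hc$merge[i, ]
    eff[i] <- max(eff[i], eff[ch[ch > 0]])
  }
  dmax <- max(eff)
  cutoff <- cutoff_fraction * dmax
  raw <- flat_cut(hc$merge, eff, n, cutoff + 1e-12 * dmax)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  k <- max(labels)
  medoids <- vapply(seq_len(k), function(cl)
    medoid(which(labels == cl), d), integer(1))
  structure(list(labels = labels, medoids = medoids, cutoff = cutoff,
                 cutoff_fraction = cutoff_fraction,
                 merge_heights = heights, hclust = hc),
            class = "ClusterResult")
}

# flat clusters from a merge table: union the two children of every
# merge whose (monotonized) height is <= the cut
flat_cut <- function(merge, eff, n, cut) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_rep <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    ch <- merge[i, ]
    reps <- ifelse(ch < 0, -ch, node_rep[pmax(ch, 1L)])
    node_rep[i] <- find(reps[1L])
    if (eff[i] <= cut) {
      r1 <- find(reps[1L]); r2 <- find(reps[2L])
      parent[max(r1, r2)] <- min(r1, r2)
      node_rep[i] <- min(r1, r2)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Medoid of a frame subset
#'
#' The member minimizing the summed dissimilarity to its co-members
#' (k-medoids with k = 1); ties are broken by the lowest frame index.
#'
#' @param frames integer vector of frame indices (non-empty).
#' @param d dissimilarity matrix over all frames.
#' @return the medoid frame index.
#' @export
medoid <- function(frames, d) {
  if (!length(frames)) stop("empty frame set")
  sums <- rowSums(d[frames, frames, drop = FALSE])
  min(frames[sums <= min(sums)])  # lowest frame index among exact ties
}

#' Export a dendrogram as nested Newick-like text
#' @param cl a `ClusterResult` from [cluster_upgmc()].
#' @export
dendrogram_newick <- function(cl) {
  hc <- cl$hclust
  if (is.null(hc)) return("(1);")
  build <- function(i) {
    if (i < 0) return(as.character(-i))
    h <- sqrt(max(hc$height[i], 0))
    sprintf("(%s,%s):%.4f", build(hc$merge[i, 1]), build(hc$merge[i, 2]), h)
  }
  paste0(build(nrow(hc$merge)), ";")
}
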