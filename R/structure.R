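#' @keywords internal
"_PACKAGE"

#' Atomic structure container
#'
#' A `Structure` holds a fixed atom topology (serial, name, element, residue
#' number/name, chain, occupancy, B-factor) together with one or more
#' coordinate models sharing that topology.  Coordinates are Cartesian
#' angstroms in a right-handed frame.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `occupancy`, `b`.  Missing `occupancy`/`b`
#'   default to 1 and 0.
#' @param models list of N x 3 numeric matrices (one per coordinate model),
#'   all with the same row count as `atoms`.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, models) {
  stopifnot(is.data.frame(atoms), is.list(models), length(models) >= 1L)
  need <- c("serial", "name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  n <- nrow(atoms)
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      stop("model ", i, " is not an N x 3 matrix matching the atom table")
    if (!all(is.finite(m)))
      stop("model ", i, " contains non-finite coordinates")
    storage.mode(models[[i]]) <- "double"
    dimnames(models[[i]]) <- NULL
  }
  # residue numbering unique within a chain (per residue, not per atom)
  key <- unique(data.frame(chain = atoms$chain, resno = atoms$resno,
                           resname = atoms$resname))
  if (anyDuplicated(key[c("chain", "resno")]))
    stop("duplicate residue numbers within a chain")
  structure(list(atoms = atoms, models = models), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s), %d model(s)\n",
              n_atoms(x),
              nrow(unique(x$atoms[c("chain", "resno")])),
              length(unique(x$atoms$chain)), n_models(x)))
  invisible(x)
}

#' @rdname new_structure
#' @param s a `Structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' @rdname new_structure
#' @export
n_models <- function(s) length(s$models)

#' Extract a coordinate model
#'
#' @param s a `Structure`.
#' @param model model index (1-based).
#' @return N x 3 matrix of coordinates in angstrom.
#' @export
get_xyz <- function(s, model = 1L) {
  if (model < 1L || model > n_models(s)) stop("model index out of range")
  s$models[[model]]
}

#' Replace the coordinates of one model
#' @inheritParams get_xyz
#' @param xyz N x 3 replacement coordinates.
#' @export
set_xyz <- function(s, xyz, model = 1L) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L, nrow(xyz) == n_atoms(s),
            all(is.finite(xyz)))
  s$models[[model]] <- xyz
  s
}

#' Atom selection
#'
#' Builds a predicate over the atom table and returns the (order-preserving)
#' indices of matching atoms.  All supplied criteria are ANDed; `NULL`
#' criteria match everything.  A `selection()` object is just the stored
#' criteria; `select_atoms()` applies it.
#'
#' @param chain chain identifier(s).
#' @param resno residue numbers (any integer vector, e.g. `10:20`).
#' @param name atom name(s), e.g. `"CA"`.
#' @param element element symbol(s).
#' @return `selection()`: a `SelectionSpec`; `select_atoms()`: integer
#'   vector of atom indices (possibly empty).
#' @export
selection <- function(chain = NULL, resno = NULL, name = NULL,
                      element = NULL) {
  structure(list(chain = chain, resno = resno, name = name,
                 element = element), class = "SelectionSpec")
}

#' @rdname selection
#' @param s a `Structure`.
#' @param sel a `SelectionSpec` (or an integer index vector, passed through).
#' @export
select_atoms <- function(s, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "SelectionSpec"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain))   keep <- keep & a$chain   %in% sel$chain
  if (!is.null(sel$resno))   keep <- keep & a$resno   %in% sel$resno
  if (!is.null(sel$name))    keep <- keep & a$name    %in% sel$name
  if (!is.null(sel$element)) keep <- keep & a$element %in% sel$element
  which(keep)
}

#' Hinge specification for rigid-body dihedral sampling
#'
#' Defines the short backbone segment whose phi/psi dihedrals carry the
#' rigid-body motion of a downstream mobile domain, in the sense of
#' hinge-based kinase-domain sampling: the mobile domain and the hinge
#' residues (apart from the sampled dihedrals themselves) stay internally
#' rigid while the rest of the structure is held fixed.
#'
#' @param s the `Structure` the spec refers to (validated against).
#' @param chain chain holding the hinge.
#' @param hinge_residues inclusive residue-number range of the hinge
#'   (typically 3 residues, e.g. `326:328`).
#' @param mobile_residues residue numbers of the rigid mobile domain
#'   downstream of the hinge.
#' @param sampled_dihedrals data frame with columns `resno` and `dihedral`
#'   (`"phi"` or `"psi"`); default: all phi and psi of the hinge residues.
#' @return a `HingeSpec`.
#' @export
hinge_spec <- function(s, chain, hinge_residues, mobile_residues,
                       sampled_dihedrals = NULL) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  in_chain <- a$chain == chain
  if (!all(hinge_residues %in% a$resno[in_chain]))
    stop("hinge residues not all present in chain ", chain)
  mob_idx <- which(in_chain & a$resno %in% mobile_residues)
  hin_idx <- which(in_chain & a$resno %in% hinge_residues)
  if (length(intersect(mob_idx, hin_idx)))
    stop("mobile selection overlaps the hinge residues")
  if (is.null(sampled_dihedrals)) {
    sampled_dihedrals <- data.frame(
      resno = rep(sort(hinge_residues), each = 2L),
      dihedral = rep(c("phi", "psi"), length(hinge_residues)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(sampled_dihedrals$dihedral %in% c("phi", "psi")))
  h <- structure(list(chain = chain,
                      hinge_residues = sort(unique(hinge_residues)),
                      mobile_residues = sort(unique(mobile_residues)),
                      sampled_dihedrals = sampled_dihedrals),
                 class = "HingeSpec")
  # each sampled dihedral's four defining backbone atoms must exist
  for (k in seq_len(nrow(sampled_dihedrals)))
    dihedral_atoms(s, h, sampled_dihedrals$resno[k],
                   sampled_dihedrals$dihedral[k])
  h
}

# Indices of the four backbone atoms defining phi/psi of residue i:
#   phi(i): C(i-1), N(i), CA(i), C(i);  psi(i): N(i), CA(i), C(i), N(i+1)
dihedral_atoms <- function(s, h, resno, dihedral) {
  a <- s$atoms
  find1 <- function(rn, nm) {
    i <- which(a$chain == h$chain & a$resno == rn & a$name == nm)
    if (length(i) != 1L)
      stop(sprintf("dihedral %s of residue %d: backbone atom %s/%d %s",
                   dihedral, resno, nm, rn,
                   if (length(i)) "is duplicated" else "is missing"))
    i
  }
  if (dihedral == "phi")
    c(find1(resno - 1L, "C"), find1(resno, "N"),
      find1(resno, "CA"), find1(resno, "C"))
  else
    c(find1(resno, "N"), find1(resno, "CA"),
      find1(resno, "C"), find1(resno + 1L, "N"))
}

# Atoms carried by a rotation of the given hinge dihedral: the hinge-residue
# atoms C-terminal of the rotated bond, plus the entire mobile domain.  The
# remainder of the structure (including any scaffold that is C-terminal in
# sequence but held static) does not move.
moving_atoms <- function(s, h, resno, dihedral) {
  a <- s$atoms
  in_chain <- a$chain == h$chain
  hinge_after <- which(in_chain & a$resno %in% h$hinge_residues &
                         a$resno > resno)
  if (dihedral == "phi") {
    # rotation about N(i)-CA(i): carries CB, C, O of residue i
    own <- which(in_chain & a$resno == resno &
                   !(a$name %in% c("N", "CA", "H")))
  } else {
    # rotation about CA(i)-C(i): carries O of residue i
    own <- which(in_chain & a$resno == resno & a$name == "O")
  }
  mob <- which(in_chain & a$resno %in% h$mobile_residues)
  sort(unique(c(own, hinge_after, mob)))
}

# Rodrigues rotation of points about a unit axis through the origin.
rotate_about_axis <- function(xyz, axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  # cross-product matrix [u]x, filled column-major
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  R <- ct * diag(3) + st * K + (1 - ct) * tcrossprod(u)
  xyz %*% t(R)
}

#' Apply rigid-body hinge rotations
#'
#' Rotates each sampled dihedral by the given increment (degrees, IUPAC sign
#' convention: looking from the second to the third defining atom, positive
#' is clockwise i.e. right-handed about the bond vector).  Every atom
#' C-terminal of the rotated bond within the hinge, plus the whole mobile
#' domain, moves rigidly; static atoms are untouched.  Rotations are applied
#' in backbone (N- to C-terminal, phi-before-psi) order.
#'
#' @param s a `Structure`.
#' @param h a `HingeSpec`.
#' @param deltas numeric vector of rotation increments in degrees, one per
#'   row of `h$sampled_dihedrals`.
#' @param model model index to transform.
#' @return a `Structure` with the rotated coordinates in `model`.
#' @export
apply_hinge_rotation <- function(s, h, deltas, model = 1L) {
  sd <- h$sampled_dihedrals
  if (length(deltas) != nrow(sd))
    stop("deltas length (", length(deltas), ") does not match the ",
         nrow(sd), " sampled dihedrals")
  ord <- order(sd$resno, match(sd$dihedral, c("phi", "psi")))
  xyz <- get_xyz(s, model)
  for (k in ord) {
    if (deltas[k] == 0) next
    ai <- dihedral_atoms(s, h, sd$resno[k], sd$dihedral[k])
    mov <- moving_atoms(s, h, sd$resno[k], sd$dihedral[k])
    origin <- xyz[ai[2L], ]
    axis <- xyz[ai[3L], ] - origin
    shifted <- sweep(xyz[mov, , drop = FALSE], 2L, origin)
    # negative angle about the 2->3 bond vector increases the IUPAC
    # dihedral by +delta
    xyz[mov, ] <- sweep(rotate_about_axis(shifted, axis,
                                          -deltas[k] * pi / 180), 2L,
                        origin, "+")
  }
  set_xyz(s, xyz, model)
}

#' Measure a backbone dihedral angle
#'
#' @inheritParams apply_hinge_rotation
#' @param resno residue number.
#' @param dihedral `"phi"` or `"psi"`.
#' @return angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(s, h, resno, dihedral, model = 1L) {
  ai <- dihedral_atoms(s, h, resno, dihedral)
  xyz <- get_xyz(s, model)
  p <- xyz[ai, ]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Centroid of an atom selection
#' @param s a `Structure`.
#' @param sel a `SelectionSpec` or index vector.
#' @param model model index.
#' @export
centroid <- function(s, sel, model = 1L) {
  idx <- select_atoms(s, sel)
  if (!length(idx)) stop("empty selection")
  colMeans(get_xyz(s, model)[idx, , drop = FALSE])
}
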