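test_that("PDB writing and reading round-trip within format precision", {
  toy <- toy_system()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$structure, f)
  back <- read_pdb(f)
  expect_equal(n_atoms(back), n_atoms(toy$structure))
  expect_lt(max(abs(get_xyz(back) - get_xyz(toy$structure))), 1e-3)
  expect_identical(back$atoms$name, toy$structure$atoms$name)
  expect_identical(back$atoms$resno, toy$structure$atoms$resno)

  # one-atom file round-trips exactly at 3-decimal precision
  one <- new_structure(
    data.frame(serial = 1, name = "CA", element = "C", resno = 7,
               resname = "GLY", chain = "B"),
    list(matrix(c(1.125, -2.5, 300.001), 1, 3)))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(one, f1)
  r1 <- read_pdb(f1)
  expect_equal(get_xyz(r1), get_xyz(one), tolerance = 1e-9)
  expect_identical(r1$atoms$chain, "B")

  # multi-model round trip preserves every model
  multi <- new_structure(one$atoms,
                         list(get_xyz(one), get_xyz(one) + 1.5))
  fm <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(multi, fm)
  rm_ <- read_pdb(fm)
  expect_equal(n_models(rm_), 2L)
  expect_equal(get_xyz(rm_, 2), get_xyz(multi, 2), tolerance = 1e-9)
})

test_that("read_pdb agrees with an independent PDB parser", {
  skip_if_not_installed("bio3d")
  toy <- toy_system()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$structure, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE),
               read_pdb(f)$models[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("malformed and inconsistent PDB input is rejected with diagnostics", {
  bad <- c("ATOM      1  CA  ALA A   1      1.0x0   2.000   3.000  1.00  0.00           C")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 1.*x coordinate|malformed")

  # two models with different atom counts
  l1 <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  l2 <- "ATOM      2  CB  ALA A   1       2.000   2.000   3.000  1.00  0.00           C"
  fm <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", l1, l2, "ENDMDL",
               "MODEL     2", l1, "ENDMDL"), fm)
  expect_error(read_pdb(fm), "topology error")
})

test_that("write_pdb range-checks the fixed-width coordinate field", {
  one <- new_structure(
    data.frame(serial = 1, name = "CA", element = "C", resno = 1,
               resname = "ALA", chain = "A"),
    list(matrix(c(10000.5, 0, 0), 1, 3)))
  expect_error(write_pdb(one, withr::local_tempfile()), "range error")
  neg <- set_xyz(one, matrix(c(-1000.5, 0, 0), 1, 3))
  expect_error(write_pdb(neg, withr::local_tempfile()), "range error")

  # empty structure still produces a readable file with zero ATOM records
  empty <- structure(list(
    atoms = data.frame(serial = integer(), name = character(),
                       element = character(), resno = integer(),
                       resname = character(), chain = character(),
                       occupancy = numeric(), b = numeric()),
    models = list(matrix(numeric(), 0, 3))), class = "Structure")
  fe <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(empty, fe)
  expect_false(any(startsWith(readLines(fe), "ATOM")))
})

test_that("structure invariants are enforced", {
  # the same residue number used by two different residues in one chain
  a <- data.frame(serial = 1:2, name = c("CA", "CA"), element = "C",
                  resno = c(1L, 1L), resname = c("ALA", "GLY"),
                  chain = "A")
  expect_error(new_structure(a, list(matrix(0, 2, 3))),
               "duplicate residue")
  b <- data.frame(serial = 1, name = "CA", element = "C", resno = 1L,
                  resname = "ALA", chain = "A")
  expect_error(new_structure(b, list(matrix(c(NA, 0, 0), 1, 3))),
               "non-finite")
  expect_error(new_structure(b, list(matrix(0, 2, 3))), "N x 3")
})

test_that("selections are order-preserving and empty predicates match nothing", {
  toy <- toy_system()
  s <- toy$structure
  idx <- select_atoms(s, selection(name = "CA"))
  expect_identical(idx, sort(idx))
  expect_length(select_atoms(s, selection(chain = "Z")), 0)
  expect_length(select_atoms(s, selection(resno = 1:3, name = "CA")), 3)
})

test_that("hinge_spec validates residues, disjointness and dihedral atoms", {
  toy <- toy_system()
  s <- toy$structure
  expect_error(hinge_spec(s, "A", 900:902, toy$mobile_residues),
               "not all present")
  expect_error(hinge_spec(s, "A", toy$hinge_residues,
                          c(toy$hinge_residues[1], toy$mobile_residues)),
               "overlaps")
  # phi of the chain's first residue has no preceding C
  expect_error(hinge_spec(s, "A", 1:3, toy$mobile_residues,
                          data.frame(resno = 1L, dihedral = "phi")),
               "missing")
})

test_that("hinge rotation is an identity at zero and an involution at 180", {
  toy <- toy_system()
  s <- toy$structure
  h <- toy$hinge
  expect_identical(get_xyz(apply_hinge_rotation(s, h, rep(0, 6))),
                   get_xyz(s))
  twice <- apply_hinge_rotation(
    apply_hinge_rotation(s, h, c(0, 180, 0, 0, 0, 0)),
    h, c(0, 180, 0, 0, 0, 0))
  expect_lt(max(abs(get_xyz(twice) - get_xyz(s))), 1e-9)
})

test_that("rotations on one dihedral compose additively", {
  toy <- toy_system()
  s <- toy$structure
  h <- toy$hinge
  for (k in c(1L, 4L)) {
    d1 <- rep(0, 6); d1[k] <- 33
    d2 <- rep(0, 6); d2[k] <- -74
    d12 <- rep(0, 6); d12[k] <- 33 - 74
    a <- apply_hinge_rotation(apply_hinge_rotation(s, h, d1), h, d2)
    b <- apply_hinge_rotation(s, h, d12)
    expect_lt(max(abs(get_xyz(a) - get_xyz(b))), 1e-9)
  }
})

test_that("hinge rotation matches an explicit Rodrigues-matrix oracle", {
  toy <- toy_system()
  s <- toy$structure
  h <- toy$hinge
  res <- h$hinge_residues[2]
  ai <- csutools:::dihedral_atoms(s, h, res, "psi")
  xyz <- get_xyz(s)
  origin <- xyz[ai[2], ]
  axis <- xyz[ai[3], ] - origin
  # package convention: +delta increases the IUPAC dihedral, which is a
  # rotation by -delta about the 2->3 bond vector
  R <- rodrigues_matrix(axis, -90 * pi / 180)
  mov <- csutools:::moving_atoms(s, h, res, "psi")
  expected <- xyz
  expected[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, origin) %*%
                             t(R), 2, origin, "+")
  deltas <- rep(0, 6); deltas[4] <- 90   # psi of the middle hinge residue
  got <- get_xyz(apply_hinge_rotation(s, h, deltas))
  expect_lt(max(abs(got - expected)), 1e-9)
  # and the measured dihedral moves by +90 degrees
  d0 <- measure_dihedral(s, h, res, "psi")
  d1 <- measure_dihedral(apply_hinge_rotation(s, h, deltas), h, res, "psi")
  expect_equal(csutools:::wrap_angle(d1 - d0), 90, tolerance = 1e-9)
})

test_that("hinge rotation is an isometry of the mobile body and leaves the static region untouched", {
  toy <- toy_system()
  s <- toy$structure
  h <- toy$hinge
  mob <- select_atoms(s, selection(resno = h$mobile_residues))
  stat <- setdiff(seq_len(n_atoms(s)),
                  select_atoms(s, selection(
                    resno = c(h$mobile_residues, h$hinge_residues))))
  d0 <- dist(get_xyz(s)[mob, ])
  set.seed(4)
  for (i in 1:10) {
    rot <- apply_hinge_rotation(s, h, runif(6, -180, 180))
    expect_lt(max(abs(dist(get_xyz(rot)[mob, ]) - d0)), 1e-9)
    expect_identical(get_xyz(rot)[stat, ], get_xyz(s)[stat, ])
  }
})
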