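test_that("PDB writing and reading round-trips at format precision", {
  set.seed(31)
  a <- atom_set(chain = rep(c("A", "B"), each = 5), resno = rep(1:5, 2),
                resname = "GLY", atom = "CA",
                xyz = matrix(round(rnorm(30, 0, 20), 3), 10, 3))
  f <- tempfile(fileext = ".pdb")
  write_pdb(a, f)
  b <- read_pdb(f)
  expect_equal(b$xyz, a$xyz, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(b$records$chain, a$records$chain)
  expect_equal(b$records$resno, a$records$resno)
})

test_that("the parser enforces fixed-column semantics", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.104   6.134   1.759  1.00  0.00           C",
    "ATOM      2  CA  GLY B   2       1.000   2.000   3.000  1.00  0.00           C"), f)
  a <- read_pdb(f)
  expect_equal(nrow(a$xyz), 2)
  expect_equal(a$records$chain, c("A", "B"))
  expect_equal(a$xyz[1, ], c(11.104, 6.134, 1.759), ignore_attr = TRUE)

  writeLines(c("ATOM      1  CA  GLY A   1      11.104   6.134", "END"), f)
  expect_error(read_pdb(f), "line 1")

  writeLines("ATOM      1  CA AGLY A   1      11.104   6.134   1.759  1.00  0.00", f)
  expect_error(read_pdb(f), "alternate location")
})

test_that("the reader agrees with bio3d on a shared fixture", {
  a <- atom_set(chain = "A", resno = 1:4, resname = "ALA", atom = "CA",
                xyz = matrix(c(1.5, -2.25, 3.125, 4, 0, -7.5,
                               2, 3, 4, -1, -2, -3), 4, 3, byrow = TRUE))
  f <- tempfile(fileext = ".pdb")
  write_pdb(a, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE), a$xyz,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref$atom$resno, a$records$resno)
})

test_that("rigid transforms act as an isometry group", {
  set.seed(41)
  a <- atom_set(chain = "A", resno = 1:8, resname = "GLY", atom = "CA",
                xyz = matrix(rnorm(24), 8, 3))
  th <- 0.6; R1 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ph <- -1.1; R2 <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  t1 <- rigid_transform(R1, c(1, -2, 3)); t2 <- rigid_transform(R2, c(0, 5, -1))
  expect_equal(apply_transform(a, rigid_transform())$xyz, a$xyz)
  b <- apply_transform(a, t1)
  expect_lt(max(abs(dist(a$xyz) - dist(b$xyz))), 1e-9)
  # composition associativity / consistency
  c1 <- apply_transform(apply_transform(a, t1), t2)
  c2 <- apply_transform(a, compose_transform(t2, t1))
  expect_lt(max(abs(c1$xyz - c2$xyz)), 1e-9)
  # inverse restores coordinates
  back <- apply_transform(b, invert_transform(t1))
  expect_lt(max(abs(back$xyz - a$xyz)), 1e-9)
  # reflections are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "improper")
})

test_that("landmark sidecar mappings resolve records", {
  a <- atom_set(chain = c("A", "A", "B"), resno = c(21, 98, 21), resname = "GLY",
                atom = "CA", xyz = diag(3))
  map <- data.frame(label = c("arm", "dna"), ref = c("A:21", "A:98"))
  b <- read_landmarks(a, map)
  expect_equal(landmark_xyz(b, "arm"), c(1, 0, 0), ignore_attr = TRUE)
  expect_error(read_landmarks(a, data.frame(label = "x", ref = "C:5")), "not resolved")
})
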