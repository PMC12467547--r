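# closed-form element matrices of the unit right triangle (0,0),(1,0),(0,1):
# S = 1/2 * [[2,-1,-1],[-1,1,0],[-1,0,1]], B = A/6 on the diagonal, A/12 off
test_that("element matrices match the symbolic linear-FEM integrals", {
  tri <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1, 2, 3), 1))
  fem <- fem_matrices(tri)
  expect_equal(as.matrix(fem$S),
               0.5 * rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  A <- 0.5
  expect_equal(as.matrix(fem$B),
               matrix(A / 12, 3, 3) + diag(rep(A / 12, 3)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("assembled matrices satisfy the global FEM invariants", {
  for (n in c(34, 104)) {
    mesh <- fix_layout(n)
    fem <- fem_matrices(mesh)
    expect_lt(max(abs(Matrix::rowSums(fem$S))), 1e-12)
    expect_equal(sum(fem$B), mesh_area(mesh), tolerance = 1e-12)
    expect_equal(as.matrix(fem$S), t(as.matrix(fem$S)))
  }
  # degenerate triangle is reported with its index
  bad <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
              triangles = matrix(c(1L, 2L, 3L), 1), is_closed = FALSE)
  class(bad) <- "trimesh"
  expect_error(fem_matrices(bad), "triangle 1")
})

test_that("field energy is the B-quadratic form", {
  mesh <- fix_layout(104)
  fem <- fem_matrices(mesh)
  n <- nrow(mesh$vertices)
  # constant field c on area A -> c^2 A
  expect_equal(field_energy(rep(2.5, n), fem),
               2.5^2 * mesh_area(mesh), tolerance = 1e-12)
  expect_identical(field_energy(rep(0, n), fem), 0)
  set.seed(1)
  f <- rnorm(n)
  expect_gt(field_energy(f, fem), 0)
  expect_error(field_energy(rnorm(n - 1), fem), "dimension mismatch")
})

test_that("the generalized eigenbasis is B-orthonormal with tiny residuals", {
  mesh <- fix_layout(104)
  basis <- sphara_basis(mesh, 40)
  expect_equal(basis$tau, sort(basis$tau))
  expect_equal(basis$tau[1], 0, tolerance = 1e-10)
  # DC mode is the constant
  dc <- basis$vectors[, 1]
  expect_lt(sd(dc) / abs(mean(dc)), 1e-6)
  gram <- crossprod(basis$vectors, as.matrix(basis$B %*% basis$vectors))
  expect_lt(max(abs(gram - diag(40))), 1e-8)
  expect_lt(max(headspectra:::basis_residuals(basis)), 1e-6)
})

test_that("sphere eigenvalues converge to l(l+1)/R^2 and Jeans wavelengths", {
  basis <- sphara_basis(fix_unit_sphere(), 16)
  # first nonzero eigenvalue triple ~ 2 within 5%
  expect_equal(basis$tau[2:4], rep(2, 3), tolerance = 0.05)
  expect_equal(basis$tau[5:9], rep(6, 5), tolerance = 0.05)
  # discrete wavelengths sit slightly below the Jeans wavelength
  wl <- eigen_to_wave(basis$tau[2:4])$lambda
  jeans <- jeans_wavelength(1, 1)
  expect_equal(wl, rep(jeans, 3), tolerance = 0.05)
  expect_true(all(wl <= jeans))
})

test_that("analysis/synthesis is unitary on the full basis", {
  mesh <- fix_layout(34)
  basis <- sphara_basis(mesh)        # all 34 modes
  set.seed(7)
  f <- rnorm(34)
  co <- sphara_analyze(basis, f)
  # Parseval: sum of squared coefficients equals the B-energy
  expect_equal(sum(co^2), field_energy(f, basis$B), tolerance = 1e-10)
  expect_equal(sphara_synthesize(basis, co), f, tolerance = 1e-8)
  # unit coefficient for a basis vector
  e5 <- sphara_analyze(basis, basis$vectors[, 5])
  expect_equal(e5, replace(numeric(34), 5, 1), tolerance = 1e-8)
  expect_equal(sphara_analyze(basis, numeric(34)), numeric(34))
  # truncation is a B-orthogonal projection
  k <- 10
  fk <- sphara_synthesize(basis, co[1:k])
  resid <- f - fk
  expect_lt(max(abs(crossprod(basis$vectors[, 1:k],
                              as.matrix(basis$B %*% resid)))), 1e-10)
  expect_error(sphara_analyze(basis, rnorm(12)), "length")
  expect_error(sphara_synthesize(basis, rnorm(40)), "more coefficients")
})

test_that("eigenvalue-to-wave mapping follows the wavenumber relation", {
  w <- eigen_to_wave(c(0, 1e-4, 4))
  expect_identical(w$lambda[1], Inf)
  expect_equal(w$k, c(0, 0.01, 2))
  expect_equal(w$omega, w$k / (2 * pi))
  expect_equal(w$lambda[2], 2 * pi / 0.01)
  expect_equal(w$k, sqrt(w$tau))
  expect_error(eigen_to_wave(-1), "non-negative")
})

test_that("open meshes give a valid basis with a near-zero DC eigenvalue", {
  cap <- extract_cap(fix_layout(232), c(0, 0, 1), 100)
  basis <- sphara_basis(cap, 20)
  expect_equal(basis$tau[1], 0, tolerance = 1e-10)
  expect_gt(basis$tau[2], 1e-6)
  expect_lt(max(headspectra:::basis_residuals(basis)), 1e-6)
  gram <- crossprod(basis$vectors, as.matrix(basis$B %*% basis$vectors))
  expect_lt(max(abs(gram - diag(20))), 1e-8)
})

test_that("mode-degree grouping forms 2l+1 blocks after DC", {
  expect_identical(mode_degrees(9), c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
  expect_identical(mode_degrees(5, l_max = 1), c(0L, 1L, 1L, 1L, NA_integer_))
  expect_equal(sum(mode_degrees(256) <= 15), 256)
})

test_that("a basis round-trips through its text export", {
  mesh <- fix_layout(34)
  basis <- sphara_basis(mesh, 10)
  base <- withr::local_tempfile()
  write_sphara_basis(basis, base)
  v2 <- as.matrix(utils::read.table(paste0(base, ".tsv"), sep = "\t"))
  expect_equal(unname(v2), unname(basis$vectors), tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(meta$tau, basis$tau, tolerance = 1e-12)
  expect_equal(meta$n_modes, 10)
})
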