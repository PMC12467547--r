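#' Sphara basis: Laplace-Beltrami eigenbasis of a sensor mesh
#'
#' Solves the generalized symmetric eigenproblem `S x = tau B x` of the
#' linear-FEM Laplace-Beltrami discretisation and returns the `n_modes`
#' lowest-frequency eigenpairs: ascending eigenvalues `tau` (mm^-2) and
#' B-orthonormal eigenvectors. On a connected mesh the first mode is the
#' constant (DC) mode with `tau ~ 0`; for an open mesh the natural (Neumann)
#' boundary conditions are implied by the FEM assembly, and the DC mode is
#' retained.
#'
#' The problem is reduced to a dense standard symmetric eigenproblem through
#' a Cholesky factorisation of `B` (`B = R'R`, `C = R^-T S R^-1`), which
#' yields exactly B-orthonormal vectors and is robust for the mesh sizes
#' used here (up to a few thousand vertices). Eigenvector signs are fixed so
#' the entry of largest magnitude is positive, making spectra reproducible
#' across solvers.
#'
#' @param x a [fem_matrices()] object or a [trimesh()].
#' @param n_modes number of modes to retain (default: all).
#' @return object of class `sphara_basis`: `tau` (ascending eigenvalues),
#'   `vectors` (n x n_modes, B-orthonormal), `B`, `S`, `mesh`.
#' @export
sphara_basis <- function(x, n_modes = NULL) {
  fem <- if (inherits(x, "trimesh")) fem_matrices(x) else x
  if (!inherits(fem, "fem_matrices")) stop("`x` must be a trimesh or fem_matrices")
  n <- nrow(fem$B)
  if (is.null(n_modes)) n_modes <- n
  if (n_modes > n) stop("`n_modes` cannot exceed the number of vertices")

  Bd <- as.matrix(fem$B)
  Sd <- as.matrix(fem$S)
  R <- tryCatch(chol(Bd), error = function(e)
    stop("mass matrix is not positive definite: ", conditionMessage(e)))
  # C = R^-T S R^-1, symmetric
  M1 <- backsolve(R, Sd, transpose = TRUE)
  C <- backsolve(R, t(M1), transpose = TRUE)
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  idx <- rev(seq(n - n_modes + 1, n)) # ascending order
  tau <- eig$values[idx]
  y <- eig$vectors[, idx, drop = FALSE]
  vec <- backsolve(R, y)

  # clamp the numerically-zero DC eigenvalue; fail on genuinely negative ones
  neg <- tau < 0
  if (any(tau < -1e-8 * max(abs(tau))))
    stop("eigensolver returned significantly negative eigenvalues")
  tau[neg] <- 0

  # deterministic sign: largest-magnitude entry positive
  flip <- vapply(seq_len(ncol(vec)), function(j) {
    v <- vec[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  vec <- sweep(vec, 2, ifelse(flip < 0, -1, 1), `*`)

  structure(
    list(tau = tau, vectors = vec, B = fem$B, S = fem$S, mesh = fem$mesh),
    class = "sphara_basis"
  )
}

#' @export
print.sphara_basis <- function(x, ...) {
  cat(sprintf("<sphara_basis> %d modes on %d vertices; tau in [%.3g, %.3g] mm^-2\n",
              length(x$tau), nrow(x$vectors), min(x$tau), max(x$tau)))
  invisible(x)
}

#' Analysis transform: field to Sphara coefficients
#'
#' Projects a vertex-sampled field onto the basis using the B-inner product,
#' `c_i = f' B x_i`. With all modes retained the transform is unitary:
#' `sum c_i^2` equals the discrete surface energy `f' B f`.
#'
#' @param basis a [sphara_basis()].
#' @param f numeric vector of length n, or n x k matrix of fields.
#' @return numeric vector (or matrix) of coefficients, one per mode.
#' @export
sphara_analyze <- function(basis, f) {
  f <- as.matrix(f)
  if (nrow(f) != nrow(basis$vectors))
    stop("field length does not match the basis mesh")
  out <- crossprod(basis$vectors, as.matrix(basis$B %*% f))
  if (ncol(out) == 1) drop(out) else out
}

#' Synthesis transform: Sphara coefficients to field
#'
#' Inverse of [sphara_analyze()]: `f = sum c_i x_i`. With fewer coefficients
#' than modes the result is the B-orthogonal projection onto the leading
#' subspace.
#'
#' @param basis a [sphara_basis()].
#' @param coefficients numeric vector (length <= n_modes) or matrix.
#' @return vertex-sampled field (vector or matrix).
#' @export
sphara_synthesize <- function(basis, coefficients) {
  coefficients <- as.matrix(coefficients)
  k <- nrow(coefficients)
  if (k > ncol(basis$vectors))
    stop("more coefficients than modes in the basis")
  out <- basis$vectors[, seq_len(k), drop = FALSE] %*% coefficients
  if (ncol(out) == 1) drop(out) else out
}

#' Eigenvalue to spatial wave quantities
#'
#' Maps a Laplace-Beltrami eigenvalue `tau` (mm^-2) to the spatial
#' wavenumber `k = sqrt(tau)` (rad/mm), frequency `omega = k / (2 pi)`
#' (1/mm) and wavelength `lambda = 2 pi / k` (mm, `Inf` for the DC mode).
#'
#' @param tau numeric vector of eigenvalues (>= 0).
#' @return tibble with columns `tau`, `k`, `omega`, `lambda`.
#' @export
eigen_to_wave <- function(tau) {
  if (any(tau < 0)) stop("`tau` must be non-negative")
  k <- sqrt(tau)
  tibble::tibble(
    tau = tau,
    k = k,
    omega = k / (2 * pi),
    lambda = ifelse(k == 0, Inf, 2 * pi / k)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Sphara basis into one row per mode
#'
#' @param x a [sphara_basis()].
#' @param ... unused.
#' @return tibble with `mode` (1-based, mode 1 = DC), `tau`, `k`, `omega`,
#'   `lambda`.
#' @export
tidy.sphara_basis <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mode = seq_along(x$tau)), eigen_to_wave(x$tau))
}

#' One-row summary of a Sphara basis
#'
#' @param x a [sphara_basis()].
#' @param ... unused.
#' @return tibble with vertex/mode counts, the largest generalized-eigenpair
#'   residual and the worst B-orthonormality error.
#' @export
glance.sphara_basis <- function(x, ...) {
  res <- basis_residuals(x)
  gram <- crossprod(x$vectors, as.matrix(x$B %*% x$vectors))
  tibble::tibble(
    n_vertices = nrow(x$vectors),
    n_modes = length(x$tau),
    max_residual = max(res),
    max_orthonormality_error = max(abs(gram - diag(ncol(gram))))
  )
}

# relative residuals ||S x - tau B x|| / ||B x|| per mode
basis_residuals <- function(basis) {
  sx <- as.matrix(basis$S %*% basis$vectors)
  bx <- as.matrix(basis$B %*% basis$vectors)
  num <- sqrt(colSums((sx - sweep(bx, 2, basis$tau, `*`))^2))
  den <- sqrt(colSums(bx^2))
  num / den
}

#' Group Sphara modes by equivalent spherical-harmonic degree
#'
#' After skipping the DC mode, consecutive blocks of `2l+1` modes are mapped
#' to degree `l`. On a sphere this matches the degenerate Laplace-Beltrami
#' spectrum exactly; on other surfaces it is an approximation.
#'
#' @param n_modes number of modes to label.
#' @param l_max largest degree to assign; later modes get `NA`.
#' @return integer vector of degrees (`0` for DC), length `n_modes`.
#' @export
mode_degrees <- function(n_modes, l_max = NULL) {
  deg <- integer(0)
  l <- 0L
  while (length(deg) < n_modes) {
    deg <- c(deg, rep(l, 2L * l + 1L))
    l <- l + 1L
  }
  deg <- deg[seq_len(n_modes)]
  if (!is.null(l_max)) deg[deg > l_max] <- NA_integer_
  deg
}

#' Export / import a Sphara basis as delimited text
#'
#' The eigenvector matrix is written as tab-separated text alongside a JSON
#' sidecar holding the eigenvalues, mode count and a hash of the mesh.
#'
#' @param basis a [sphara_basis()].
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return invisibly, the two file paths.
#' @export
write_sphara_basis <- function(basis, path) {
  tsv <- paste0(path, ".tsv")
  meta <- paste0(path, ".json")
  utils::write.table(format(basis$vectors, digits = 17), tsv, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      n_modes = length(basis$tau),
      n_vertices = nrow(basis$vectors),
      tau = basis$tau,
      mesh_hash = mesh_hash(basis$mesh)
    ),
    meta, digits = NA, auto_unbox = TRUE
  )
  invisible(c(tsv, meta))
}

mesh_hash <- function(mesh) {
  v <- round(mesh$vertices, 9)
  sum(abs(v)) + 1e-3 * nrow(mesh$triangles) + sum(mesh$triangles %% 97)
}
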