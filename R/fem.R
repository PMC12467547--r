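#' Linear-FEM mass and stiffness matrices of a triangle mesh
#'
#' Assembles the cotangent stiffness matrix `S` and the consistent linear-FEM
#' mass matrix `B` of the Laplace-Beltrami operator discretised with
#' piecewise linear elements on a triangle mesh. Per triangle of area `A`,
#' the mass contributes `A/6` to each diagonal entry and `A/12` to each
#' off-diagonal pair; the stiffness contributes `cot(angle opposite edge)/2`
#' off-diagonal (negated) with compensating diagonal.
#'
#' `S` is symmetric positive semi-definite with the constants in its null
#' space (zero row sums); `B` is symmetric positive definite and its entries
#' sum to the total surface area.
#'
#' @param mesh a [trimesh()] (closed or open).
#' @return list of class `fem_matrices` with sparse matrices `S` (1/dim-less,
#'   units mm^0) and `B` (mm^2), plus the `mesh`.
#' @export
fem_matrices <- function(mesh) {
  if (!inherits(mesh, "trimesh")) stop("`mesh` must be a trimesh")
  v <- mesh$vertices
  tri <- mesh$triangles
  n <- nrow(v)
  m <- nrow(tri)

  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  e1 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE] # opposite vertex 1
  e2 <- v[i1, , drop = FALSE] - v[i3, , drop = FALSE]
  e3 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  cr <- cbind(
    e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
    e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
    e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  )
  area2 <- sqrt(rowSums(cr^2)) # twice the triangle area
  if (any(area2 <= 0 | !is.finite(area2))) {
    bad <- which(area2 <= 0 | !is.finite(area2))[1]
    stop(sprintf("assembly error: triangle %d has zero area", bad))
  }
  area <- area2 / 2

  # cot of the angle at vertex k = (e_i . e_j) / (2 A), signs per convention
  cot1 <- -rowSums(e2 * e3) / area2
  cot2 <- -rowSums(e3 * e1) / area2
  cot3 <- -rowSums(e1 * e2) / area2

  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ss <- -0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = ss, dims = c(n, n))
  Matrix::diag(S) <- -Matrix::rowSums(S)

  bb <- c(rep(area / 12, 6), rep(area / 6, 3))
  B <- Matrix::sparseMatrix(
    i = c(ii, i1, i2, i3), j = c(jj, i1, i2, i3), x = bb, dims = c(n, n)
  )

  structure(list(S = S, B = B, mesh = mesh), class = "fem_matrices")
}

#' @export
print.fem_matrices <- function(x, ...) {
  cat(sprintf("<fem_matrices> n = %d, total area = %.3f mm^2\n",
              nrow(x$B), sum(x$B)))
  invisible(x)
}

#' Discrete surface energy of a vertex-sampled field
#'
#' Quadratic form `f' B f`: the linear-FEM approximation of the surface
#' integral of the squared field, the discrete counterpart of the exact
#' surface energy of the forward model.
#'
#' @param f numeric vector (length n) or n x k matrix of vertex-sampled
#'   fields.
#' @param B mass matrix (n x n), or a `fem_matrices` / `sphara_basis` object
#'   carrying one.
#' @return scalar energy (or length-k vector for a matrix input).
#' @export
field_energy <- function(f, B) {
  if (inherits(B, "fem_matrices")) B <- B$B
  if (inherits(B, "sphara_basis")) B <- B$B
  f <- as.matrix(f)
  if (nrow(f) != nrow(B)) stop("dimension mismatch between field and mass matrix")
  drop(colSums(f * as.matrix(B %*% f)))
}
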