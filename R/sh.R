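#' Real spherical harmonics (geodesy 4pi normalization)
#'
#' Real-valued spherical harmonics `Y_lm(theta, phi)` with the geodesy
#' `4 pi` normalization and no Condon-Shortley phase: the normalized
#' associated Legendre function is
#' `Pbar_lm = sqrt((2 - delta_0m)(2l+1)(l-m)!/(l+m)!) P_lm`, and
#' `Y_lm = Pbar_lm(cos theta) cos(m phi)` for `m >= 0`,
#' `Y_l,-m = Pbar_l|m|(cos theta) sin(|m| phi)` for `m < 0`. With this
#' convention `(1/4pi) int Y_lm Y_l'm' dOmega = delta_ll' delta_mm'`.
#'
#' @param l degree (scalar >= 0).
#' @param m order, `-l <= m <= l` (scalar).
#' @param theta colatitude in radians (vector).
#' @param phi longitude in radians (vector, recycled against theta).
#' @return numeric vector of function values.
#' @export
real_sh <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("|m| must not exceed l")
  am <- abs(m)
  p <- normalized_legendre(l, cos(theta))[am + 1, ]
  if (m >= 0) p * cos(m * phi) else p * sin(am * phi)
}

# Pbar_l0..Pbar_ll at x: (l+1) x length(x) matrix, geodesy 4pi convention,
# no Condon-Shortley phase
normalized_legendre <- function(l, x) {
  if (l == 0) return(matrix(1, 1, length(x)))
  p <- pracma::legendre(l, x)             # MATLAB convention, CS phase
  m <- 0:l
  norm <- sqrt((2 - (m == 0)) * (2 * l + 1) *
                 exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  ((-1)^m * norm) * p
}

#' Spherical-harmonic design matrix
#'
#' Basis values at scattered points for all `(l, m)` with `l <= l_max`,
#' column order `(0,0), (1,-1), (1,0), (1,1), (2,-2), ...`.
#'
#' @param points n x 3 matrix on a sphere (any radius).
#' @param l_max maximum degree.
#' @return list with `G` (n x (l_max+1)^2 matrix), `l`, `m` (column labels).
#' @export
sh_design_matrix <- function(points, l_max) {
  points <- as.matrix(points)
  r <- sqrt(rowSums(points^2))
  theta <- acos(pmin(1, pmax(-1, points[, 3] / r)))
  phi <- atan2(points[, 2], points[, 1])
  nc <- (l_max + 1)^2
  G <- matrix(0, nrow(points), nc)
  ls <- integer(nc)
  ms <- integer(nc)
  j <- 1L
  for (l in 0:l_max) {
    p <- normalized_legendre(l, cos(theta))
    for (m in -l:l) {
      am <- abs(m)
      G[, j] <- if (m >= 0) p[am + 1, ] * cos(m * phi) else p[am + 1, ] * sin(am * phi)
      ls[j] <- l
      ms[j] <- m
      j <- j + 1L
    }
  }
  list(G = G, l = ls, m = ms)
}

#' Least-squares spherical-harmonic expansion
#'
#' Fits coefficients `F_lm` to scattered samples on a sphere by ordinary
#' least squares over all harmonics of degree `<= l_max`, using a
#' rank-revealing QR factorisation (no regularisation). The system must be
#' overdetermined: `n >= (l_max + 1)^2`; for equidistant layouts the
#' resolvable degree is bounded by [sampling_bounds()]'s `l_up`.
#'
#' @param points n x 3 matrix on a sphere.
#' @param values numeric vector of samples (length n) or n x k matrix.
#' @param l_max maximum degree of the fit.
#' @return For vector input, a tibble with columns `l`, `m`, `flm`
#'   (class `sh_coefficients`); for matrix input a `(l_max+1)^2 x k`
#'   coefficient matrix with attributes `l` and `m`.
#' @export
sh_expand_lsq <- function(points, values, l_max) {
  points <- as.matrix(points)
  vals <- as.matrix(values)
  nb <- (l_max + 1)^2
  if (nrow(points) < nb)
    stop(sprintf(
      "underdetermined system: %d points cannot resolve l_max = %d; need l_max <= %d",
      nrow(points), l_max, sampling_bounds(n = nrow(points))$l_up))
  des <- sh_design_matrix(points, l_max)
  qrG <- qr(des$G)
  if (qrG$rank < nb)
    warning(sprintf("rank-deficient design matrix: rank %d < %d columns",
                    qrG$rank, nb))
  coef <- qr.coef(qrG, vals)
  coef[is.na(coef)] <- 0
  if (ncol(vals) == 1 && !is.matrix(values)) {
    out <- tibble::tibble(l = des$l, m = des$m, flm = drop(coef))
    class(out) <- c("sh_coefficients", class(out))
    out
  } else {
    attr(coef, "l") <- des$l
    attr(coef, "m") <- des$m
    coef
  }
}

#' Evaluate a spherical-harmonic expansion at points
#'
#' @param coefficients an `sh_coefficients` tibble from [sh_expand_lsq()]
#'   (columns `l`, `m`, `flm`).
#' @param points n x 3 matrix on a sphere.
#' @return numeric vector of synthesised values.
#' @export
sh_synthesize <- function(coefficients, points) {
  l_max <- max(coefficients$l)
  des <- sh_design_matrix(points, l_max)
  key_in <- paste(coefficients$l, coefficients$m)
  key_des <- paste(des$l, des$m)
  f <- numeric(length(key_des))
  f[match(key_in, key_des)] <- coefficients$flm
  drop(des$G %*% f)
}

#' Jeans relation: degree to Cartesian wavelength
#'
#' Equivalent spatial wavelength of spherical harmonics of degree `l` on a
#' sphere of radius `R`: `lambda = 2 pi R / sqrt(l (l + 1))`. Degree 0 is
#' the spatial DC component with infinite wavelength.
#'
#' @param l degree vector (>= 0).
#' @param radius sphere radius in mm.
#' @return wavelengths in mm (`Inf` at `l = 0`).
#' @export
jeans_wavelength <- function(l, radius) {
  if (any(l < 0)) stop("`l` must be >= 0")
  if (radius <= 0) stop("`radius` must be positive")
  ifelse(l == 0, Inf, 2 * pi * radius / sqrt(l * (l + 1)))
}

#' Sampling bounds for discrete spherical harmonics
#'
#' Classical point counts needed to resolve degree `l`: Gauss-Legendre
#' quadrature grids use `N_GLQ = (l+1)(2l+1)` points and Driscoll-Healy
#' regular grids `N_DH = (2l+2)^2`. Conversely, for `n` scattered
#' (approximately equidistant) samples the resolvable degree is bounded by
#' `l_up = floor(sqrt(n/2) - 1)`, the inversion of the GLQ count
#' `N ~ 2 l^2`.
#'
#' @param l degree (optional).
#' @param n number of sampling points (optional).
#' @return one-row tibble with whichever of `n_glq`, `n_dh`, `l_up` apply.
#' @export
sampling_bounds <- function(l = NULL, n = NULL) {
  pieces <- list()
  if (!is.null(l)) {
    if (any(l < 0)) stop("`l` must be >= 0")
    pieces$l <- l
    pieces$n_glq <- (l + 1) * (2 * l + 1)
    pieces$n_dh <- (2 * l + 2)^2
  }
  if (!is.null(n)) {
    if (any(n < 2)) stop("`n` must be >= 2")
    pieces$n <- n
    pieces$l_up <- as.integer(floor(sqrt(n / 2) - 1))
  }
  if (!length(pieces)) stop("supply `l`, `n`, or both")
  tibble::as_tibble(pieces)
}
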