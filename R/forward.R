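#' Four-shell series factor C(l)
#'
#' Per-degree factor of the Legendre-series solution for the scalp potential
#' of a current dipole in a four-shell concentric spherical conductor. The
#' factor is computed from the standard multilayer boundary-value problem
#' (continuity of potential and of radial current density at the three inner
#' interfaces, zero radial current at the outer surface) written as a product
#' of 2 x 2 interface/propagation matrices. All radius powers enter as ratios
#' `(Ri/Rj)^(2l+1) <= 1`, so the evaluation is stable up to `l = 600` and
#' beyond. In the homogeneous limit (all conductivities equal) the factor
#' reduces exactly to `(2l+1)^3`.
#'
#' @param l vector of series degrees (>= 1).
#' @param model a [shell_model()].
#' @return numeric vector of positive factors, dimensionless.
#' @export
C_of_l <- function(l, model = shell_model()) {
  if (any(l < 1)) stop("`l` must be >= 1")
  l <- as.numeric(l)
  R <- model$radii
  k <- model$k
  vapply(l, function(n) {
    m <- function(kk) {
      matrix(c(n * kk + n + 1, (n + 1) * (1 - kk),
               n * (1 - kk), (n + 1) * kk + n), 2, 2, byrow = TRUE) / (2 * n + 1)
    }
    d <- function(ra, rb) diag(c(1, (ra / rb)^(2 * n + 1)))
    tr <- d(R[3], R[4]) %*% m(k[3]) %*% d(R[2], R[3]) %*% m(k[2]) %*%
      d(R[1], R[2]) %*% m(k[1])
    # the surface amplitude combines the transfer entries with the outer
    # Neumann condition; using det(T) = k1 k2 k3 (R1/R4)^(2n+1) exactly, the
    # factor collapses to a cancellation-free form (homogeneous limit:
    # T21 = 0, T11 = 1 gives (2n+1)^3)
    out <- (2 * n + 1)^3 * (n * tr[1, 1] - (n + 1) * tr[2, 1]) / n
    if (!is.finite(out) || out <= 0)
      stop(sprintf("numeric failure evaluating C(l) at l = %d", n))
    out
  }, numeric(1))
}

# prefactor 1/(4 pi sigma4 R4^2), radii converted mm -> m so potentials are
# volts for a 1 A*m moment
forward_prefactor <- function(model) {
  r4 <- model$radii[4] * 1e-3
  1 / (4 * pi * model$conductivities[4] * r4^2)
}

# per-degree series amplitude (2l+1)^4 f^(l-1) / C(l); f^0 := 1 at f = 0
series_amplitude <- function(l, f, model) {
  (2 * l + 1)^4 * ifelse(l == 1, 1, f^(l - 1)) / C_of_l(l, model)
}

check_on_outer_surface <- function(points, model) {
  r <- sqrt(rowSums(points^2))
  if (any(abs(r - model$radii[4]) > 1e-6 * model$radii[4]))
    stop("surface points must lie on the outer shell R4")
  invisible(r)
}

#' Single series term of the dipole potential
#'
#' The degree-`l` term of the Legendre-series scalp potential for a dipole in
#' canonical position (on the +z axis; use [rotate_to_canonical()] first).
#' The z moment component multiplies `P_l(cos theta)`; the x and y components
#' multiply `P_l^1(cos theta) cos(phi)` and `P_l^1(cos theta) sin(phi)`
#' divided by `l`.
#'
#' @param l series degree (scalar, >= 1).
#' @param d a canonical-frame [dipole()].
#' @param model a [shell_model()].
#' @param surface_points n x 3 matrix of points on the outer surface R4 (mm),
#'   in the canonical frame.
#' @return numeric vector of potentials (volts for a unit 1 A*m moment).
#' @export
term_potential <- function(l, d, model, surface_points) {
  stopifnot(length(l) == 1, l >= 1)
  surface_points <- as.matrix(surface_points)
  check_on_outer_surface(surface_points, model)
  ct <- pmin(1, pmax(-1, surface_points[, 3] / sqrt(rowSums(surface_points^2))))
  phi <- atan2(surface_points[, 2], surface_points[, 1])
  pl <- legendre_pl(l, ct)
  pl1 <- legendre_pl1(l, ct)
  amp <- forward_prefactor(model) * series_amplitude(l, d$f, model)
  mom <- d$moment
  amp * (mom[3] * pl[l + 1, ] +
           (mom[1] * cos(phi) + mom[2] * sin(phi)) * pl1[l, ] / l)
}

# Legendre polynomials P_0..P_lmax at x; (lmax+1) x length(x) matrix
legendre_pl <- function(lmax, x) {
  out <- matrix(0, lmax + 1, length(x))
  out[1, ] <- 1
  if (lmax >= 1) out[2, ] <- x
  if (lmax >= 2) {
    for (n in 2:lmax) {
      out[n + 1, ] <- ((2 * n - 1) * x * out[n, ] - (n - 1) * out[n - 1, ]) / n
    }
  }
  out
}

# first-order associated Legendre P_1^1..P_lmax^1 (no Condon-Shortley phase);
# lmax x length(x) matrix
legendre_pl1 <- function(lmax, x) {
  out <- matrix(0, lmax, length(x))
  s <- sqrt(pmax(0, 1 - x^2))
  out[1, ] <- s
  if (lmax >= 2) out[2, ] <- 3 * x * s
  if (lmax >= 3) {
    for (n in 3:lmax) {
      out[n, ] <- ((2 * n - 1) * x * out[n - 1, ] - n * out[n - 2, ]) / (n - 1)
    }
  }
  out
}

#' Closed-form surface energy of a single series term
#'
#' Exact surface integral of the squared degree-`l` potential term over the
#' outer sphere, using the Legendre orthogonality integrals
#' `int P_l^2 dOmega = 4 pi / (2l+1)` and
#' `int (P_l^1)^2 sin(theta) dtheta dphi * int cos^2 = 2 pi l(l+1)/(2l+1)`.
#' Because terms of distinct degree are orthogonal on the sphere, these
#' energies are additive and give the total surface energy without any
#' discretisation of the surface.
#'
#' @param l vector of degrees (>= 1).
#' @param d a [dipole()] (any frame; rotated internally).
#' @param model a [shell_model()].
#' @return numeric vector of energies (V^2 m^2 for a unit moment).
#' @export
term_energy <- function(l, d, model = shell_model()) {
  if (any(l < 1)) stop("`l` must be >= 1")
  dc <- rotate_to_canonical(d, model)$dipole
  r4 <- model$radii[4] * 1e-3
  amp <- forward_prefactor(model) * series_amplitude(l, dc$f, model)
  mom <- dc$moment
  r4^2 * amp^2 * (
    mom[3]^2 * 4 * pi / (2 * l + 1) +
      (mom[1]^2 + mom[2]^2) / l^2 * 2 * pi * l * (l + 1) / (2 * l + 1)
  )
}

#' Total surface energy of a dipole's scalp potential
#'
#' Sum of closed-form per-term energies until the running term falls below
#' `tol` times the accumulated energy (or `l_max_cap` is reached).
#'
#' @inheritParams term_energy
#' @param tol relative per-term energy tolerance.
#' @param l_max_cap hard cap on the series degree.
#' @return scalar energy with attributes `l_used` and `converged`.
#' @export
total_surface_energy <- function(d, model = shell_model(), tol = 1e-10,
                                 l_max_cap = 600L) {
  dc <- rotate_to_canonical(d, model)$dipole
  if (dc$f == 0) {
    out <- term_energy(1, dc, model)
    attr(out, "l_used") <- 1L
    attr(out, "converged") <- TRUE
    return(out)
  }
  tot <- 0
  l <- 1L
  repeat {
    e <- term_energy(l, dc, model)
    tot <- tot + e
    if (l > 1L && e < tol * tot) break
    if (l >= l_max_cap) break
    l <- l + 1L
  }
  attr(tot, "l_used") <- l
  attr(tot, "converged") <- l < l_max_cap || e < tol * tot
  tot
}

#' Scalp potential of a dipole by series summation
#'
#' Sums the Legendre-series terms of the four-shell forward solution at
#' arbitrary points of the outer surface. The dipole may be anywhere inside
#' the innermost shell; points and dipole are rotated into the canonical
#' frame internally. Truncation: the series stops once the closed-form
#' per-term energy drops below `tol` times the accumulated energy.
#'
#' @param d a [dipole()] in world coordinates.
#' @param model a [shell_model()].
#' @param surface_points n x 3 matrix on the outer surface (mm), world frame.
#' @param tol relative per-term energy tolerance.
#' @param l_max_cap hard cap on the series degree.
#' @return numeric vector of potentials with attributes `l_used` and
#'   `converged`; a convergence warning is recorded in the `converged`
#'   attribute rather than raised.
#' @export
forward_potential <- function(d, model = shell_model(), surface_points,
                              tol = 1e-10, l_max_cap = 600L) {
  surface_points <- as.matrix(surface_points)
  check_on_outer_surface(surface_points, model)
  can <- rotate_to_canonical(d, model)
  dc <- can$dipole
  pts <- surface_points %*% t(can$rotation)
  ct <- pmin(1, pmax(-1, pts[, 3] / sqrt(rowSums(pts^2))))
  phi <- atan2(pts[, 2], pts[, 1])
  s <- sqrt(pmax(0, 1 - ct^2))
  mom <- dc$moment
  pref <- forward_prefactor(model)
  azim <- mom[1] * cos(phi) + mom[2] * sin(phi)

  v <- numeric(nrow(pts))
  # rolling Legendre recurrences
  pl_m2 <- rep(1, length(ct))   # P_0
  pl_m1 <- ct                   # P_1
  pl1_m2 <- numeric(length(ct)) # "P_0^1" = 0
  pl1_m1 <- s                   # P_1^1
  tot_e <- 0
  l <- 1L
  repeat {
    amp <- pref * series_amplitude(l, dc$f, model)
    v <- v + amp * (mom[3] * pl_m1 + azim * pl1_m1 / l)
    e <- term_energy(l, dc, model)
    tot_e <- tot_e + e
    done <- (dc$f == 0) || (l > 1L && e < tol * tot_e) || l >= l_max_cap
    if (done) break
    l <- l + 1L
    pl_new <- ((2 * l - 1) * ct * pl_m1 - (l - 1) * pl_m2) / l
    pl_m2 <- pl_m1; pl_m1 <- pl_new
    if (l == 2L) {
      pl1_new <- 3 * ct * s
    } else {
      pl1_new <- ((2 * l - 1) * ct * pl1_m1 - l * pl1_m2) / (l - 1)
    }
    pl1_m2 <- pl1_m1; pl1_m1 <- pl1_new
  }
  attr(v, "l_used") <- l
  attr(v, "converged") <- (dc$f == 0) || l < l_max_cap ||
    (tot_e > 0 && e < tol * tot_e)
  v
}
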