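# shared fixtures, built once per test run
fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, envir = cache)) assign(name, build(), envir = cache)
    get(name, envir = cache)
  }
})

fix_model <- function() shell_model()

fix_layout <- function(n, seed = 1L) {
  fix(sprintf("layout_%d_%d", n, seed), function()
    triangulate_sphere_points(equidistant_sphere_points(n, 92, seed = seed)))
}

# dense unit-sphere mesh for analytic Laplace-Beltrami comparisons
fix_unit_sphere <- function() {
  fix("unit_sphere", function()
    triangulate_sphere_points(equidistant_sphere_points(2200, 1, seed = 5)))
}

# Gauss-Legendre (colatitude) x trapezoid (longitude) quadrature over the
# unit sphere; returns points on radius R and weights carrying R^2 dOmega
sphere_quadrature <- function(n_theta = 80, n_phi = 160, radius = 92) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, times = n_phi)
  ph <- rep(phi, each = n_theta)
  st <- sqrt(1 - ct^2)
  pts <- cbind(radius * st * cos(ph), radius * st * sin(ph), radius * ct)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi) * radius^2
  list(points = pts, weights = w)
}

# independent numeric oracle for the four-shell factor: direct dense solve of
# the per-degree boundary-value problem (7 unknowns), in per-shell scaled
# variables; deliberately distinct from the transfer-matrix implementation
C_of_l_bvp <- function(l, model) {
  R <- model$radii
  sig <- model$conductivities
  vapply(l, function(n) {
    # unknowns: A1, A2, B2, A3, B3, A4, B4 (scaled: Aj' = Aj * Rj^n,
    # Bj' = Bj * R_{j-1}^-(n+1)); source term s = 1 * r^-(n+1) in region 1
    # rows: potential and current continuity at R1, R2, R3; outer Neumann
    A <- matrix(0, 7, 7)
    b <- numeric(7)
    # region radial factors at a given interface radius r:
    #  region1: A1' * (r/R1)^n        (+ source r^-(n+1))
    #  region j>=2: Aj'*(r/Rj)^n + Bj'*(R_{j-1}/r)^(n+1)
    s_at <- function(r) r^-(n + 1)
    ds_at <- function(r) -(n + 1) * r^-(n + 2)
    dval_a <- function(rref, r) n * (r / rref)^n / r
    dval_b <- function(rref, r) -(n + 1) * (rref / r)^(n + 1) / r
    # continuity of V at R1: A1' - A2'*(R1/R2)^n - B2' = s(R1)
    A[1, 1] <- 1; A[1, 2] <- -(R[1] / R[2])^n; A[1, 3] <- -1
    b[1] <- -s_at(R[1])
    # current at R1
    A[2, 1] <- sig[1] * dval_a(R[1], R[1])
    A[2, 2] <- -sig[2] * dval_a(R[2], R[1])
    A[2, 3] <- -sig[2] * dval_b(R[1], R[1])
    b[2] <- -sig[1] * ds_at(R[1])
    # V at R2
    A[3, 2] <- 1; A[3, 3] <- (R[1] / R[2])^(n + 1)
    A[3, 4] <- -(R[2] / R[3])^n; A[3, 5] <- -1
    # current at R2
    A[4, 2] <- sig[2] * dval_a(R[2], R[2])
    A[4, 3] <- sig[2] * dval_b(R[1], R[2])
    A[4, 4] <- -sig[3] * dval_a(R[3], R[2])
    A[4, 5] <- -sig[3] * dval_b(R[2], R[2])
    # V at R3
    A[5, 4] <- 1; A[5, 5] <- (R[2] / R[3])^(n + 1)
    A[5, 6] <- -(R[3] / R[4])^n; A[5, 7] <- -1
    # current at R3
    A[6, 4] <- sig[3] * dval_a(R[3], R[3])
    A[6, 5] <- sig[3] * dval_b(R[2], R[3])
    A[6, 6] <- -sig[4] * dval_a(R[4], R[3])
    A[6, 7] <- -sig[4] * dval_b(R[3], R[3])
    # Neumann at R4
    A[7, 6] <- dval_a(R[4], R[4])
    A[7, 7] <- dval_b(R[3], R[4])
    x <- solve(A, b)
    v_out <- x[6] + x[7] * (R[3] / R[4])^(n + 1)  # V(R4) per unit source
    (2 * n + 1)^4 * sig[1] / (sig[4] * n * R[4]^(n + 1) * v_out)
  }, numeric(1))
}
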