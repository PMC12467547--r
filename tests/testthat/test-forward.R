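# frozen exact-arithmetic values of the four-shell factor C(l) for the
# 80/81/86/92 mm, 0.33/1.79/0.0066/0.33 S/m model, computed by solving the
# per-degree boundary-value problem in rational arithmetic (25 significant
# digits retained)
frozen_C <- c(
  `1` = 36.53094890814987,
  `2` = 249.5027216867415,
  `5` = 6659.848270573631,
  `15` = 498912.9050331168,
  `60` = 61992008.79139107
)

test_that("C(l) matches the exact-arithmetic boundary-value solution", {
  model <- fix_model()
  got <- C_of_l(as.numeric(names(frozen_C)), model)
  expect_equal(got, unname(frozen_C), tolerance = 1e-12)
  expect_error(C_of_l(0, model), ">= 1")
})

test_that("C(l) agrees with an independent dense BVP solve across degrees", {
  model <- fix_model()
  l <- c(1:20, 30, 50, 80, 120)
  expect_equal(C_of_l(l, model), C_of_l_bvp(l, model), tolerance = 1e-7)
})

test_that("C(l) reduces to (2l+1)^3 for equal conductivities and stays finite to l = 600", {
  hom <- shell_model(conductivities = rep(0.4, 4))
  l <- c(1, 2, 3, 10, 40)
  expect_equal(C_of_l(l, hom), (2 * l + 1)^3, tolerance = 1e-12)
  big <- C_of_l(c(300, 600), fix_model())
  expect_true(all(is.finite(big) & big > 0))
})

test_that("the shell model constructor enforces its invariants", {
  expect_error(shell_model(radii = c(80, 81, 81, 92)), "increasing")
  expect_error(shell_model(radii = c(92, 86, 81, 80)), "increasing")
  expect_error(shell_model(conductivities = c(0.33, -1, 0.0066, 0.33)),
               "positive")
  expect_error(dipole(c(0, 0, 85), c(0, 0, 1)), "inside")
})

test_that("equal-conductivity potentials match the homogeneous-sphere oracle", {
  # independent oracle: the classical insulated homogeneous sphere series
  # with per-term factors (2l+1) f^(l-1) (radial) and (2l+1)/l f^(l-1)
  # (tangential), summed directly
  hom <- shell_model(conductivities = rep(0.33, 4))
  R4 <- hom$radii[4]
  q <- sphere_quadrature(40, 80, R4)
  pts <- q$points[seq(1, nrow(q$points), by = 37), ]
  homogeneous_potential <- function(mom, f, pts, lmax = 200) {
    r4m <- R4 * 1e-3
    ct <- pts[, 3] / sqrt(rowSums(pts^2))
    phi <- atan2(pts[, 2], pts[, 1])
    pl <- headspectra:::legendre_pl(lmax, ct)
    pl1 <- headspectra:::legendre_pl1(lmax, ct)
    v <- 0
    for (l in 1:lmax) {
      fac <- f^(l - 1) * (2 * l + 1) / (4 * pi * 0.33 * r4m^2)
      v <- v + fac * (mom[3] * pl[l + 1, ] +
                        (mom[1] * cos(phi) + mom[2] * sin(phi)) * pl1[l, ] / l)
    }
    v
  }
  for (case in list(list(m = c(0, 0, 1), r = 50), list(m = c(1, 0, 0), r = 70))) {
    d <- dipole(c(0, 0, case$r), case$m, model = hom)
    got <- forward_potential(d, hom, pts, tol = 1e-14)
    want <- homogeneous_potential(case$m, case$r / R4, pts)
    # agreement is truncation-limited: per-term energy tolerance 1e-14
    # corresponds to ~1e-7 amplitude
    expect_equal(as.numeric(got), want, tolerance = 1e-6)
  }
})

test_that("single series terms carry the stated angular structure", {
  model <- fix_model()
  R4 <- model$radii[4]
  th <- seq(0.2, 3, length.out = 7)
  ph <- seq(0, 2 * pi - 0.3, length.out = 5)
  g <- expand.grid(th = th, ph = ph)
  pts <- R4 * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))

  dz <- dipole(c(0, 0, 40), c(0, 0, 1), model = model)
  vz <- term_potential(3, dz, model, pts)
  # z-moment: no longitude dependence
  expect_equal(matrix(vz, length(th))[, 1], matrix(vz, length(th))[, 3],
               tolerance = 1e-12)

  dx <- dipole(c(0, 0, 40), c(1, 0, 0), model = model)
  pts_flip <- R4 * cbind(sin(g$th) * cos(g$ph + pi),
                         sin(g$th) * sin(g$ph + pi), cos(g$th))
  vx <- term_potential(3, dx, model, pts)
  vx_f <- term_potential(3, dx, model, pts_flip)
  # cos(phi) factor: antisymmetric under phi -> phi + pi
  expect_equal(vx_f, -vx, tolerance = 1e-12)

  # central dipole: l = 1 term only
  d0 <- dipole(c(0, 0, 0), c(0, 0, 1), model = model, orientation_class = "free")
  expect_gt(max(abs(term_potential(1, d0, model, pts))), 0)
  expect_equal(term_potential(2, d0, model, pts), numeric(nrow(pts)))
  expect_equal(term_energy(2:6, d0, model), numeric(5))

  expect_error(term_potential(1, dz, model, pts * 1.01), "outer shell")
})

test_that("closed-form term energies match surface quadrature", {
  model <- fix_model()
  q <- sphere_quadrature(60, 120, model$radii[4])
  mm2_to_m2 <- 1e-6
  for (case in list(list(m = c(0, 0, 1), r = 70), list(m = c(1, 0, 0), r = 70),
                    list(m = c(0.6, 0, 0.8), r = 40))) {
    d <- dipole(c(0, 0, case$r), case$m, model = model)
    for (l in c(1, 2, 5)) {
      v <- term_potential(l, d, model, q$points)
      e_quad <- sum(q$weights * v^2) * mm2_to_m2
      expect_equal(e_quad, term_energy(l, d, model), tolerance = 1e-8)
    }
    # additivity: energy of the summed potential equals the sum of term
    # energies (Legendre orthogonality on the sphere)
    v <- forward_potential(d, model, q$points)
    e_quad <- sum(q$weights * v^2) * mm2_to_m2
    expect_equal(e_quad, as.numeric(total_surface_energy(d, model)),
                 tolerance = 1e-6)
    # no spatial DC on the closed sphere
    expect_lt(abs(sum(q$weights * v)) / sqrt(e_quad * 4 * pi * 92^2 * 1e-6),
              1e-8)
  }
})

test_that("forward potentials are rotation-invariant and orientation-symmetric", {
  model <- fix_model()
  pts <- fix_layout(34)$vertices
  d <- dipole(c(30, -10, 55), c(0.2, 0.9, -0.3), model = model)
  v <- forward_potential(d, model, pts)
  th <- 1.1
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d2 <- dipole(as.numeric(Q %*% d$position), as.numeric(Q %*% d$moment),
               model = model)
  v2 <- forward_potential(d2, model, pts %*% t(Q))
  expect_equal(as.numeric(v2), as.numeric(v), tolerance = 1e-8)

  # tangential dipole: antisymmetric bipolar pattern under (x,y) -> (-x,-y)
  dt <- dipole(c(0, 0, 70), c(1, 0, 0), model = model)
  g <- expand.grid(th = seq(0.1, 3.1, length.out = 9), ph = c(0.3, 2.2))
  p1 <- 92 * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  p2 <- p1 %*% diag(c(-1, -1, 1))
  expect_equal(as.numeric(forward_potential(dt, model, p2)),
               -as.numeric(forward_potential(dt, model, p1)),
               tolerance = 1e-10)

  # central dipole: the full potential is its l = 1 term
  d0 <- dipole(c(0, 0, 0), c(1, 1, 1), model = model, orientation_class = "free")
  expect_equal(as.numeric(forward_potential(d0, model, pts)),
               term_potential(1, d0, model, pts), tolerance = 1e-12)
  expect_identical(attr(forward_potential(d0, model, pts), "l_used"), 1L)
})

test_that("canonical rotation round-trips and leaves energies invariant", {
  model <- fix_model()
  d <- dipole(c(0, 0, 50), c(0, 0, 1), model = model)
  can <- rotate_to_canonical(d, model)
  expect_equal(can$rotation, diag(3))
  expect_equal(can$dipole$moment, c(0, 0, 1))

  d2 <- dipole(c(20, 30, -40), c(0, 1, 0), model = model)
  can2 <- rotate_to_canonical(d2, model)
  expect_equal(can2$dipole$position[1:2], c(0, 0))
  expect_equal(can2$inverse %*% can2$rotation, diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(can2$dipole$moment^2)), 1, tolerance = 1e-12)

  # energy does not depend on the tangential azimuth
  es <- vapply(seq(0, 2 * pi, length.out = 8), function(a) {
    dt <- dipole(c(0, 0, 60), c(cos(a), sin(a), 0), model = model)
    as.numeric(total_surface_energy(dt, model))
  }, numeric(1))
  expect_lt(diff(range(es)) / mean(es), 1e-10)
})

test_that("energies grow monotonically with eccentricity; l=1 term is depth-invariant", {
  model <- fix_model()
  radii <- seq(0, 76, by = 4)
  for (mom in list(c(0, 0, 1), c(1, 0, 0))) {
    es <- vapply(radii, function(r) {
      d <- if (r == 0)
        dipole(c(0, 0, 0), c(0, 0, 1), model = model, orientation_class = "free")
      else dipole(c(0, 0, r), mom, model = model)
      as.numeric(total_surface_energy(d, model))
    }, numeric(1))
    expect_true(all(diff(es) > 0))
  }
  e1 <- vapply(c(0, 20, 45, 76), function(r) {
    d <- if (r == 0)
      dipole(c(0, 0, 0), c(0, 1, 0), model = model, orientation_class = "free")
    else dipole(c(0, 0, r), c(0, 1, 0), model = model)
    term_energy(1, d, model)
  }, numeric(1))
  expect_equal(e1, rep(e1[1], 4), tolerance = 1e-12)
})
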