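#' Synthetic dipole ensemble over concentric shells
#'
#' Generates the source ensemble used throughout the spherical analyses:
#' `per_shell` approximately equidistributed positions on each concentric
#' shell of the given radii (default 0-76 mm in 1 mm steps, 100 per shell,
#' i.e. 7700 positions), with unit moments. Non-central positions carry a
#' radial moment, a tangential moment with seeded random azimuth, or both
#' (the default, one row each). Central positions (radius 0) have no
#' radial/tangential distinction and receive seeded random orientations.
#' Per-shell positions use the same seeded repulsion construction as the
#' sensor layouts.
#'
#' @param radii shell radii in mm (must be < R1 of `model`).
#' @param per_shell sources per shell (>= 1).
#' @param orientation_class `"both"`, `"radial"` or `"tangential"` for the
#'   non-central shells.
#' @param seed integer seed.
#' @param model a [shell_model()]; positions must stay inside its R1.
#' @return A tibble of class `dipole_ensemble`, one row per dipole:
#'   `source`, `x`, `y`, `z`, `mx`, `my`, `mz` (unit moment), `radius_mm`,
#'   `depth_mm` (distance to the outer surface), `eccentricity`,
#'   `orientation_class`.
#' @export
dipole_ensemble <- function(radii = 0:76, per_shell = 100,
                            orientation_class = c("both", "radial", "tangential"),
                            seed = 1L, model = shell_model()) {
  orientation_class <- match.arg(orientation_class)
  if (per_shell < 1) stop("`per_shell` must be >= 1")
  if (any(radii < 0) || any(radii >= model$radii[1]))
    stop("shell radii must satisfy 0 <= r < R1")

  rows <- purrr::imap(radii, function(r, i) {
    if (r == 0) {
      mom <- with_local_seed(seed + 5000L + i, random_unit_vectors(per_shell))
      pos <- matrix(0, per_shell, 3)
      tibble::tibble(
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        mx = mom[, 1], my = mom[, 2], mz = mom[, 3],
        radius_mm = 0, orientation_class = "free"
      )
    } else {
      # repulsion layouts need >= 4 points; tiny shells fall back to seeded
      # uniform directions
      pos <- if (per_shell >= 4) {
        equidistant_sphere_points(per_shell, r, seed = seed + i)
      } else {
        r * with_local_seed(seed + i, random_unit_vectors(per_shell))
      }
      u <- pos / r
      out <- list()
      if (orientation_class %in% c("both", "radial")) {
        out$radial <- tibble::tibble(
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          mx = u[, 1], my = u[, 2], mz = u[, 3],
          radius_mm = r, orientation_class = "radial"
        )
      }
      if (orientation_class %in% c("both", "tangential")) {
        tang <- with_local_seed(seed + 9000L + i, random_tangent(u))
        out$tangential <- tibble::tibble(
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          mx = tang[, 1], my = tang[, 2], mz = tang[, 3],
          radius_mm = r, orientation_class = "tangential"
        )
      }
      dplyr::bind_rows(out)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    out,
    source = dplyr::row_number(),
    depth_mm = model$radii[4] - .data$radius_mm,
    eccentricity = .data$radius_mm / model$radii[4],
    .before = 1
  )
  out <- out[, c("source", "x", "y", "z", "mx", "my", "mz",
                 "radius_mm", "depth_mm", "eccentricity", "orientation_class")]
  attr(out, "seed") <- seed
  attr(out, "per_shell") <- per_shell
  class(out) <- c("dipole_ensemble", class(out))
  out
}

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# random unit vectors orthogonal to the rows of u (unit row vectors)
random_tangent <- function(u) {
  v <- random_unit_vectors(nrow(u))
  t <- v - u * rowSums(v * u)
  nt <- sqrt(rowSums(t^2))
  # regenerate the (measure-zero) degenerate draws
  bad <- nt < 1e-8
  while (any(bad)) {
    v2 <- random_unit_vectors(sum(bad))
    t[bad, ] <- v2 - u[bad, , drop = FALSE] *
      rowSums(v2 * u[bad, , drop = FALSE])
    nt <- sqrt(rowSums(t^2))
    bad <- nt < 1e-8
  }
  t / nt
}

# turn ensemble rows into dipole objects on demand
ensemble_dipole <- function(row, model) {
  dipole(c(row$x, row$y, row$z), c(row$mx, row$my, row$mz), model = model,
         orientation_class = row$orientation_class, unit = TRUE)
}

#' Open spherical cap fixture with a pseudo lead field
#'
#' Builds an open-surface test bed for the lead-field analysis route: an
#' equidistant layout on the outer shell, cut to an angular cap, together
#' with a lead-field matrix computed from the semi-analytical four-shell
#' forward model at the cap vertices, and the source table. Because the
#' forward physics is the same as the analytic route, pipeline results on
#' this bundle can be checked against the closed-form energies.
#'
#' @param n_points layout size before cutting.
#' @param radius outer radius in mm (must equal `model$radii[4]`).
#' @param cap_angle half-opening angle in degrees; values below 180 give an
#'   open mesh, 180 keeps the closed sphere (the closed-route reduction).
#' @param seed integer seed for layout and sources.
#' @param sources a `dipole_ensemble` tibble; default: a small ensemble.
#' @param model a [shell_model()].
#' @return list of class `leadfield_bundle`: `mesh` (cap [trimesh()]),
#'   `leadfield` (n_sources x n_vertices), `sources` (tibble).
#' @export
open_surface_fixture <- function(n_points = 500, radius = 92, cap_angle = 110,
                                 seed = 1L, sources = NULL,
                                 model = shell_model()) {
  if (cap_angle > 180) stop("`cap_angle` must be <= 180")
  if (abs(radius - model$radii[4]) > 1e-9)
    stop("`radius` must equal the outer shell radius of `model`")
  closed <- triangulate_sphere_points(
    equidistant_sphere_points(n_points, radius, seed = seed)
  )
  mesh <- if (cap_angle >= 180) closed else
    extract_cap(closed, axis = c(0, 0, 1), max_angle = cap_angle)
  if (nrow(mesh$vertices) < 4)
    stop("too few points remain in the cap; increase `n_points` or `cap_angle`")
  if (is.null(sources))
    sources <- dipole_ensemble(radii = seq(0, 70, by = 10), per_shell = 10,
                               seed = seed, model = model)
  lf <- pseudo_leadfield(mesh, sources, model)
  structure(list(mesh = mesh, leadfield = lf, sources = sources),
            class = "leadfield_bundle")
}

#' Lead field from the semi-analytical forward model
#'
#' Evaluates the four-shell series potential of every ensemble source at the
#' vertices of a (possibly open) surface mesh on the outer shell.
#'
#' @param mesh a [trimesh()] with vertices on R4.
#' @param sources a `dipole_ensemble` tibble.
#' @param model a [shell_model()].
#' @param tol,l_max_cap series truncation controls.
#' @return n_sources x n_vertices matrix (volts per unit moment).
#' @export
pseudo_leadfield <- function(mesh, sources, model = shell_model(),
                             tol = 1e-10, l_max_cap = 600L) {
  pts <- mesh$vertices
  out <- matrix(0, nrow(sources), nrow(pts))
  # batch sources sharing (radius, class): one Legendre recurrence per batch
  key <- paste(sources$radius_mm, sources$orientation_class)
  for (k in unique(key)) {
    idx <- which(key == k)
    out[idx, ] <- t(forward_fields_batch(pts, sources[idx, ], model,
                                         tol = tol, l_max_cap = l_max_cap))
  }
  out
}

# forward potentials for sources of a common eccentricity, vectorised over
# sources: returns n_points x n_sources
forward_fields_batch <- function(points, sources, model, tol = 1e-10,
                                 l_max_cap = 600L) {
  np <- nrow(points)
  ns <- nrow(sources)
  ct <- matrix(0, np, ns)
  az <- matrix(0, np, ns)
  mz <- numeric(ns)
  f <- sources$radius_mm[1] / model$radii[4]
  for (j in seq_len(ns)) {
    d <- ensemble_dipole(sources[j, ], model)
    can <- rotate_to_canonical(d, model)
    pc <- points %*% t(can$rotation)
    ct[, j] <- pmin(1, pmax(-1, pc[, 3] / sqrt(rowSums(pc^2))))
    phi <- atan2(pc[, 2], pc[, 1])
    mom <- can$dipole$moment
    az[, j] <- mom[1] * cos(phi) + mom[2] * sin(phi)
    mz[j] <- mom[3]
  }
  # common truncation degree for the batch, from the closed-form energies
  l_need <- series_degree_needed(f, model, tol, l_max_cap)
  pref <- forward_prefactor(model)
  mzr <- rep(mz, each = np)
  s <- sqrt(pmax(0, 1 - ct^2))
  v <- matrix(0, np, ns)
  pl_m2 <- matrix(1, np, ns); pl_m1 <- ct
  pl1_m2 <- matrix(0, np, ns); pl1_m1 <- s
  for (l in seq_len(l_need)) {
    if (l > 1L) {
      pl_new <- ((2 * l - 1) * ct * pl_m1 - (l - 1) * pl_m2) / l
      pl_m2 <- pl_m1; pl_m1 <- pl_new
      pl1_new <- if (l == 2L) 3 * ct * s else
        ((2 * l - 1) * ct * pl1_m1 - l * pl1_m2) / (l - 1)
      pl1_m2 <- pl1_m1; pl1_m1 <- pl1_new
    }
    amp <- pref * series_amplitude(l, f, model)
    v <- v + amp * (mzr * pl_m1 + az * pl1_m1 / l)
  }
  v
}

# smallest series degree at which both orientation classes have converged
series_degree_needed <- function(f, model, tol = 1e-10, l_max_cap = 600L) {
  if (f == 0) return(1L)
  dr <- dipole(c(0, 0, f * model$radii[4]), c(0, 0, 1), model = model)
  dt <- dipole(c(0, 0, f * model$radii[4]), c(1, 0, 0), model = model)
  er <- et <- 0
  l <- 1L
  repeat {
    tr <- term_energy(l, dr, model)
    tt <- term_energy(l, dt, model)
    er <- er + tr; et <- et + tt
    if (l > 1L && tr < tol * er && tt < tol * et) break
    if (l >= l_max_cap) break
    l <- l + 1L
  }
  l
}

#' Import an externally computed lead-field bundle
#'
#' Reads a surface mesh (OFF or ASCII PLY), a delimited lead-field matrix
#' and a source table, validates that the dimensions agree (transposed
#' matrices are auto-detected when unambiguous), and returns a bundle ready
#' for the spectral pipeline.
#'
#' @param mesh_file OFF or ASCII-PLY mesh path.
#' @param matrix_file tab- or comma-separated numeric matrix,
#'   n_sources x n_vertices (or its transpose).
#' @param sources_file delimited table with columns
#'   `x,y,z,mx,my,mz` (additional columns such as `depth_mm`,
#'   `orientation_deg` are kept).
#' @return list of class `leadfield_bundle` with `mesh`, `leadfield`,
#'   `sources`.
#' @export
leadfield_import <- function(mesh_file, matrix_file, sources_file) {
  mesh <- read_mesh(mesh_file)
  lf <- as.matrix(utils::read.table(matrix_file, sep = "\t",
                                    comment.char = "#"))
  dimnames(lf) <- NULL
  src <- tibble::as_tibble(utils::read.csv(sources_file, comment.char = "#"))
  need <- c("x", "y", "z", "mx", "my", "mz")
  if (!all(need %in% names(src)))
    stop("schema error: sources file must contain columns ",
         paste(need, collapse = ", "))
  nv <- nrow(mesh$vertices)
  ns <- nrow(src)
  if (ncol(lf) == nv && nrow(lf) == ns) {
    # as expected
  } else if (nrow(lf) == nv && ncol(lf) == ns) {
    lf <- t(lf)
  } else {
    stop(sprintf(
      "schema error: lead field is %d x %d but expected %d sources x %d vertices",
      nrow(lf), ncol(lf), ns, nv))
  }
  structure(list(mesh = mesh, leadfield = lf, sources = src),
            class = "leadfield_bundle")
}

#' Write a lead-field bundle as plain text
#'
#' Counterpart of [leadfield_import()]: writes `<base>_mesh.off`,
#' `<base>_leadfield.tsv` and `<base>_sources.csv`.
#'
#' @param bundle a `leadfield_bundle`.
#' @param base base path (directory must exist).
#' @return invisibly, the three file paths.
#' @export
leadfield_export <- function(bundle, base) {
  mf <- paste0(base, "_mesh.off")
  lf <- paste0(base, "_leadfield.tsv")
  sf <- paste0(base, "_sources.csv")
  write_mesh_off(bundle$mesh, mf)
  utils::write.table(format(bundle$leadfield, digits = 17, trim = TRUE),
                     lf, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.csv(bundle$sources, sf, row.names = FALSE, quote = FALSE)
  invisible(c(mf, lf, sf))
}
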