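#' Equidistant points on a sphere
#'
#' Generates an approximately equidistant set of `n` points on a sphere of
#' the given radius by seeded repulsion in the distmesh manner: a
#' Fibonacci-lattice initialisation with a small seeded jitter, then
#' truncated repulsive springs acting along the edges of the current
#' spherical Delaunay triangulation (recomputed as the points move, via the
#' convex hull), with points reprojected to the sphere after every step.
#' Iteration stops once the largest per-sweep displacement falls below
#' `1e-4 * radius`. The construction is deterministic for a fixed
#' `(n, radius, seed)` triple, and its edge-length statistics closely match
#' published distmesh sensor layouts.
#'
#' @param n number of points (>= 4).
#' @param radius sphere radius in mm.
#' @param seed integer seed for the jitter.
#' @param max_outer cap on retriangulation sweeps.
#' @return n x 3 matrix of coordinates (mm), each row at distance `radius`
#'   from the origin.
#' @export
equidistant_sphere_points <- function(n, radius, seed = 1L, max_outer = 300L) {
  if (n < 4) stop("`n` must be at least 4")
  if (radius <= 0) stop("`radius` must be positive")
  p <- fibonacci_sphere(n)
  # seeded symmetry-breaking jitter, small relative to spacing
  p <- with_local_seed(seed, {
    p + matrix(stats::rnorm(3 * n, sd = 0.05 * sqrt(4 / n)), n, 3)
  })
  p <- p * (radius / sqrt(rowSums(p^2)))
  for (sweep in seq_len(max_outer)) {
    tri <- convex_hull3_cpp(p)
    ue <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    ue <- cbind(pmin(ue[, 1], ue[, 2]), pmax(ue[, 1], ue[, 2]))
    ue <- ue[!duplicated(ue[, 1] * (n + 1) + ue[, 2]), , drop = FALSE]
    res <- spring_relax_cpp(p, ue, radius, 10L, 0.2, 1.2)
    p <- res$points
    if (res$max_displacement < 1e-4 * radius) break
  }
  colnames(p) <- c("x", "y", "z")
  p
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# run code under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Triangulate points on a sphere
#'
#' Triangulates a spherical point set by its convex hull, which for points
#' on a common sphere coincides with the Delaunay triangulation of the
#' sphere. The result is a closed mesh with outward-oriented triangles and
#' exactly `2n - 4` faces.
#'
#' @param points n x 3 matrix of coordinates on a common sphere (n >= 4).
#' @return a closed [trimesh()].
#' @export
triangulate_sphere_points <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  r <- sqrt(rowSums(points^2))
  if (stats::sd(r) / mean(r) > 1e-6)
    stop("points do not lie on a common sphere centred at the origin")
  tri <- tryCatch(
    convex_hull3_cpp(points),
    error = function(e) stop("triangulation failure: ", conditionMessage(e))
  )
  mesh <- trimesh(points, tri)
  if (!mesh$is_closed) stop("triangulation failure: hull not closed")
  # orient outward: signed volume must be positive
  if (signed_volume(mesh) < 0)
    mesh <- trimesh(points, mesh$triangles[, c(1, 3, 2)])
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ) / 6
}

#' Generate, triangulate and characterise a sensor layout
#'
#' Convenience wrapper producing the triangulated layout together with its
#' edge statistics and spatial Nyquist limits, one row per requested size.
#'
#' @param n vector of layout sizes.
#' @param radius sphere radius in mm (default 92, adult-head scale).
#' @param seed integer seed.
#' @return tibble with columns `n`, `mesh` (list of [trimesh()]), the
#'   [edge_stats()] columns and the [nyquist_limits()] columns.
#' @export
sensor_layouts <- function(n, radius = 92, seed = 1L) {
  purrr::map_dfr(n, function(ni) {
    mesh <- triangulate_sphere_points(
      equidistant_sphere_points(ni, radius, seed = seed)
    )
    st <- edge_stats(mesh)
    dplyr::bind_cols(
      tibble::tibble(n = ni, mesh = list(mesh)),
      st,
      nyquist_limits(st$h_max)[, c("k_n", "omega_n", "lambda_n")]
    )
  })
}

#' Read/write sensor layouts as delimited text
#'
#' Layout files are 3-column comma-separated text (x, y, z in mm) with
#' optional `#` comment lines.
#'
#' @param points n x 3 coordinate matrix.
#' @param path file path.
#' @return `read_layout()` returns an n x 3 matrix; `write_layout()` its
#'   input, invisibly.
#' @export
write_layout <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sensor layout: x,y,z in mm", con)
  utils::write.table(
    format(points, digits = 12, trim = TRUE, scientific = FALSE),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(points)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  d <- utils::read.table(path, sep = ",", comment.char = "#")
  m <- unname(as.matrix(d[, 1:3]))
  colnames(m) <- c("x", "y", "z")
  m
}
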