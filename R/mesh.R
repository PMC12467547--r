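#' Triangle surface mesh
#'
#' Light-weight container for a triangulated surface sampled at sensor or
#' model positions: a matrix of 3D vertex coordinates (mm) and a matrix of
#' vertex-index triples. The mesh may be closed (no boundary edges, Euler
#' characteristic 2) or open (one or more boundary loops), e.g. an electrode
#' cap covering only part of the scalp.
#'
#' Validation enforces the usual manifold-surface conditions: every edge
#' belongs to one (boundary) or two triangles, triangle orientation is
#' consistent across shared edges, and all triangle areas are positive.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param validate logical; check manifold invariants (default `TRUE`).
#' @return An object of class `trimesh` with fields `vertices`, `triangles`
#'   and `is_closed`.
#' @export
trimesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("`triangles` must be an m x 3 matrix")
  if (nrow(triangles) < 1L) stop("mesh must contain at least one triangle")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")

  mesh <- structure(
    list(vertices = vertices, triangles = triangles, is_closed = NA),
    class = "trimesh"
  )
  bnd <- boundary_edge_count(mesh)
  mesh$is_closed <- bnd == 0L
  if (validate) validate_trimesh(mesh)
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf(
    "<trimesh> %d vertices, %d triangles, %s\n",
    nrow(x$vertices), nrow(x$triangles),
    if (isTRUE(x$is_closed)) "closed" else "open"
  ))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  b <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh a [trimesh()].
#' @return scalar area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

# directed edges as a 3m x 2 matrix (in triangle winding order)
directed_edges <- function(mesh) {
  t <- mesh$triangles
  rbind(
    cbind(t[, 1], t[, 2]),
    cbind(t[, 2], t[, 3]),
    cbind(t[, 3], t[, 1])
  )
}

edge_key <- function(e, n) {
  pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
}

#' Unique undirected edges of a mesh
#' @param mesh a [trimesh()].
#' @return integer matrix, one row per unique edge.
#' @export
mesh_edges <- function(mesh) {
  de <- directed_edges(mesh)
  n <- nrow(mesh$vertices)
  ue <- cbind(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  ue[!duplicated(edge_key(ue, n)), , drop = FALSE]
}

boundary_edge_count <- function(mesh) {
  de <- directed_edges(mesh)
  n <- nrow(mesh$vertices)
  sum(table(edge_key(de, n)) == 1L)
}

#' Boundary edges of a mesh
#' @param mesh a [trimesh()].
#' @return integer matrix of directed boundary edges (0 rows for a closed mesh).
#' @export
boundary_edges <- function(mesh) {
  de <- directed_edges(mesh)
  n <- nrow(mesh$vertices)
  key <- edge_key(de, n)
  cnt <- table(key)
  de[key %in% as.numeric(names(cnt)[cnt == 1L]), , drop = FALSE]
}

#' Number of closed boundary loops of an open mesh
#' @param mesh a [trimesh()].
#' @return integer loop count (0 for a closed mesh).
#' @export
boundary_loop_count <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(0L)
  nxt <- integer(nrow(mesh$vertices))
  nxt[be[, 1]] <- be[, 2]
  seen <- rep(FALSE, nrow(mesh$vertices))
  loops <- 0L
  for (s in be[, 1]) {
    if (seen[s]) next
    loops <- loops + 1L
    v <- s
    repeat {
      seen[v] <- TRUE
      v <- nxt[v]
      if (v == s || v == 0L) break
    }
  }
  loops
}

#' Euler characteristic V - E + F
#' @param mesh a [trimesh()].
#' @return integer; 2 for a closed sphere-topology mesh, 1 for a disc.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

validate_trimesh <- function(mesh) {
  ar <- triangle_areas(mesh)
  if (any(ar <= 0 | !is.finite(ar))) {
    bad <- which(ar <= 0 | !is.finite(ar))[1]
    stop(sprintf("triangle %d has non-positive area", bad))
  }
  de <- directed_edges(mesh)
  n <- nrow(mesh$vertices)
  cnt <- table(edge_key(de, n))
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles")
  # consistent orientation: no directed edge may appear twice
  dcnt <- table(de[, 1] * (n + 1) + de[, 2])
  if (any(dcnt > 1L))
    stop("inconsistent triangle orientation: repeated directed edge")
  invisible(mesh)
}

#' Edge-length statistics of a mesh
#'
#' Mean, standard deviation and maximum of the unique edge lengths, the
#' quantities tabulated for each sensor layout and the input to the spatial
#' Nyquist limit ([nyquist_limits()]).
#'
#' @param mesh a [trimesh()].
#' @return A one-row tibble with columns `h_mean`, `h_sd`, `h_max` (mm),
#'   `n_vertices`, `n_triangles`.
#' @export
edge_stats <- function(mesh) {
  if (!inherits(mesh, "trimesh")) stop("`mesh` must be a trimesh")
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  tibble::tibble(
    h_mean = mean(len),
    h_sd = stats::sd(len),
    h_max = max(len),
    n_vertices = nrow(mesh$vertices),
    n_triangles = nrow(mesh$triangles)
  )
}

#' Spatial Nyquist limits of a triangulated layout
#'
#' Worst-case sampling bound for an irregular mesh, driven by its maximum
#' edge length: wavenumber `k_n = pi / h_max`, frequency
#' `omega_n = 1 / (2 h_max)` and wavelength `lambda_n = 2 h_max`. Spatial
#' frequencies above `omega_n` cannot be represented without aliasing even
#' in the sparsest region of the mesh.
#'
#' @param h_max maximum edge length in mm (scalar or vector), or a
#'   [trimesh()] from which it is computed.
#' @return A tibble with columns `h_max`, `k_n` (rad/mm), `omega_n` (1/mm),
#'   `lambda_n` (mm).
#' @export
nyquist_limits <- function(h_max) {
  if (inherits(h_max, "trimesh")) h_max <- edge_stats(h_max)$h_max
  if (any(!is.finite(h_max)) || any(h_max <= 0))
    stop("`h_max` must be positive and finite")
  tibble::tibble(
    h_max = h_max,
    k_n = pi / h_max,
    omega_n = 1 / (2 * h_max),
    lambda_n = 2 * h_max
  )
}

#' Extract an angular cap from a closed mesh
#'
#' Keeps the vertices whose angular distance from `axis` (seen from the
#' origin) is at most `max_angle`, and the triangles whose three vertices are
#' all kept, i.e. the cap is a strict subcomplex of the input. For
#' `max_angle < 180` the result is an open mesh with boundary; this mimics
#' the part of a scalp covered by an electrode cap.
#'
#' @param mesh a closed [trimesh()].
#' @param axis length-3 direction of the cap centre (need not be unit).
#' @param max_angle half-opening angle in degrees, in (0, 180].
#' @return An (open) `trimesh`; vertices are renumbered.
#' @export
extract_cap <- function(mesh, axis = c(0, 0, 1), max_angle = 90) {
  if (!inherits(mesh, "trimesh")) stop("`mesh` must be a trimesh")
  if (max_angle <= 0 || max_angle > 180)
    stop("`max_angle` must lie in (0, 180]")
  axis <- axis / sqrt(sum(axis^2))
  v <- mesh$vertices
  ang <- acos(pmin(1, pmax(-1, (v %*% axis) / sqrt(rowSums(v^2)))))
  keep <- which(ang <= max_angle * pi / 180 + 1e-12)
  tri <- mesh$triangles
  tkeep <- rowSums(matrix(tri %in% keep, nrow(tri), 3)) == 3L
  if (!any(tkeep))
    stop("empty selection: no triangle lies fully inside the cap")
  newid <- integer(nrow(v))
  newid[keep] <- seq_along(keep)
  trimesh(v[keep, , drop = FALSE],
          matrix(newid[tri[tkeep, , drop = FALSE]], ncol = 3))
}

#' Scale or transform mesh coordinates
#' @param mesh a [trimesh()].
#' @param f function applied to the vertex matrix (must return n x 3).
#' @return a `trimesh` with mapped vertices.
#' @export
map_vertices <- function(mesh, f) {
  trimesh(f(mesh$vertices), mesh$triangles)
}
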