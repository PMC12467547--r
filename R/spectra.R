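#' Energy ratio to decibels
#'
#' Energy convention `10 log10(fraction)`: a fraction of 0.5 is about -3 dB.
#' Zero maps to `-Inf`; negative fractions are invalid.
#'
#' @param fraction non-negative energy ratio(s).
#' @return dB values.
#' @export
to_db <- function(fraction) {
  if (any(fraction < 0, na.rm = TRUE)) stop("`fraction` must be non-negative")
  ifelse(fraction == 0, -Inf, 10 * log10(fraction))
}

# energy of the central reference source (orientation-invariant, l = 1 only)
center_reference_energy <- function(model, moment = c(0, 0, 1)) {
  term_energy(1, dipole(c(0, 0, 0), moment, model = model), model)
}

#' Depth dependence of the scalp-potential energy
#'
#' Closed-form total surface energies of unit dipoles over a sweep of source
#' radii, for radial and tangential orientations, normalised to the central
#' unit source (0 dB). Near-surface radial sources carry more than twice
#' the central energy; tangential ones about 1.7 times.
#'
#' @param model a [shell_model()].
#' @param radii source radii in mm (must be < R1).
#' @param orientations subset of `c("radial", "tangential")`.
#' @param tol,l_max_cap series truncation controls.
#' @return tibble with `radius_mm`, `orientation`, `energy` (V^2 m^2),
#'   `ratio` (to the central source) and `db`.
#' @export
energy_gain_curve <- function(model = shell_model(), radii = 0:76,
                              orientations = c("radial", "tangential"),
                              tol = 1e-10, l_max_cap = 600L) {
  e_ref <- center_reference_energy(model)
  grid <- tidyr::expand_grid(radius_mm = radii, orientation = orientations)
  grid <- grid[!(grid$radius_mm == 0 & grid$orientation != orientations[1]), ]
  res <- purrr::pmap_dfr(grid, function(radius_mm, orientation) {
    d <- sweep_dipole(radius_mm, orientation, model)
    e <- as.numeric(total_surface_energy(d, model, tol = tol,
                                         l_max_cap = l_max_cap))
    tibble::tibble(radius_mm = radius_mm,
                   orientation = if (radius_mm == 0) "free" else orientation,
                   energy = e)
  })
  res <- dplyr::distinct(res, .data$radius_mm, .data$orientation,
                         .keep_all = TRUE)
  dplyr::mutate(res, ratio = .data$energy / e_ref, db = to_db(.data$ratio))
}

# canonical sweep source: on +z axis; radial = z moment, tangential = x moment
sweep_dipole <- function(radius_mm, orientation, model) {
  if (radius_mm == 0)
    return(dipole(c(0, 0, 0), c(0, 0, 1), model = model,
                  orientation_class = "free"))
  mom <- if (orientation == "radial") c(0, 0, 1) else c(1, 0, 0)
  dipole(c(0, 0, radius_mm), mom, model = model)
}

#' Per-degree energy spectrum of the semi-analytical series
#'
#' Closed-form energy contribution of each Legendre term (degree `l`) to the
#' scalp-surface energy, relative to the central reference source. The
#' central source contributes exclusively at `l = 1`; the `l = 1`
#' contribution is identical for all depths and orientations of unit
#' sources.
#'
#' @param model a [shell_model()].
#' @param radii source radii in mm.
#' @param orientations subset of `c("radial", "tangential")`.
#' @param l_max largest degree reported.
#' @return tibble of class `energy_spectrum` with `radius_mm`, `orientation`,
#'   `l`, `lambda_mm`, `energy`, `fraction`, `db`; the reference energy is
#'   stored in the `reference_energy` attribute.
#' @export
term_spectrum <- function(model = shell_model(), radii = c(0, 30, 50, 60, 65, 70, 73, 75, 76),
                          orientations = c("radial", "tangential"),
                          l_max = 15L) {
  e_ref <- center_reference_energy(model)
  grid <- tidyr::expand_grid(radius_mm = radii, orientation = orientations)
  grid <- grid[!(grid$radius_mm == 0 & grid$orientation != orientations[1]), ]
  out <- purrr::pmap_dfr(grid, function(radius_mm, orientation) {
    d <- sweep_dipole(radius_mm, orientation, model)
    tibble::tibble(
      radius_mm = radius_mm,
      orientation = if (radius_mm == 0) "free" else orientation,
      l = seq_len(l_max),
      energy = term_energy(seq_len(l_max), d, model)
    )
  })
  out <- dplyr::distinct(out, .data$radius_mm, .data$orientation, .data$l,
                         .keep_all = TRUE)
  out <- dplyr::mutate(
    out,
    lambda_mm = jeans_wavelength(.data$l, model$radii[4]),
    fraction = .data$energy / e_ref,
    db = to_db(.data$fraction),
    .after = "l"
  )
  attr(out, "reference_energy") <- e_ref
  attr(out, "grouping") <- "degree"
  class(out) <- c("energy_spectrum", class(out))
  out
}

#' Energy misestimation of discrete sensor layouts
#'
#' For every source of an ensemble and every sensor layout, compares the
#' discrete surface energy (mass-matrix quadratic form of the sampled
#' potential) with the exact closed-form series energy. Coarse layouts
#' systematically underestimate the energy, increasingly so for
#' near-surface sources whose potentials contain spatial frequencies above
#' the layout's Nyquist limit.
#'
#' @param layouts a named list of closed [trimesh()] layouts, or the tibble
#'   returned by [sensor_layouts()].
#' @param model a [shell_model()].
#' @param ensemble a [dipole_ensemble()] tibble.
#' @param tol,l_max_cap series truncation controls.
#' @return tibble with one row per (layout, source): `layout_n`, source
#'   descriptors, `e_exact`, `e_sampled` (V^2 m^2) and
#'   `rel_dev = (e_sampled - e_exact) / e_exact`.
#' @export
sampled_energy_deviation <- function(layouts, model = shell_model(), ensemble,
                                     tol = 1e-10, l_max_cap = 600L) {
  if (inherits(layouts, "data.frame")) {
    meshes <- stats::setNames(layouts$mesh, layouts$n)
  } else {
    meshes <- layouts
    if (is.null(names(meshes)))
      names(meshes) <- vapply(meshes, function(m) nrow(m$vertices), numeric(1))
  }
  # exact energies depend only on (radius, orientation class)
  ex_key <- paste(ensemble$radius_mm, ensemble$orientation_class)
  uniq <- !duplicated(ex_key)
  ex_map <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    d <- ensemble_dipole(ensemble[i, ], model)
    assign(ex_key[i],
           as.numeric(total_surface_energy(d, model, tol, l_max_cap)),
           envir = ex_map)
  }
  e_exact <- vapply(ex_key, function(k) get(k, envir = ex_map), numeric(1))

  purrr::imap_dfr(meshes, function(mesh, nm) {
    fem <- fem_matrices(mesh)
    lf <- pseudo_leadfield(mesh, ensemble, model, tol = tol,
                           l_max_cap = l_max_cap)
    e_sam <- field_energy(t(lf), fem$B) * 1e-6  # mm^2 -> m^2
    dplyr::bind_cols(
      tibble::tibble(layout_n = as.integer(nm)),
      ensemble[, c("source", "radius_mm", "depth_mm", "orientation_class")],
      tibble::tibble(
        e_exact = unname(e_exact),
        e_sampled = e_sam,
        rel_dev = (e_sam - e_exact) / e_exact
      )
    )
  })
}

#' Discrete spherical-harmonic energy spectrum of forward fields
#'
#' Samples the forward potential of each source at the given layout points,
#' expands in real spherical harmonics by least squares, and reports the
#' per-degree energy contributions relative to the mean energy of the
#' central sources of the ensemble (the 0 dB reference).
#'
#' @param points n x 3 sensor coordinates on the outer shell.
#' @param model a [shell_model()].
#' @param sources a [dipole_ensemble()] tibble; must contain central
#'   (radius 0) sources, which define the reference.
#' @param l_max maximum degree of the expansion.
#' @param tol,l_max_cap series truncation controls.
#' @return `energy_spectrum` tibble: `source`, `radius_mm`, `depth_mm`,
#'   `orientation_class`, `l` (0..l_max), `energy`, `fraction`, `db`.
#' @export
sh_spectrum <- function(points, model = shell_model(), sources, l_max = 15L,
                        tol = 1e-10, l_max_cap = 600L) {
  points <- as.matrix(points)
  lu <- sampling_bounds(n = nrow(points))$l_up
  if (l_max > lu)
    stop(sprintf("l_max = %d exceeds the resolvable degree l_up = %d for %d points",
                 l_max, lu, nrow(points)))
  fields <- t(pseudo_leadfield(trivial_point_mesh(points), sources, model,
                               tol = tol, l_max_cap = l_max_cap))
  coef <- sh_expand_lsq(points, fields, l_max)   # (l_max+1)^2 x n_sources
  r4m2 <- (model$radii[4] * 1e-3)^2
  degs <- attr(coef, "l")
  e_by_l <- t(rowsum(coef^2, degs)) * 4 * pi * r4m2  # n_sources x (l_max+1)
  spectrum_tibble(e_by_l, sources, method = "sh")
}

# wrap bare points for pseudo_leadfield (which only needs $vertices)
trivial_point_mesh <- function(points) {
  structure(list(vertices = as.matrix(points)), class = "point_set")
}

#' Sphara energy spectrum of forward fields
#'
#' Samples the forward potential of each source at the mesh vertices,
#' projects onto the Laplace-Beltrami eigenbasis, and reports per-mode
#' squared coefficients grouped into spherical-harmonic-equivalent degrees
#' (blocks of `2l+1` modes after the DC mode), relative to the mean discrete
#' energy of the central sources.
#'
#' @param basis a [sphara_basis()] with at least `(l_max+1)^2` modes, or a
#'   closed [trimesh()] from which one is computed.
#' @param model a [shell_model()].
#' @param sources a [dipole_ensemble()] tibble with central sources.
#' @param l_max maximum reported degree.
#' @param by `"degree"` (default) groups modes into degrees; `"mode"`
#'   returns one row per basis function.
#' @param fields optional precomputed n_vertices x n_sources field matrix.
#' @param tol,l_max_cap series truncation controls.
#' @return `energy_spectrum` tibble as in [sh_spectrum()]; for
#'   `by = "mode"` with columns `mode` and `l`.
#' @export
sphara_spectrum <- function(basis, model = shell_model(), sources, l_max = 15L,
                            by = c("degree", "mode"), fields = NULL,
                            tol = 1e-10, l_max_cap = 600L) {
  by <- match.arg(by)
  n_modes_needed <- (l_max + 1)^2
  if (inherits(basis, "trimesh")) basis <- sphara_basis(basis, n_modes_needed)
  nv <- nrow(basis$vectors)
  lu <- sampling_bounds(n = nv)$l_up
  if (l_max > lu)
    stop(sprintf("l_max = %d exceeds the resolvable degree l_up = %d for %d vertices; reduce l_max or refine the layout",
                 l_max, lu, nv))
  if (ncol(basis$vectors) < n_modes_needed)
    stop(sprintf("basis has %d modes but %d are needed for l_max = %d",
                 ncol(basis$vectors), n_modes_needed, l_max))
  if (is.null(fields))
    fields <- t(pseudo_leadfield(basis$mesh, sources, model, tol = tol,
                                 l_max_cap = l_max_cap))
  coef <- sphara_analyze(basis, fields)           # n_modes x n_sources
  coef <- coef[seq_len(n_modes_needed), , drop = FALSE]
  e_mode <- coef^2 * 1e-6                         # mm^2 -> m^2
  degs <- mode_degrees(n_modes_needed, l_max)
  ref <- mean(field_energy(fields[, sources$radius_mm == 0, drop = FALSE],
                           basis$B)) * 1e-6
  if (!is.finite(ref) || ref <= 0)
    stop("ensemble must contain central (radius 0) sources for the reference")
  if (by == "degree") {
    e_by_l <- t(rowsum(e_mode, degs))
    spectrum_tibble(e_by_l, sources, method = "sphara", reference = ref)
  } else {
    ns <- nrow(sources)
    out <- dplyr::bind_cols(
      sources[rep(seq_len(ns), each = n_modes_needed),
              c("source", "radius_mm", "depth_mm", "orientation_class")],
      tibble::tibble(
        mode = rep(seq_len(n_modes_needed), ns),
        l = rep(degs, ns),
        energy = as.vector(e_mode)
      )
    )
    out <- dplyr::mutate(out, fraction = .data$energy / ref,
                         db = to_db(.data$fraction))
    attr(out, "reference_energy") <- ref
    attr(out, "grouping") <- "mode"
    class(out) <- c("energy_spectrum", class(out))
    out
  }
}

# shared assembly of per-degree spectra; e_by_l is n_sources x n_degrees
# with degree labels in colnames-order 0..l_max
spectrum_tibble <- function(e_by_l, sources, method, reference = NULL) {
  l_vals <- if (is.null(colnames(e_by_l))) seq_len(ncol(e_by_l)) - 1L
            else as.integer(colnames(e_by_l))
  if (is.null(reference)) {
    ctr <- sources$radius_mm == 0
    if (!any(ctr))
      stop("ensemble must contain central (radius 0) sources for the reference")
    reference <- mean(rowSums(e_by_l[ctr, , drop = FALSE]))
  }
  ns <- nrow(sources)
  nl <- length(l_vals)
  out <- dplyr::bind_cols(
    sources[rep(seq_len(ns), each = nl),
            c("source", "radius_mm", "depth_mm", "orientation_class")],
    tibble::tibble(l = rep(l_vals, ns), energy = as.vector(t(e_by_l)))
  )
  out <- dplyr::mutate(out, fraction = .data$energy / reference,
                       db = to_db(.data$fraction))
  attr(out, "reference_energy") <- reference
  attr(out, "grouping") <- "degree"
  attr(out, "method") <- method
  class(out) <- c("energy_spectrum", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two energy spectra
#'
#' Elementwise differences of the relative energy contributions of two
#' spectra on the same sources and degree grouping, in percentage points.
#'
#' @param spec_a,spec_b `energy_spectrum` tibbles with `grouping = "degree"`.
#' @return one-row tibble with `max_abs_diff` and `median_abs_diff`
#'   (percentage points).
#' @export
compare_spectra <- function(spec_a, spec_b) {
  if (!identical(attr(spec_a, "grouping"), attr(spec_b, "grouping")))
    stop("grouping mismatch between the two spectra")
  j <- dplyr::inner_join(
    spec_a[, c("source", "l", "fraction")],
    spec_b[, c("source", "l", "fraction")],
    by = c("source", "l"), suffix = c("_a", "_b")
  )
  if (nrow(j) != nrow(spec_a) || nrow(j) != nrow(spec_b))
    stop("grouping mismatch: spectra do not share the same (source, degree) grid")
  d <- 100 * abs(j$fraction_a - j$fraction_b)
  tibble::tibble(max_abs_diff = max(d), median_abs_diff = stats::median(d))
}

#' Percentile envelopes of spectra over sources
#'
#' Per-frequency percentiles (median, 90th, 99th, 99.9th by default) and
#' the maximum of the relative energy contributions across all sources.
#'
#' @param spectra an `energy_spectrum` tibble.
#' @param probs percentile levels.
#' @return tibble of class `spectral_report`: `l`, `stat`, `fraction`, `db`;
#'   stats are ordered and pointwise non-decreasing.
#' @export
percentile_envelopes <- function(spectra, probs = c(0.5, 0.9, 0.99, 0.999)) {
  probs <- sort(probs)
  labs <- c(sprintf("p%s", formatC(100 * probs, format = "fg")), "max")
  out <- dplyr::group_modify(dplyr::group_by(spectra, .data$l), function(d, g) {
    q <- stats::quantile(d$fraction, probs = probs, names = FALSE, type = 7)
    tibble::tibble(stat = factor(labs, levels = labs),
                   fraction = c(q, max(d$fraction)))
  })
  out <- dplyr::ungroup(dplyr::mutate(out, db = to_db(.data$fraction)))
  attr(out, "probs") <- probs
  class(out) <- c("spectral_report", class(out))
  out
}

#' Per-depth-group maximum envelopes
#'
#' Splits the sources into depth groups (equal-count groups by default) and
#' reports, per group and spatial frequency, the maximum relative energy
#' contribution. Near-surface groups dominate at high spatial frequencies.
#'
#' @param spectra an `energy_spectrum` tibble (carries `depth_mm`).
#' @param n_groups number of equal-count depth groups (default 6).
#' @param edges optional explicit strictly-increasing depth edges
#'   (length `n_groups + 1`), overriding the equal-count split.
#' @return tibble: `group`, `depth_min`, `depth_max`, `n_sources`, `l`,
#'   `fraction`, `db`.
#' @export
depth_group_envelopes <- function(spectra, n_groups = 6L, edges = NULL) {
  src <- dplyr::distinct(spectra, .data$source, .data$depth_mm)
  if (is.null(edges)) {
    edges <- stats::quantile(src$depth_mm, probs = seq(0, 1, length.out = n_groups + 1))
    edges <- unique(as.numeric(edges))
  }
  if (any(diff(edges) <= 0)) stop("depth group edges must be strictly increasing")
  grp <- cut(spectra$depth_mm, breaks = edges, include.lowest = TRUE)
  if (any(is.na(grp))) warning("sources outside the depth edges were dropped")
  keep <- !is.na(grp)
  d <- dplyr::mutate(spectra[keep, ], group = grp[keep])
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(d, .data$source, .data$depth_mm,
                                    .data$group), .data$group),
    n_sources = dplyr::n(), .groups = "drop"
  )
  empty <- setdiff(levels(grp), as.character(counts$group))
  if (length(empty))
    warning("empty depth group(s) omitted: ", paste(empty, collapse = ", "))
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$l),
    depth_min = min(.data$depth_mm),
    depth_max = max(.data$depth_mm),
    fraction = max(.data$fraction),
    .groups = "drop"
  )
  out <- dplyr::left_join(out, counts, by = "group")
  out <- dplyr::mutate(out, db = to_db(.data$fraction))
  out[, c("group", "depth_min", "depth_max", "n_sources", "l", "fraction", "db")]
}

#' Depth and orientation metrics of sources
#'
#' For each source: the depth (distance to the nearest point of the outer
#' surface) and the orientation angle between the source moment and the
#' direction to the nearest point of the inner surface, folded into the range
#' 0 to 90 degrees (0 = radial, 90 = tangential).
#'
#' Surfaces may be analytic spheres (given as radii) or [trimesh()] objects
#' (nearest mesh vertex is used).
#'
#' @param sources a tibble with columns `x,y,z,mx,my,mz` (e.g. a
#'   [dipole_ensemble()]).
#' @param outer outer surface: radius in mm or a `trimesh`.
#' @param inner inner surface: radius in mm or a `trimesh`.
#' @return the input with columns `depth_mm` and `orientation_deg`
#'   added/replaced.
#' @export
source_geometry_metrics <- function(sources, outer, inner) {
  pos <- as.matrix(sources[, c("x", "y", "z")])
  mom <- as.matrix(sources[, c("mx", "my", "mz")])
  r <- sqrt(rowSums(pos^2))
  if (is.numeric(inner)) {
    if (any(r >= inner)) stop("source(s) outside the inner surface")
    dir_in <- pos / ifelse(r == 0, 1, r)     # radial direction
    if (any(r == 0))
      dir_in[r == 0, ] <- matrix(c(0, 0, 1), sum(r == 0), 3, byrow = TRUE)
  } else {
    nn <- nearest_vertex(pos, inner$vertices)
    dir_in <- inner$vertices[nn, , drop = FALSE] - pos
    dir_in <- dir_in / sqrt(rowSums(dir_in^2))
  }
  depth <- if (is.numeric(outer)) outer - r else {
    nn <- nearest_vertex(pos, outer$vertices)
    sqrt(rowSums((outer$vertices[nn, , drop = FALSE] - pos)^2))
  }
  ca <- abs(rowSums(mom * dir_in)) / sqrt(rowSums(mom^2))
  ang <- acos(pmin(1, ca)) * 180 / pi
  dplyr::mutate(tibble::as_tibble(sources), depth_mm = depth,
                orientation_deg = ang)
}

nearest_vertex <- function(pos, verts) {
  vapply(seq_len(nrow(pos)), function(i) {
    which.min(colSums((t(verts) - pos[i, ])^2))
  }, integer(1))
}
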