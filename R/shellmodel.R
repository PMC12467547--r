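#' Four-shell concentric spherical head model
#'
#' Concentric spheres for brain, CSF, skull and scalp with piecewise-constant
#' isotropic conductivities. Defaults are the widely used adult-head values:
#' radii 80/81/86/92 mm and conductivities 0.33/1.79/0.0066/0.33 S/m
#' (brain, CSF, skull, scalp).
#'
#' @param radii increasing positive radii R1 < R2 < R3 < R4 in mm.
#' @param conductivities positive conductivities in S/m, same order.
#' @return An object of class `shell_model` with fields `radii`,
#'   `conductivities` and the conductivity ratios `k = c(s1/s2, s2/s3, s3/s4)`.
#' @export
shell_model <- function(radii = c(80, 81, 86, 92),
                        conductivities = c(0.33, 1.79, 0.0066, 0.33)) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != 4 || length(conductivities) != 4)
    stop("need exactly four radii and four conductivities")
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")
  if (any(conductivities <= 0))
    stop("conductivities must be positive")
  structure(
    list(
      radii = radii,
      conductivities = conductivities,
      k = conductivities[1:3] / conductivities[2:4]
    ),
    class = "shell_model"
  )
}

#' @export
print.shell_model <- function(x, ...) {
  cat("<shell_model> four concentric shells\n")
  cat("  radii (mm):        ", paste(format(x$radii), collapse = ", "), "\n")
  cat("  conductivity (S/m):", paste(format(x$conductivities), collapse = ", "), "\n")
  invisible(x)
}

#' Current dipole source
#'
#' A point current dipole inside the innermost shell, with unit moment by
#' default. The eccentricity `f` is the distance from the model centre
#' divided by the outer radius R4; it controls the `f^(l-1)` depth weighting
#' of the Legendre series terms.
#'
#' @param position length-3 position in mm (must lie strictly inside R1).
#' @param moment length-3 moment direction; normalised to unit length unless
#'   `unit = FALSE`.
#' @param model a [shell_model()] used to validate the position and derive
#'   the eccentricity.
#' @param orientation_class one of `"radial"`, `"tangential"`, `"free"`;
#'   `"auto"` classifies from the angle between moment and position.
#' @param unit normalise the moment to unit magnitude (default `TRUE`).
#' @return An object of class `dipole` with fields `position`, `moment`,
#'   `f` (eccentricity) and `orientation_class`.
#' @export
dipole <- function(position, moment, model = shell_model(),
                   orientation_class = "auto", unit = TRUE) {
  position <- as.numeric(position)
  moment <- as.numeric(moment)
  if (length(position) != 3 || length(moment) != 3)
    stop("`position` and `moment` must be length-3")
  r <- sqrt(sum(position^2))
  if (r >= model$radii[1])
    stop("dipole position must lie strictly inside the innermost shell R1")
  nm <- sqrt(sum(moment^2))
  if (nm == 0) stop("moment must be nonzero")
  if (unit) moment <- moment / nm
  if (identical(orientation_class, "auto")) {
    if (r == 0) {
      orientation_class <- "free"
    } else {
      ca <- abs(sum(position * moment)) / (r * sqrt(sum(moment^2)))
      orientation_class <- if (ca > 1 - 1e-9) "radial"
        else if (ca < 1e-9) "tangential" else "free"
    }
  }
  structure(
    list(
      position = position,
      moment = moment,
      f = r / model$radii[4],
      orientation_class = orientation_class
    ),
    class = "dipole"
  )
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf(
    "<dipole> r = %.2f mm (f = %.3f), class = %s\n",
    sqrt(sum(x$position^2)) , x$f, x$orientation_class
  ))
  invisible(x)
}

#' Rotate a dipole into the canonical frame
#'
#' The series solution of the four-shell model is stated for a dipole on the
#' positive z-axis. This helper returns the rotation that maps the dipole
#' position onto +z, the rotated (canonical) dipole, and the inverse
#' rotation for mapping surface fields back. A dipole at the centre gets the
#' identity rotation.
#'
#' @param d a [dipole()].
#' @param model a [shell_model()].
#' @return list with elements `dipole` (canonical), `rotation` (3 x 3,
#'   maps world to canonical coordinates) and `inverse` (its transpose).
#' @export
rotate_to_canonical <- function(d, model = shell_model()) {
  r <- sqrt(sum(d$position^2))
  if (r == 0) {
    q <- diag(3)
  } else {
    q <- rotation_onto_z(d$position / r)
  }
  dc <- d
  dc$position <- as.numeric(q %*% d$position)
  dc$position[1:2] <- 0  # exact canonical form
  dc$moment <- as.numeric(q %*% d$moment)
  list(dipole = dc, rotation = q, inverse = t(q))
}

# rotation matrix Q with Q u = e_z, minimal-angle (Rodrigues)
rotation_onto_z <- function(u) {
  ez <- c(0, 0, 1)
  cth <- sum(u * ez)
  if (cth > 1 - 1e-14) return(diag(3))
  if (cth < -1 + 1e-14) return(diag(c(1, -1, -1)))  # half-turn about x
  v <- c(u[2] * ez[3] - u[3] * ez[2],
         u[3] * ez[1] - u[1] * ez[3],
         u[1] * ez[2] - u[2] * ez[1])   # u x ez
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}
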