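#' Build a helical collagen fiber field
#'
#' Assigns each element a unit fiber direction realizing a global fascicle
#' twist angle `alpha`: fibers follow helices about the (bowed) mesh
#' centerline with uniform axial twist rate `k = alpha / L` over the free
#' tendon length `L`, so the accumulated rotation of peripheral fibers from
#' the proximal to the distal free tendon equals `alpha`. At the centerline
#' the direction is axial. The handedness matches the internal rotation of
#' the subtendon partition; flipping `side` mirrors the circumferential
#' component.
#'
#' The direction at an element centroid with in-plane radius `r` and
#' angular position `phi` is the normalized local helix tangent
#' `(-r k sin(phi), r k cos(phi), 1)` (plus the centerline slope), the
#' continuum counterpart of fitting per-point material rotations as a
#' smooth field.
#'
#' @param mesh a [generate_mesh()] mesh.
#' @param alpha global fascicle twist angle, degrees, >= 0. Values above
#'   90 degrees trigger a warning (outside the physiological range) but
#'   are accepted.
#' @param side chirality; defaults to the mesh geometry's side.
#' @return object of class `fiber_field`: list with `alpha` (degrees) and
#'   `directions` (E x 3 unit vectors).
#' @examples
#' mesh <- generate_mesh(geometry_params(), resolution = c(4, 8))
#' fib <- build_fiber_field(mesh, 30)
#' range(sqrt(rowSums(fib$directions^2)))
#' @export
build_fiber_field <- function(mesh, alpha, side = mesh$params$side) {
  stopifnot(alpha >= 0)
  if (alpha > 90)
    warning("fascicle twist angle ", alpha,
            " deg is outside the physiological range (0-90 deg)")
  params <- mesh$params
  cent <- element_centroids(mesh)
  k <- alpha * pi / 180 / params$free_tendon_length  # rad/mm
  sgn <- if (side == "right") -1 else 1
  dx <- cent[, 1] - centerline_offset(cent[, 3], params)
  dy <- cent[, 2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  d <- cbind(centerline_slope(cent[, 3], params) + sgn * r * k * (-sin(phi)),
             sgn * r * k * cos(phi),
             1)
  d <- d / sqrt(rowSums(d^2))
  structure(list(alpha = alpha, directions = d, side = side),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("Helical fiber field: alpha = %g deg (%s side), %d element directions\n",
              x$alpha, x$side, nrow(x$directions)))
  invisible(x)
}

#' Euler angles mapping the axial direction onto a fiber direction
#'
#' Decomposes the rotation taking the reference axial direction (0, 0, 1)
#' onto a given unit direction as three sequential intrinsic z-x-z
#' rotations (the third angle, a spin about the fiber axis, is immaterial
#' for a transversely isotropic material and is set to zero).
#'
#' @param direction unit 3-vector.
#' @return numeric vector `c(phi, theta, psi)` in radians such that
#'   `euler_to_rotation(angles) %*% c(0, 0, 1)` reproduces `direction`.
#' @seealso [euler_to_rotation()]
#' @export
rotation_to_euler <- function(direction) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-14) stop("cannot orient a zero-length direction")
  d <- direction / n
  theta <- acos(max(-1, min(1, d[3])))
  phi <- if (sin(theta) < 1e-14) 0 else atan2(d[1], -d[2])
  c(phi = phi, theta = theta, psi = 0)
}

#' Compose intrinsic z-x-z Euler rotations
#'
#' @param angles numeric vector `c(phi, theta, psi)`, radians.
#' @return 3x3 rotation matrix `Rz(phi) %*% Rx(theta) %*% Rz(psi)`.
#' @export
euler_to_rotation <- function(angles) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0,
                             -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  rx <- function(a) matrix(c(1, 0, 0,
                             0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
}
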