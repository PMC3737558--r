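#' Confining spherocylinder geometry
#'
#' Constructs the spherocylindrical (capped-cylinder) container in reduced
#' units. The cylinder diameter `D` defines the unit of length; the total
#' tip-to-tip length `L` (including both hemispherical caps) is `aspect * D`.
#'
#' @param diameter Cylinder diameter `D` (reduced length unit; default 1).
#' @param aspect Aspect ratio `A = L / D` where `L` is the total tip-to-tip
#'   length. Must be >= 1 so the caps fit. Default 4, the aspect ratio of a
#'   typical E. coli cell.
#' @return An object of class `spherocylinder` with fields `D`, `L`, `aspect`
#'   and `volume`.
#' @examples
#' geom <- spherocylinder()
#' geom$volume            # 11 * pi / 12 for D = 1, L = 4
#' @export
spherocylinder <- function(diameter = 1, aspect = 4) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("'diameter' must be a single positive number")
  if (!is.numeric(aspect) || length(aspect) != 1L || aspect < 1)
    stop("'aspect' must be a single number >= 1 (caps must fit)")
  L <- aspect * diameter
  geom <- list(
    D = diameter,
    L = L,
    aspect = aspect,
    volume = spherocylinder_volume(diameter, L)
  )
  class(geom) <- "spherocylinder"
  geom
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat("Spherocylindrical container (reduced units)\n")
  cat(sprintf("  diameter D      : %g\n", x$D))
  cat(sprintf("  total length L  : %g (aspect L/D = %g)\n", x$L, x$aspect))
  cat(sprintf("  volume          : %g\n", x$volume))
  invisible(x)
}

#' Volume of a spherocylinder
#'
#' Volume of a cylinder of diameter `D` with two hemispherical caps, where `L`
#' is the total tip-to-tip length: `pi (D/2)^2 (L - D) + (4/3) pi (D/2)^3`.
#' At `L = D` this degenerates to a sphere.
#'
#' @param D Cylinder diameter (> 0).
#' @param L Total tip-to-tip length (>= D).
#' @return The volume.
#' @examples
#' spherocylinder_volume(1, 1)  # sphere: pi/6
#' spherocylinder_volume(1, 4)  # 11*pi/12
#' @export
spherocylinder_volume <- function(D, L) {
  if (!is.numeric(D) || !is.numeric(L) || any(D <= 0) || any(L <= 0))
    stop("'D' and 'L' must be positive")
  if (any(L < D))
    stop("total length L must be >= diameter D (hemispherical caps must fit)")
  pi * (D / 2)^2 * (L - D) + (4 / 3) * pi * (D / 2)^3
}

#' Bead radius for a target volume fraction
#'
#' Solves for the bead radius `r` such that `N_total` beads occupy the volume
#' fraction `phi` of the container: `N_total (4/3) pi r^3 = phi V`. This is
#' how the chains are made thinner as they are made longer at constant
#' monomer volume: with the container fixed, `r` scales as `N_total^(-1/3)`
#' and the diameter ratio `D/d = D/(2r)` grows as `N_total^(1/3)`.
#'
#' @param n_total Total number of beads over all chains (>= 1).
#' @param phi Target volume fraction, in (0, 0.74).
#' @param geom A [spherocylinder()].
#' @return Bead radius `r` (reduced length).
#' @examples
#' geom <- spherocylinder()
#' r <- solve_bead_radius(400, 0.05, geom)
#' geom$D / (2 * r)  # ~ 11
#' @export
solve_bead_radius <- function(n_total, phi, geom) {
  stopifnot(inherits(geom, "spherocylinder"))
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1)
    stop("'n_total' must be a single count >= 1")
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 0.74)
    stop("'phi' must lie in (0, 0.74)")
  r <- (phi * geom$volume * 3 / (4 * pi * n_total))^(1 / 3)
  if (2 * r >= geom$D)
    stop(sprintf("bead diameter 2r = %g does not fit in the container (D = %g)",
                 2 * r, geom$D))
  r
}

#' Test whether a bead lies entirely inside the container
#'
#' A bead of radius `r` centred at `center` lies inside the spherocylinder iff
#' its centre lies inside the container eroded by `r`, i.e. within distance
#' `D/2 - r` of the axial segment from `z = -(L - D)/2` to `z = +(L - D)/2`
#' (container axis = z, origin at the centroid). The boundary counts as
#' inside.
#'
#' @param geom A [spherocylinder()].
#' @param center Numeric vector of length 3, or an `n x 3` matrix of centres.
#' @param r Bead radius, `0 <= r < D/2`.
#' @return Logical (vector if `center` is a matrix).
#' @export
contains_bead <- function(geom, center, r) {
  stopifnot(inherits(geom, "spherocylinder"))
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= geom$D / 2)
    stop("'r' must satisfy 0 <= r < D/2")
  if (is.null(dim(center))) center <- matrix(center, ncol = 3L)
  stopifnot(ncol(center) == 3L)
  half <- (geom$L - geom$D) / 2          # axial half-length of the cylinder body
  dz <- pmax(abs(center[, 3L]) - half, 0)
  d2 <- center[, 1L]^2 + center[, 2L]^2 + dz^2
  d2 <= (geom$D / 2 - r)^2 * (1 + 1e-12) # closed boundary, fp-tolerant
}
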