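#' Nuclear shape
#'
#' Construct a spherical or ellipsoidal nucleus. All lengths are in
#' micrometres. A sphere is stored as an ellipsoid with three equal
#' semi-axes.
#'
#' @param semi_axes Numeric vector of one (sphere radius) or three
#'   (ellipsoid semi-axes a, b, c) positive lengths in micrometres.
#' @return An object of class `nucleus_shape` with fields `kind`
#'   (`"sphere"` or `"ellipsoid"`) and `semi_axes` (length 3).
#' @examples
#' nucleus_shape(5)                    # 5 um radius sphere
#' nucleus_shape(c(1.0, 11.8, 11.8))   # flattened ellipsoid
#' @export
nucleus_shape <- function(semi_axes) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("semi_axes must be 1 or 3 positive finite lengths (um)")
  }
  kind <- if (length(unique(semi_axes)) == 1L) "sphere" else "ellipsoid"
  structure(list(kind = kind, semi_axes = semi_axes),
            class = "nucleus_shape")
}

#' @export
print.nucleus_shape <- function(x, ...) {
  cat(sprintf("<nucleus %s: %s um, V = %.2f um^3>\n", x$kind,
              paste(signif(x$semi_axes, 4), collapse = " x "),
              nucleus_volume(x)))
  invisible(x)
}

#' Nucleus volume
#'
#' @param nucleus A [nucleus_shape()].
#' @return Volume in cubic micrometres, (4/3) pi a b c.
#' @export
nucleus_volume <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_shape"))
  (4 / 3) * pi * prod(nucleus$semi_axes)
}

#' Nucleus surface area
#'
#' Exact for spheres; Knud Thomsen's approximation (p = 1.6075,
#' relative error below 1.1 percent) for ellipsoids.
#'
#' @param nucleus A [nucleus_shape()].
#' @return Surface area in square micrometres.
#' @export
nucleus_surface <- function(nucleus) {
  s <- nucleus$semi_axes
  if (nucleus$kind == "sphere") return(4 * pi * s[1]^2)
  p <- 1.6075
  4 * pi * ((s[1]^p * s[2]^p + s[1]^p * s[3]^p + s[2]^p * s[3]^p) / 3)^(1 / p)
}

#' Mean chord length of the nucleus
#'
#' Cauchy's formula for convex bodies, 4 V / S. Used to convert a dose
#' and LET into an expected particle-track count.
#'
#' @param nucleus A [nucleus_shape()].
#' @return Mean chord length in micrometres.
#' @export
mean_chord_length <- function(nucleus) {
  4 * nucleus_volume(nucleus) / nucleus_surface(nucleus)
}

#' Normalised radial coordinate of points
#'
#' For a point x the value u = sqrt((x/a)^2 + (y/b)^2 + (z/c)^2); u <= 1
#' iff the point is inside the nucleus, and u is the fraction of the
#' boundary distance along the ray from the centre.
#'
#' @param coords Numeric matrix n x 3 (um).
#' @param nucleus A [nucleus_shape()].
#' @return Numeric vector of length n.
#' @export
nucleus_radial <- function(coords, nucleus) {
  coords <- coords_matrix(coords)
  s <- nucleus$semi_axes
  sqrt((coords[, 1] / s[1])^2 + (coords[, 2] / s[2])^2 +
         (coords[, 3] / s[3])^2)
}

#' Test points for nucleus membership
#'
#' Ellipsoid membership is (x/a)^2 + (y/b)^2 + (z/c)^2 <= 1.
#'
#' @inheritParams nucleus_radial
#' @param tol Numerical slack on the boundary.
#' @return Logical vector.
#' @export
nucleus_contains <- function(coords, nucleus, tol = 1e-12) {
  nucleus_radial(coords, nucleus) <= 1 + tol
}

#' Distance beyond the nuclear boundary
#'
#' Zero for points inside the nucleus. Outside, the distance is measured
#' along the ray from the centre to the scaled boundary point
#' (exact for spheres; scaled-radial approximation for ellipsoids).
#'
#' @inheritParams nucleus_radial
#' @return Numeric vector of non-negative distances in micrometres.
#' @export
boundary_excess <- function(coords, nucleus) {
  coords <- coords_matrix(coords)
  u <- nucleus_radial(coords, nucleus)
  r <- sqrt(rowSums(coords^2))
  out <- numeric(length(u))
  i <- u > 1
  out[i] <- r[i] * (1 - 1 / u[i])
  out
}

#' Sample points uniformly inside the nucleus
#'
#' Uniform in the unit ball (normal direction, cube-root radius), then
#' scaled by the semi-axes, which is uniform in the ellipsoid volume.
#' Uses the current R random number stream.
#'
#' @param n Number of points.
#' @param nucleus A [nucleus_shape()].
#' @return Numeric matrix n x 3 in micrometres.
#' @export
sample_in_nucleus <- function(n, nucleus) {
  stopifnot(inherits(nucleus, "nucleus_shape"), n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z <- z / sqrt(rowSums(z^2))
  r <- stats::runif(n)^(1 / 3)
  pts <- z * r
  sweep(pts, 2, nucleus$semi_axes, `*`)
}

# coerce to an n x 3 numeric matrix; accepts a length-3 vector as one point
coords_matrix <- function(coords) {
  if (is.null(dim(coords))) {
    stopifnot(length(coords) == 3L)
    coords <- matrix(coords, 1L, 3L)
  }
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  storage.mode(coords) <- "double"
  coords
}
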