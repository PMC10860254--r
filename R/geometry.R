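## Planar geometry in the y-down image frame (patient faces +x).
## Points are numeric length-2 vectors c(x, y); lines carry an origin and a
## direction that need not be unit length.

#' Construct a line from an origin and direction
#'
#' Lines live in the y-down image coordinate frame. The direction need not be
#' normalised but must be nonzero.
#'
#' @param origin Numeric length-2 point `c(x, y)` in pixels.
#' @param direction Numeric length-2 direction vector; nonzero.
#' @return An object of class `ceph_line`.
#' @seealso [line_through()] to construct from two points.
#' @export
ceph_line <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  stopifnot(length(origin) == 2, length(direction) == 2,
            all(is.finite(origin)), all(is.finite(direction)))
  if (sum(direction^2) == 0) {
    stop("line direction must have nonzero norm", call. = FALSE)
  }
  structure(list(origin = origin, direction = direction), class = "ceph_line")
}

#' @rdname ceph_line
#' @param from,to Two distinct points; the line runs from `from` towards `to`.
#' @export
line_through <- function(from, to) {
  ceph_line(from, as.numeric(to) - as.numeric(from))
}

#' @export
print.ceph_line <- function(x, ...) {
  cat(sprintf("<ceph_line> origin (%.2f, %.2f), direction (%.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$direction[1], x$direction[2]))
  invisible(x)
}

as_point <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 2, all(is.finite(p)))
  p
}

#' Angle at a vertex
#'
#' The angle a-v-b in degrees, i.e. the angle between the arms v->a and v->b,
#' always in \[0, 180\]. This is the working definition of cephalometric
#' angles such as SNA (S-N-A) and SNB (S-N-B).
#'
#' @param a,v,b Numeric length-2 points; `v` is the vertex.
#' @return Angle in degrees in \[0, 180\].
#' @export
#' @examples
#' angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)) # 90
angle_at_vertex <- function(a, v, b) {
  a <- as_point(a); v <- as_point(v); b <- as_point(b)
  u <- a - v
  w <- b - v
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) {
    stop("angle_at_vertex: zero-length arm", call. = FALSE)
  }
  co <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, co))) * 180 / pi
}

#' Angle between two lines
#'
#' Undirected angle between two lines in degrees: `acute` gives the value in
#' \[0, 90\], `obtuse` its supplement. Used for measurements between
#' cephalometric planes, e.g. the facial depth (facial plane vs Frankfurt
#' horizontal, acute) and the facial axis (obtuse).
#'
#' @param l1,l2 [ceph_line] objects.
#' @param convention `"acute"` or `"obtuse"`.
#' @return Angle in degrees.
#' @export
angle_between_lines <- function(l1, l2, convention = c("acute", "obtuse")) {
  convention <- match.arg(convention)
  d1 <- l1$direction
  d2 <- l2$direction
  co <- abs(sum(d1 * d2)) / sqrt(sum(d1^2) * sum(d2^2))
  acute <- acos(min(1, co)) * 180 / pi
  if (convention == "obtuse") 180 - acute else acute
}

#' Signed inclination difference between two lines
#'
#' Inclination of `l_ref` minus inclination of `l`, in degrees in (-180, 180],
#' where inclination is `atan2(dy, dx)` in the y-down frame. Both lines must
#' be directed anteriorly (positive x direction component); this is the
#' convention behind the palatal-plane angle, measured against the Frankfurt
#' horizontal.
#'
#' @param l_ref,l [ceph_line] objects directed anteriorly.
#' @return Signed angle in degrees.
#' @export
inclination_difference <- function(l_ref, l) {
  for (ln in list(l_ref, l)) {
    if (ln$direction[1] <= 0) {
      stop("inclination_difference: lines must be directed anteriorly (+x)",
           call. = FALSE)
    }
  }
  inc <- function(d) atan2(d[2], d[1]) * 180 / pi
  delta <- inc(l_ref$direction) - inc(l$direction)
  # wrap to (-180, 180]
  delta - 360 * ceiling((delta - 180) / 360)
}

#' Signed perpendicular distance from a point to a line
#'
#' Perpendicular distance in pixels with a clinically meaningful sign:
#' * `anterior_positive` — positive when the point lies anterior (towards the
#'   face, +x side) of a line directed cranial-to-caudal, as used for the
#'   convexity of point A, incisor positions and lip-to-E-line distances;
#' * `inferior_positive` — positive when the point lies inferior (+y side) of
#'   a line directed posterior-to-anterior, as used for the vertical molar
#'   distance to the palatal plane.
#'
#' @param p Numeric length-2 point.
#' @param l A [ceph_line] directed according to the chosen convention.
#' @param sign_convention `"anterior_positive"` or `"inferior_positive"`.
#' @return Signed distance in pixels.
#' @export
signed_point_line_distance <- function(p, l,
                                       sign_convention = c("anterior_positive",
                                                           "inferior_positive")) {
  sign_convention <- match.arg(sign_convention)
  p <- as_point(p)
  d <- l$direction
  delta <- p - l$origin
  nrm <- sqrt(sum(d^2))
  if (sign_convention == "anterior_positive") {
    (d[2] * delta[1] - d[1] * delta[2]) / nrm
  } else {
    (d[1] * delta[2] - d[2] * delta[1]) / nrm
  }
}

#' Scalar projection of a point onto an axis
#'
#' Signed length of the projection of `origin -> p` onto the direction of
#' `axis`, in pixels. Used for the sagittal molar distance measured along the
#' Frankfurt horizontal from the pterygoid point.
#'
#' @param p Numeric length-2 point.
#' @param origin Numeric length-2 point the projection is measured from.
#' @param axis A [ceph_line] supplying the direction.
#' @return Signed projection length in pixels.
#' @export
project_along <- function(p, origin, axis) {
  p <- as_point(p)
  origin <- as_point(origin)
  d <- axis$direction
  sum((p - origin) * d) / sqrt(sum(d^2))
}

#' Intersection point of two lines
#'
#' Solves the 2x2 linear system for the unique intersection. Lines closer to
#' parallel than `tol` (on the sine of the angle between them) are an error.
#' This is the construction of Gnk, the intersection of the mandibular plane
#' (hT-Me) with the facial plane (N-Po).
#'
#' @param l1,l2 [ceph_line] objects.
#' @param tol Parallelism tolerance on |sin(angle)|.
#' @return Numeric length-2 intersection point.
#' @export
line_intersection <- function(l1, l2, tol = 1e-9) {
  d1 <- l1$direction
  d2 <- l2$direction
  cross <- d1[1] * d2[2] - d1[2] * d2[1]
  sin_angle <- abs(cross) / sqrt(sum(d1^2) * sum(d2^2))
  if (sin_angle < tol) {
    stop("line_intersection: lines are (near-)parallel", call. = FALSE)
  }
  rhs <- l2$origin - l1$origin
  t1 <- (rhs[1] * d2[2] - rhs[2] * d2[1]) / cross
  l1$origin + t1 * d1
}

#' Construct Xi, the ramus midpoint
#'
#' Xi is the centre of the ramus of the mandible, located in the frame aligned
#' with the Frankfurt horizontal: with u the unit direction along FH and n its
#' perpendicular, Xi has u-coordinate midway between R1 and R2 and
#' n-coordinate midway between R3 and R4 — the centre of the FH-oriented
#' rectangle bounded laterally by R1/R2 and vertically by R3/R4.
#'
#' @param r1,r2,r3,r4 Numeric length-2 ramus border points.
#' @param fh The Frankfurt horizontal as a [ceph_line] (P towards Or).
#' @return Numeric length-2 point Xi.
#' @export
construct_xi <- function(r1, r2, r3, r4, fh) {
  d <- fh$direction
  u <- d / sqrt(sum(d^2))
  n <- c(-u[2], u[1])
  pts <- lapply(list(r1, r2, r3, r4), as_point)
  uc <- vapply(pts, function(p) sum(p * u), numeric(1))
  nc <- vapply(pts, function(p) sum(p * n), numeric(1))
  xi_u <- (uc[1] + uc[2]) / 2
  xi_n <- (nc[3] + nc[4]) / 2
  xi_u * u + xi_n * n
}
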